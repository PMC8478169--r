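# Copper-induction qPCR analysis: reference-gene stability screening
# (BestKeeper-style CT standard deviation), delta-delta-CT relative
# expression, and normality-gated significance testing.

#' Read a CT table (delimited: strain, gene, condition, timepoint, replicate, ct)
#'
#' @param path CSV path.
#' @return The CT records data frame.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "gene", "condition", "timepoint", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("CT table needs columns: ", paste(need, collapse = ", "))
  ct
}

#' Reference-gene stability by CT standard deviation
#'
#' BestKeeper-style screen: the sample standard deviation (n-1 denominator)
#' of all CT observations of the gene, across conditions and replicates; the
#' gene is stable when the SD is strictly below 1 cycle.
#'
#' @param records CT records (see [read_ct_table]).
#' @param gene Candidate reference gene.
#' @return `list(sd, stable, n)`.
#' @export
reference_stability <- function(records, gene) {
  ct <- records$ct[records$gene == gene]
  if (length(ct) < 2L)
    stop(sprintf("need at least 2 CT observations for gene '%s' (have %d)",
                 gene, length(ct)))
  s <- stats::sd(ct)
  list(sd = s, stable = s < 1, n = length(ct))
}

#' Normality-gated two-group expression test
#'
#' Shapiro-Wilk is applied to each group; if both groups are consistent with
#' normality (p >= 0.05) a two-sided two-sample Student t-test (pooled
#' variance) is used, otherwise the two-sided Mann-Whitney U test. The pooled
#' t is exact at the small, balanced group sizes typical of qPCR designs,
#' where the Welch approximation is conservative. Groups smaller than 3
#' cannot be gated and fall back to Mann-Whitney with a warning. A group with
#' zero variance is treated as failing the normality gate.
#'
#' @param dct_treated,dct_control Per-replicate delta-CT values.
#' @param alpha Significance level. Default 0.05.
#' @return `list(test_used, p_value, significant)` with `test_used` one of
#'   `"t_test"`, `"mann_whitney"`.
#' @export
expression_test <- function(dct_treated, dct_control, alpha = 0.05) {
  if (length(dct_treated) == 0L || length(dct_control) == 0L)
    stop("empty group")
  use_t <- FALSE
  if (length(dct_treated) < 3L || length(dct_control) < 3L) {
    warning("groups smaller than 3: skipping the normality gate, using Mann-Whitney")
  } else {
    normal_p <- function(x) {
      if (stats::sd(x) == 0) return(0)  # degenerate: not testably normal
      stats::shapiro.test(x)$p.value
    }
    use_t <- normal_p(dct_treated) >= 0.05 && normal_p(dct_control) >= 0.05
  }
  if (use_t) {
    p <- stats::t.test(dct_treated, dct_control, var.equal = TRUE)$p.value
    test <- "t_test"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(dct_treated, dct_control, exact = NULL)$p.value)
    test <- "mann_whitney"
  }
  if (is.na(p)) p <- 1  # both groups constant and identical
  list(test_used = test, p_value = p, significant = p < alpha)
}

#' Relative expression by the delta-delta-CT method
#'
#' Per replicate within each condition, `dCT = CT(target) - CT(reference)`;
#' `ddCT = mean(dCT treated) - mean(dCT control)` (the calibrator is the mean
#' control dCT); `fold_change = 2^(-ddCT)`, `log2_fold_change = -ddCT`.
#' Significance comes from [expression_test] on the per-replicate dCT groups.
#'
#' @param records CT records (see [read_ct_table]).
#' @param target_gene,reference_gene Gene names; the reference must pass
#'   [reference_stability] unless `check_reference = FALSE`.
#' @param condition Treated condition label.
#' @param control_condition Control condition label. Default `"control"`.
#' @param strain,timepoint Optional filters applied before analysis.
#' @param alpha Significance level. Default 0.05.
#' @param check_reference Enforce reference stability. Default `TRUE`.
#' @return An `expression_result`: list with `gene`, `condition`,
#'   `dct_treated`, `dct_control`, `ddct`, `log2_fold_change`, `fold_change`,
#'   `test_used`, `p_value`, `significant`.
#' @export
delta_delta_ct <- function(records, target_gene, reference_gene,
                           condition, control_condition = "control",
                           strain = NULL, timepoint = NULL, alpha = 0.05,
                           check_reference = TRUE) {
  if (!is.null(strain)) records <- records[records$strain == strain, , drop = FALSE]
  if (!is.null(timepoint)) records <- records[records$timepoint == timepoint, , drop = FALSE]
  if (check_reference) {
    stab <- reference_stability(records, reference_gene)
    if (!stab$stable)
      stop(sprintf("reference gene '%s' is not stable (CT sd = %.3f >= 1)",
                   reference_gene, stab$sd))
  }
  dct_for <- function(cond) {
    tg <- records[records$gene == target_gene & records$condition == cond, , drop = FALSE]
    rf <- records[records$gene == reference_gene & records$condition == cond, , drop = FALSE]
    if (nrow(tg) == 0L)
      stop(sprintf("no CT observations for target '%s' in condition '%s'",
                   target_gene, cond))
    m <- match(tg$replicate, rf$replicate)
    if (anyNA(m))
      stop(sprintf("missing reference CT for replicate %s in condition '%s'",
                   paste(tg$replicate[is.na(m)], collapse = ", "), cond))
    stats::setNames(tg$ct - rf$ct[m], tg$replicate)
  }
  dct_treated <- dct_for(condition)
  dct_control <- dct_for(control_condition)
  ddct <- mean(dct_treated) - mean(dct_control)
  test <- expression_test(dct_treated, dct_control, alpha = alpha)
  structure(
    list(gene = target_gene, condition = condition,
         dct_treated = dct_treated, dct_control = dct_control,
         ddct = ddct, log2_fold_change = -ddct, fold_change = 2^(-ddct),
         test_used = test$test_used, p_value = test$p_value,
         significant = test$significant),
    class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("%s @ %s: log2FC %.2f (fold %.2f), %s p = %.4g%s\n",
              x$gene, x$condition, x$log2_fold_change, x$fold_change,
              x$test_used, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Run delta-delta-CT analysis over many genes and conditions
#'
#' @param records CT records.
#' @param target_genes Character vector of target genes.
#' @param reference_gene Stable reference gene.
#' @param conditions Treated condition labels (default: all non-control
#'   conditions present).
#' @param control_condition Control label. Default `"control"`.
#' @param strain,timepoint Optional filters.
#' @param alpha Significance level.
#' @param p_adjust `"none"` (default, mirroring the per-test convention) or
#'   `"BH"` for Benjamini-Hochberg across the result set.
#' @return `data.frame(gene, condition, ddct, log2_fold_change, fold_change,
#'   test_used, p_value, significant)`.
#' @export
analyze_expression <- function(records, target_genes, reference_gene,
                               conditions = NULL, control_condition = "control",
                               strain = NULL, timepoint = NULL, alpha = 0.05,
                               p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (is.null(conditions))
    conditions <- setdiff(unique(records$condition), control_condition)
  grid <- expand.grid(gene = target_genes, condition = conditions,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- delta_delta_ct(records, grid$gene[i], reference_gene,
                        grid$condition[i], control_condition,
                        strain = strain, timepoint = timepoint, alpha = alpha)
    data.frame(gene = r$gene, condition = r$condition, ddct = r$ddct,
               log2_fold_change = r$log2_fold_change,
               fold_change = r$fold_change, test_used = r$test_used,
               p_value = r$p_value, significant = r$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  }
  out
}
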