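# Turning raw profile-HMM hits into per-species, per-system resistome counts:
# duplicate-hit resolution, catalog-driven tabulation, E-value sweeps.

#' Resolve duplicate hits: one model per protein, smallest E-value wins
#'
#' Proteins hit by more than one model are assigned to the model with the
#' smallest E-value; exact ties are broken by the lexicographically smallest
#' model accession so the result is deterministic.
#'
#' @param hits Hit table (one proteome) with columns `protein_id`,
#'   `model_accession`, `evalue`.
#' @return The hit table with each `protein_id` occurring at most once.
#' @export
deduplicate_hits <- function(hits) {
  stopifnot(all(c("protein_id", "model_accession", "evalue") %in% names(hits)))
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$protein_id, hits$evalue, hits$model_accession)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$protein_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Tabulate deduplicated hits into per-model, per-category counts
#'
#' Counts hits per model accession (zero-hit models and categories are
#' reported explicitly as 0) for one labeled species/strain. Input should be
#' deduplicated so the count unit is proteins, not raw hits.
#'
#' @param hits Deduplicated hit table.
#' @param catalog Model catalog (see [default_model_catalog]).
#' @param species_label Caller-supplied species or strain label.
#' @param max_evalue Optional E-value threshold recorded as metadata.
#' @return `data.frame(species, system_category, model_accession, n_hits)`
#'   with one row per catalog model, attribute `max_evalue`.
#' @export
tabulate_hits <- function(hits, catalog = default_model_catalog(),
                          species_label = "unknown", max_evalue = NA_real_) {
  validate_model_catalog(catalog)
  unknown <- setdiff(unique(hits$model_accession), catalog$model_accession)
  if (length(unknown))
    stop("hit table references accessions absent from the catalog: ",
         paste(unknown, collapse = ", "))
  counts <- table(factor(hits$model_accession, levels = catalog$model_accession))
  out <- data.frame(species = species_label,
                    system_category = factor(catalog$system_category,
                                             levels = CATEGORY_LEVELS),
                    model_accession = catalog$model_accession,
                    n_hits = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(out$system_category, out$model_accession), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "max_evalue") <- max_evalue
  out
}

#' Per-category totals of a resistome count table
#'
#' @param counts Output of [tabulate_hits].
#' @return `data.frame(species, system_category, n_hits)`, all four categories
#'   present.
#' @export
category_totals <- function(counts) {
  agg <- stats::aggregate(n_hits ~ species + system_category, data = counts,
                          FUN = sum, drop = FALSE)
  agg$n_hits[is.na(agg$n_hits)] <- 0L
  agg[order(agg$species, agg$system_category), , drop = FALSE]
}

#' E-value sensitivity sweep
#'
#' For each threshold `t`, hits with `evalue <= t` are kept, deduplicated
#' independently, and tabulated. The number of distinct proteins with a
#' passing hit is non-decreasing as the threshold loosens.
#'
#' @param raw_hits Unthresholded (or loosely thresholded) hit table.
#' @param catalog Model catalog.
#' @param thresholds Numeric vector of E-value cutoffs (will be sorted
#'   ascending); must be non-empty.
#' @param species_label Species/strain label.
#' @return `list(by_model, by_category, n_proteins)`: long count tables with a
#'   `threshold` column, and the distinct-protein count per threshold.
#' @export
evalue_sweep <- function(raw_hits, catalog = default_model_catalog(),
                         thresholds, species_label = "unknown") {
  if (missing(thresholds) || length(thresholds) == 0L)
    stop("empty threshold list")
  thresholds <- sort(as.numeric(thresholds))
  per <- lapply(thresholds, function(t) {
    dd <- deduplicate_hits(raw_hits[raw_hits$evalue <= t, , drop = FALSE])
    tab <- tabulate_hits(dd, catalog, species_label, max_evalue = t)
    tab$threshold <- t
    cat_tot <- category_totals(tab)
    cat_tot$threshold <- t
    list(by_model = tab, by_category = cat_tot,
         n_proteins = data.frame(threshold = t,
                                 n_proteins = length(unique(dd$protein_id))))
  })
  list(by_model = do.call(rbind, lapply(per, `[[`, "by_model")),
       by_category = do.call(rbind, lapply(per, `[[`, "by_category")),
       n_proteins = do.call(rbind, lapply(per, `[[`, "n_proteins")))
}
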