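#' Score a protein sequence against a profile HMM (local Viterbi, bits)
#'
#' Maximum-scoring local alignment of the sequence to the model in log2-odds:
#' the emission score of residue `a` at match state `k` is
#' `log2(m_k(a) / background(a))` (inserts analogously), transitions
#' contribute `log2(p)`, and the alignment may begin and end at any match
#' state with unaligned flanking residues costing zero bits. The ambiguity
#' code `X` scores zero bits at any state; other non-standard residues are
#' rejected.
#'
#' @param model A [profile_hmm].
#' @param sequence Non-empty amino-acid string.
#' @return `list(bit_score, ali_start, ali_end)` with 1-based inclusive
#'   residue coordinates of the optimal envelope.
#' @export
viterbi_bitscore <- function(model, sequence) {
  stopifnot(inherits(model, "profile_hmm"))
  idx <- encode_residues(sequence)
  sc <- score_matrices(model)
  res <- .viterbi_local_cpp(sc$sm, sc$si, sc$tr, idx)
  list(bit_score = res$bit_score, ali_start = res$ali_start,
       ali_end = res$ali_end)
}

# Precompute log2-odds emission and log2 transition matrices for a model.
score_matrices <- function(model) {
  bg <- model$background
  list(sm = log2(sweep(model$match_emissions, 2, bg, "/")),
       si = log2(sweep(model$insert_emissions, 2, bg, "/")),
       tr = log2(model$transitions))
}

#' Gumbel E-value for a Viterbi bit score
#'
#' `E = N * P(S >= s)` under the Gumbel null,
#' `P = 1 - exp(-exp(-lambda * (s - mu)))`.
#'
#' @param bit_score Score in bits.
#' @param model A calibrated [profile_hmm], or `NULL` when `mu` and `lambda`
#'   are given explicitly.
#' @param database_size Number of sequences searched, `N >= 1`.
#' @param mu,lambda Optional explicit Gumbel parameters overriding the model's
#'   calibration.
#' @return The E-value (dimensionless expectation, `>= 0`).
#' @export
evalue <- function(bit_score, model = NULL, database_size = 1,
                   mu = NULL, lambda = NULL) {
  if (is.null(mu) || is.null(lambda)) {
    if (is.null(model) || is.null(model$calibration))
      stop("model has no Viterbi calibration; run calibrate_model() or supply mu and lambda explicitly")
    mu <- model$calibration$mu
    lambda <- model$calibration$lambda
  }
  if (database_size < 1) stop("database_size must be >= 1")
  x <- exp(-lambda * (bit_score - mu))
  database_size * (-expm1(-x))
}

#' Read an amino-acid FASTA proteome
#'
#' @param path FASTA file path.
#' @return Named character vector of protein sequences.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Search a proteome with a set of calibrated profile HMMs
#'
#' Every (model, protein) pair is Viterbi-scored; E-values use the number of
#' proteins searched as the database size `N`; hits with
#' `evalue <= max_evalue` (inclusive boundary) are retained and sorted by
#' `(protein_id, evalue)`.
#'
#' @param models List of calibrated [profile_hmm] objects.
#' @param proteome Named character vector of protein sequences, an
#'   `AAStringSet`, or a FASTA path.
#' @param max_evalue Inclusive E-value cutoff. Default `1e-30`, the study's
#'   hit-definition threshold; use `Inf` to keep every scored pair.
#' @return A hit table: `data.frame(protein_id, model_accession, bit_score,
#'   evalue, ali_start, ali_end)` with attribute `database_size`.
#' @export
search_proteome <- function(models, proteome, max_evalue = 1e-30) {
  if (inherits(models, "profile_hmm")) models <- list(models)
  if (length(models) == 0L) stop("empty model list")
  ok <- vapply(models, function(m)
    inherits(m, "profile_hmm") && !is.null(m$calibration), logical(1))
  if (!all(ok))
    stop("all models must be calibrated profile_hmm objects (see calibrate_model)")
  if (is.character(proteome) && length(proteome) == 1L && file.exists(proteome))
    proteome <- read_proteome(proteome)
  if (inherits(proteome, "AAStringSet")) {
    nm <- sub("\\s.*$", "", names(proteome))
    proteome <- stats::setNames(as.character(proteome), nm)
  }
  if (length(proteome) == 0L) {
    warning("empty proteome: returning an empty hit table")
    return(empty_hit_table(0L))
  }
  if (is.null(names(proteome)) || anyDuplicated(names(proteome)))
    stop("proteome sequences must carry unique names (duplicate or missing protein ids)")
  N <- length(proteome)
  encoded <- lapply(proteome, encode_residues)
  out <- vector("list", length(models))
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    sc <- score_matrices(m)
    hits <- lapply(seq_along(encoded), function(pi) {
      r <- .viterbi_local_cpp(sc$sm, sc$si, sc$tr, encoded[[pi]])
      c(score = r$bit_score, start = r$ali_start, end = r$ali_end)
    })
    hm <- do.call(rbind, hits)
    ev <- evalue(hm[, "score"], m, database_size = N)
    keep <- ev <= max_evalue
    out[[mi]] <- data.frame(
      protein_id = names(proteome)[keep],
      model_accession = rep(if (is.na(m$accession)) m$name else m$accession,
                            sum(keep)),
      bit_score = hm[keep, "score"],
      evalue = ev[keep],
      ali_start = as.integer(hm[keep, "start"]),
      ali_end = as.integer(hm[keep, "end"]),
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$protein_id, res$evalue, res$model_accession), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "database_size") <- N
  res
}

empty_hit_table <- function(database_size = 0L) {
  res <- data.frame(protein_id = character(), model_accession = character(),
                    bit_score = numeric(), evalue = numeric(),
                    ali_start = integer(), ali_end = integer())
  attr(res, "database_size") <- database_size
  res
}

#' Write / read a hit table as delimited text
#'
#' @param hits Hit table as returned by [search_proteome].
#' @param path CSV path.
#' @return `path` (write) or the hit table (read).
#' @export
write_hit_table <- function(hits, path) {
  utils::write.csv(hits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
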