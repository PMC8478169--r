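#' @useDynLib copperscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The 20-letter amino-acid alphabet, in the column order used throughout
#'
#' Order matches the HMMER3 ASCII convention (alphabetical one-letter codes).
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a profile hidden Markov model
#'
#' A plan-7-style profile HMM over the 20 amino acids: per-match-state emission
#' distributions, per-state insert emissions, the seven per-node transition
#' probabilities (M->M, M->I, M->D, I->M, I->I, D->M, D->D), a background
#' distribution, and an optional Gumbel calibration for Viterbi bit scores.
#'
#' @param name Model name.
#' @param accession Model accession (e.g. `"TIGR02044"`); may be `NA`.
#' @param match_emissions Numeric matrix, `L x 20`, rows summing to 1.
#' @param insert_emissions Numeric matrix, `L x 20`, rows summing to 1.
#' @param transitions Numeric matrix, `L x 7`, columns
#'   `mm, mi, md, im, ii, dm, dd`; the three outgoing groups (from M, from I,
#'   from D) must each sum to 1 per row.
#' @param background Length-20 probability vector.
#' @param calibration `NULL`, or `list(mu = , lambda = )` describing the Gumbel
#'   null distribution of Viterbi bit scores (`mu` in bits, `lambda` per bit).
#' @return An object of class `profile_hmm`.
#' @export
profile_hmm <- function(name, accession = NA_character_,
                        match_emissions, insert_emissions, transitions,
                        background = rep(1 / 20, 20), calibration = NULL) {
  match_emissions <- as.matrix(match_emissions)
  insert_emissions <- as.matrix(insert_emissions)
  transitions <- as.matrix(transitions)
  L <- nrow(match_emissions)
  if (L < 1L) stop("a profile HMM needs at least one match state")
  if (ncol(match_emissions) != 20L || ncol(insert_emissions) != 20L)
    stop("emission matrices must have 20 columns (amino-acid alphabet)")
  if (nrow(insert_emissions) != L || nrow(transitions) != L)
    stop("insert_emissions and transitions must have one row per match state")
  if (ncol(transitions) != 7L)
    stop("transitions must have 7 columns: mm, mi, md, im, ii, dm, dd")
  colnames(match_emissions) <- AA_ALPHABET20
  colnames(insert_emissions) <- AA_ALPHABET20
  colnames(transitions) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  background <- as.numeric(background)
  if (length(background) != 20L) stop("background must have length 20")
  names(background) <- AA_ALPHABET20
  obj <- structure(
    list(name = as.character(name), accession = as.character(accession),
         length = L, alphabet = AA_ALPHABET20,
         match_emissions = match_emissions,
         insert_emissions = insert_emissions,
         transitions = transitions, background = background,
         calibration = calibration),
    class = "profile_hmm")
  validate_profile_hmm(obj)
  obj
}

#' Validate the probabilistic invariants of a profile HMM
#'
#' Checks that every emission and background distribution sums to 1 (within
#' `tol`), that the three outgoing transition groups per node sum to 1, and
#' that any calibration has a positive lambda.
#'
#' @param hmm A `profile_hmm`.
#' @param tol Tolerance on distribution sums.
#' @return `hmm`, invisibly; errors if an invariant is violated.
#' @export
validate_profile_hmm <- function(hmm, tol = 1e-6) {
  stopifnot(inherits(hmm, "profile_hmm"))
  chk <- function(x, what) {
    bad <- abs(x - 1) > tol
    if (any(bad))
      stop(sprintf("%s do(es) not sum to 1 (first offender: row %d, sum %.8f)",
                   what, which(bad)[1], x[which(bad)[1]]))
  }
  chk(rowSums(hmm$match_emissions), "match emission distributions")
  chk(rowSums(hmm$insert_emissions), "insert emission distributions")
  chk(sum(hmm$background), "background distribution")
  tr <- hmm$transitions
  chk(tr[, "mm"] + tr[, "mi"] + tr[, "md"], "M-state outgoing transitions")
  chk(tr[, "im"] + tr[, "ii"], "I-state outgoing transitions")
  chk(tr[, "dm"] + tr[, "dd"], "D-state outgoing transitions")
  if (!is.null(hmm$calibration)) {
    if (!all(c("mu", "lambda") %in% names(hmm$calibration)))
      stop("calibration must be list(mu=, lambda=)")
    if (hmm$calibration$lambda <= 0) stop("calibration lambda must be > 0")
  }
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s' (%s): %d match states, %s\n",
              x$name, ifelse(is.na(x$accession), "no accession", x$accession),
              x$length,
              if (is.null(x$calibration)) "uncalibrated"
              else sprintf("Gumbel mu=%.2f bits, lambda=%.4f",
                           x$calibration$mu, x$calibration$lambda)))
  invisible(x)
}

# Map residues to 1..20 column indices; X -> 0 (scores zero bits everywhere).
# Any other character is an error.
encode_residues <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  idx <- match(chars, AA_ALPHABET20)
  idx[chars == "X"] <- 0L
  if (anyNA(idx))
    stop(sprintf("residue '%s' at position %d is outside the amino-acid alphabet (X allowed)",
                 chars[which(is.na(idx))[1]], which(is.na(idx))[1]))
  idx
}
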