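# Pairwise-similarity homolog retention: the "greater than 45% similar,
# 40-150% of query length" filter applied to candidate protein sequences.
# Alignment is delegated to Biostrings; the similarity definition (fraction of
# alignment columns, gaps included, whose residue pair has a positive
# substitution score) and the retention rule are implemented here.

#' Global pairwise protein alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment via `Biostrings::pairwiseAlignment`.
#' Defaults (BLOSUM62, gap open 11, gap extend 1) follow BLASTP convention:
#' a gap of length `k` costs `gap_open + k * gap_extend`.
#'
#' @param a,b Non-empty amino-acid sequences (query, subject).
#' @param substitution_matrix Matrix name or matrix. Default `"BLOSUM62"`.
#' @param gap_open,gap_extend Non-negative penalties. Defaults 11 and 1.
#' @param query_id,subject_id Optional sequence labels.
#' @return A `pairwise_alignment`: list with `aligned_query`,
#'   `aligned_subject`, `score`, `similarity`, `length_ratio`
#'   (subject length over query length, unaligned).
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1,
                         query_id = "query", subject_id = "subject") {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  submat <- resolve_submatrix(substitution_matrix)
  aln <- structure(
    list(query_id = query_id, subject_id = subject_id,
         aligned_query = as.character(Biostrings::alignedPattern(pa)),
         aligned_subject = as.character(Biostrings::alignedSubject(pa)),
         score = BiocGenerics::score(pa),
         substitution_matrix = submat,
         length_ratio = nchar(b) / nchar(a)),
    class = "pairwise_alignment")
  aln$similarity <- percent_similarity(aln)
  aln
}

resolve_submatrix <- function(substitution_matrix) {
  if (is.matrix(substitution_matrix)) return(substitution_matrix)
  get(data(list = substitution_matrix,
           package = "Biostrings", envir = environment()))
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment %s vs %s: score %.1f, similarity %.3f, length ratio %.3f\n",
              x$query_id, x$subject_id, x$score, x$similarity, x$length_ratio))
  invisible(x)
}

#' Fraction of alignment columns with a positively scoring residue pair
#'
#' `similarity = (# columns whose residue pair has a positive substitution
#' score) / (total alignment columns, gap columns included)` — the
#' BLASTP-"positives" sense of percent similarity.
#'
#' @param alignment A `pairwise_alignment` from [global_align].
#' @return Similarity fraction in `[0, 1]`.
#' @export
percent_similarity <- function(alignment) {
  qa <- strsplit(alignment$aligned_query, "")[[1]]
  sa <- strsplit(alignment$aligned_subject, "")[[1]]
  ncol_aln <- length(qa)
  if (ncol_aln == 0L) stop("alignment has no columns")
  res <- qa != "-" & sa != "-"
  if (!any(res)) return(0)
  sub <- alignment$substitution_matrix
  pos <- sum(sub[cbind(qa[res], sa[res])] > 0)
  pos / ncol_aln
}

#' The retention rule: similarity strictly above 0.45, length ratio in
#' \[0.40, 1.50\]
#'
#' @param similarity Similarity fraction of the candidate vs the query.
#' @param length_ratio Candidate length over query length.
#' @param min_similarity Strict lower bound on similarity. Default 0.45.
#' @param ratio_range Inclusive length-ratio bounds. Default `c(0.40, 1.50)`.
#' @return Logical: retained or not.
#' @export
homolog_retained <- function(similarity, length_ratio,
                             min_similarity = 0.45,
                             ratio_range = c(0.40, 1.50)) {
  similarity > min_similarity &
    length_ratio >= ratio_range[1] & length_ratio <= ratio_range[2]
}

#' Filter candidate homologs of a query protein
#'
#' Retains candidates strictly more than 45% similar to the query (see
#' [percent_similarity]) and between 40% and 150% of the query length
#' (inclusive). Candidates failing the length-ratio bound are rejected
#' without alignment.
#'
#' @param query Query amino-acid sequence.
#' @param candidates Named character vector of candidate sequences.
#' @param min_similarity,ratio_range See [homolog_retained].
#' @param ... Passed to [global_align].
#' @return `data.frame(candidate_id, similarity, length_ratio)` of the
#'   retained candidates (similarity `NA` for those rejected on length alone
#'   is never reported — only retained rows are returned).
#' @export
filter_homologs <- function(query, candidates, min_similarity = 0.45,
                            ratio_range = c(0.40, 1.50), ...) {
  if (!nzchar(query)) stop("empty query sequence")
  if (length(candidates) == 0L)
    return(data.frame(candidate_id = character(), similarity = numeric(),
                      length_ratio = numeric()))
  if (is.null(names(candidates)))
    names(candidates) <- paste0("candidate_", seq_along(candidates))
  rows <- lapply(names(candidates), function(id) {
    ratio <- nchar(candidates[[id]]) / nchar(query)
    if (ratio < ratio_range[1] || ratio > ratio_range[2]) return(NULL)
    aln <- global_align(query, candidates[[id]], subject_id = id, ...)
    if (!homolog_retained(aln$similarity, ratio, min_similarity, ratio_range))
      return(NULL)
    data.frame(candidate_id = id, similarity = aln$similarity,
               length_ratio = ratio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(candidate_id = character(), similarity = numeric(),
                      length_ratio = numeric())
  rownames(out) <- NULL
  out
}
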