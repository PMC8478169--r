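#' Build a profile HMM from a multiple alignment
#'
#' Columns whose gap fraction is at most `match_column_max_gap_fraction`
#' become match states. Match emissions are pseudocounted column frequencies,
#' `(count + alpha) / (n_residues + 20 * alpha)`; the background is the
#' overall residue frequency of the alignment with the same pseudocount;
#' transition probabilities are estimated from the observed per-sequence
#' state paths (match/insert/delete relative to the chosen match columns),
#' again with pseudocount `alpha`.
#'
#' @param aligned_sequences Character vector of equal-length aligned amino-acid
#'   sequences (`-` or `.` for gaps).
#' @param alpha Pseudocount, `>= 0`. Default 1.
#' @param match_column_max_gap_fraction Columns with a gap fraction at or below
#'   this become match states. Default 0.5.
#' @param name,accession Passed to [profile_hmm].
#' @param background Optional length-20 background distribution. `NULL`
#'   (default) estimates it from the alignment's residue frequencies with the
#'   same pseudocount; supply a vector (e.g. uniform) when the alignment is
#'   too shallow for residues absent from it to be believed rare.
#' @return A [profile_hmm] (uncalibrated; see [calibrate_model]).
#' @export
build_profile_from_alignment <- function(aligned_sequences, alpha = 1,
                                         match_column_max_gap_fraction = 0.5,
                                         name = "profile", accession = NA_character_,
                                         background = NULL) {
  if (length(aligned_sequences) < 1L) stop("need at least one aligned sequence")
  if (alpha < 0) stop("alpha must be >= 0")
  rows <- lapply(toupper(aligned_sequences), function(s) strsplit(s, "")[[1]])
  w <- length(rows[[1]])
  if (any(vapply(rows, length, 1L) != w))
    stop("ragged alignment: sequences differ in length")
  amat <- do.call(rbind, rows)
  is_gap <- amat == "-" | amat == "."
  bad <- !is_gap & !(amat %in% AA_ALPHABET20)
  if (any(bad))
    stop(sprintf("non-amino-acid character '%s' in alignment", amat[bad][1]))
  nseq <- nrow(amat)
  gap_frac <- colMeans(is_gap)
  match_cols <- which(gap_frac <= match_column_max_gap_fraction)
  L <- length(match_cols)
  if (L == 0L) stop("no match columns survive the gap-fraction threshold (L = 0)")

  # emissions
  count_col <- function(j) {
    res <- amat[!is_gap[, j], j]
    tab <- table(factor(res, levels = AA_ALPHABET20))
    as.numeric(tab)
  }
  me <- t(vapply(match_cols, function(j) {
    cnt <- count_col(j)
    (cnt + alpha) / (sum(cnt) + 20 * alpha)
  }, numeric(20)))
  if (is.null(background)) {
    bg_cnt <- as.numeric(table(factor(amat[!is_gap], levels = AA_ALPHABET20)))
    background <- (bg_cnt + alpha) / (sum(bg_cnt) + 20 * alpha)
  } else {
    background <- as.numeric(background) / sum(background)
  }
  # insert emissions: pooled residues in non-match columns, else background
  ins_cols <- setdiff(seq_len(w), match_cols)
  ins_res <- amat[, ins_cols, drop = FALSE]
  ins_res <- ins_res[!(ins_res == "-" | ins_res == ".")]
  ins_cnt <- as.numeric(table(factor(ins_res, levels = AA_ALPHABET20)))
  ie_row <- (ins_cnt + alpha) / (sum(ins_cnt) + 20 * alpha)
  if (sum(ins_cnt) + 20 * alpha == 0) ie_row <- background
  ie <- matrix(ie_row, L, 20, byrow = TRUE)

  # transition counts from observed state paths
  # states per node k: M_k (residue in match col k), D_k (gap in match col k),
  # I_k (residue in a non-match column between match cols k and k+1)
  cnt <- matrix(0, L, 7)
  colnames(cnt) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  col2node <- integer(w)       # node whose insert-state a non-match column follows
  node <- 0L
  col_is_match <- seq_len(w) %in% match_cols
  node_of_col <- integer(w)
  for (j in seq_len(w)) {
    if (col_is_match[j]) node <- node + 1L
    node_of_col[j] <- node
  }
  for (s in seq_len(nseq)) {
    prev <- NULL  # c(state, node); state in "M","I","D"
    for (j in seq_len(w)) {
      here <- NULL
      if (col_is_match[j]) {
        here <- c(if (is_gap[s, j]) "D" else "M", node_of_col[j])
      } else if (!is_gap[s, j]) {
        here <- c("I", node_of_col[j])
      }
      if (!is.null(here)) {
        if (!is.null(prev)) {
          k <- as.integer(prev[2])
          if (k >= 1L && k <= L) {
            key <- paste0(tolower(prev[1]), tolower(here[1]))
            if (key %in% colnames(cnt)) cnt[k, key] <- cnt[k, key] + 1
          }
        }
        prev <- here
      }
    }
  }
  tr <- matrix(0, L, 7, dimnames = list(NULL, colnames(cnt)))
  norm_group <- function(k, cols) {
    g <- cnt[k, cols] + alpha
    if (sum(g) == 0) g <- rep(1, length(cols))
    tr[k, cols] <<- g / sum(g)
  }
  for (k in seq_len(L)) {
    norm_group(k, c("mm", "mi", "md"))
    norm_group(k, c("im", "ii"))
    norm_group(k, c("dm", "dd"))
  }
  profile_hmm(name = name, accession = accession,
              match_emissions = me, insert_emissions = ie, transitions = tr,
              background = background)
}

#' Calibrate a profile HMM's Gumbel E-value parameters by decoy scoring
#'
#' Scores `n_decoys` random sequences drawn from the model's background
#' distribution and fits the Gumbel location `mu` by the method of moments
#' with the slope `lambda` held fixed: `mu = mean(scores) - gamma / lambda`
#' (`gamma` the Euler-Mascheroni constant). The default `lambda = ln 2`
#' corresponds to one halving of the tail probability per bit.
#'
#' @param model A [profile_hmm].
#' @param n_decoys Number of background decoy sequences. Default 200.
#' @param decoy_length Length of each decoy; default 1.5 times the model length.
#' @param lambda Fixed Gumbel slope (per bit). Default `log(2)`.
#' @param seed Integer seed for the decoy draw. Default 42.
#' @return The model with `$calibration = list(mu, lambda)` set.
#' @export
calibrate_model <- function(model, n_decoys = 200, decoy_length = NULL,
                            lambda = log(2), seed = 42) {
  stopifnot(inherits(model, "profile_hmm"))
  if (is.null(decoy_length)) decoy_length <- ceiling(1.5 * model$length)
  scores <- withr::with_seed(seed, {
    vapply(seq_len(n_decoys), function(i) {
      s <- paste(sample(AA_ALPHABET20, decoy_length, replace = TRUE,
                        prob = model$background), collapse = "")
      viterbi_bitscore(model, s)$bit_score
    }, numeric(1))
  })
  gamma_em <- 0.57721566490153286
  model$calibration <- list(mu = mean(scores) - gamma_em / lambda,
                            lambda = lambda)
  model
}
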