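# Independent oracles and random-instance generators used across the suite.
# These deliberately share no code with the package implementation.

# Exhaustive path-enumeration Viterbi oracle: depth-first over every legal
# local alignment path (enter at any match state, exit at any match state,
# flanks free), scoring emissions as log2(p/bg) and transitions as log2(p).
oracle_viterbi <- function(model, sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  L <- model$length
  n <- length(aa)
  bg <- model$background
  em <- function(k, i) {
    a <- aa[i]
    if (a == "X") 0 else log2(model$match_emissions[k, a] / bg[[a]])
  }
  iem <- function(k, i) {
    a <- aa[i]
    if (a == "X") 0 else log2(model$insert_emissions[k, a] / bg[[a]])
  }
  tr <- log2(model$transitions)
  best <- -Inf
  rec <- function(state, k, i, sc) {
    if (!is.finite(sc)) return(invisible())
    if (state == "M") best <<- max(best, sc)
    if (state == "M") {
      if (k < L && i <= n) rec("M", k + 1, i + 1, sc + tr[k, "mm"] + em(k + 1, i))
      if (i <= n)          rec("I", k,     i + 1, sc + tr[k, "mi"] + iem(k, i))
      if (k < L)           rec("D", k + 1, i,     sc + tr[k, "md"])
    } else if (state == "I") {
      if (k < L && i <= n) rec("M", k + 1, i + 1, sc + tr[k, "im"] + em(k + 1, i))
      if (i <= n)          rec("I", k,     i + 1, sc + tr[k, "ii"] + iem(k, i))
    } else {
      if (k < L && i <= n) rec("M", k + 1, i + 1, sc + tr[k, "dm"] + em(k + 1, i))
      if (k < L)           rec("D", k + 1, i,     sc + tr[k, "dd"])
    }
  }
  for (i in seq_len(n)) {
    for (k in seq_len(L)) rec("M", k, i + 1, em(k, i))
  }
  best
}

# Random profile HMM with Dirichlet-ish emission rows.
random_profile <- function(L, concentrated = FALSE) {
  rdist <- function(n, k) {
    g <- matrix(stats::rgamma(n * k, shape = if (concentrated) 0.3 else 1), n, k)
    g / rowSums(g)
  }
  tr <- cbind(rdist(L, 3), rdist(L, 2), rdist(L, 2))
  colnames(tr) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  profile_hmm(name = "rand", match_emissions = rdist(L, 20),
              insert_emissions = rdist(L, 20), transitions = tr,
              background = as.numeric(rdist(1, 20)))
}

random_aa_seq <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

# Independent affine-gap global alignment score (Gotoh three-matrix DP).
# A gap of length k costs open + k * extend, end gaps included.
oracle_global_score <- function(a, b, submat, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)  # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - extend * i
  for (j in seq_len(m)) Y[1, j + 1] <- -open - extend * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force threshold/dedup/count oracle for the sweep tests: filter hits
# at the cutoff, keep each protein's smallest-e-value row (ties by accession),
# count per category through the catalog.
oracle_category_counts <- function(hits, catalog, threshold) {
  h <- hits[hits$evalue <= threshold, , drop = FALSE]
  counts <- stats::setNames(rep(0L, 4), c("Cue", "Cus", "CopPco", "Multisystem"))
  for (p in unique(h$protein_id)) {
    hp <- h[h$protein_id == p, , drop = FALSE]
    hp <- hp[order(hp$evalue, hp$model_accession), , drop = FALSE]
    cat_p <- catalog$system_category[catalog$model_accession == hp$model_accession[1]]
    counts[cat_p] <- counts[cat_p] + 1L
  }
  counts
}

# Small constructed hit table with known e-values across several proteins
# and models (used by the dedup/tabulation tests).
constructed_hit_table <- function() {
  data.frame(
    protein_id = c("P1", "P1", "P2", "P2", "P3", "P4", "P4", "P5", "P6"),
    model_accession = c("COG2217", "TIGR01480", "TIGR01386", "TIGR01387",
                        "COG3696", "COG2372", "COG1276", "TIGR02044",
                        "COG0845"),
    bit_score = c(150, 120, 90, 88, 70, 55, 54, 40, 33),
    evalue = c(1e-45, 1e-38, 1e-28, 1e-26, 1e-22, 1e-18, 1e-17, 1e-12, 1e-11),
    ali_start = 1L, ali_end = 10L,
    stringsAsFactors = FALSE)
}
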