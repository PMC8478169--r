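# Synthetic-data generators: proteomes with planted homologs among decoys,
# annotated replicons with planted merR-copA clusters and genomic-island
# intervals, and qPCR CT tables with planted log2 fold changes. Every
# generator returns a ground-truth table and is byte-deterministic under a
# fixed seed.

#' Deterministic seed sequences for the catalog model families
#'
#' One random amino-acid sequence per catalog accession, with lengths typical
#' of each protein family (e.g. a short MerR-family regulator for the CueR
#' model, a long P-type ATPase for the Cu(I)-ATPase model, a large RND pump
#' for CusA). These act as the family "founders": profiles are built from
#' them and homologs are planted as mutated copies.
#'
#' @param seed Integer seed; fixed by default so the same families exist
#'   across simulations.
#' @return Named character vector, one sequence per catalog accession.
#' @export
catalog_seed_sequences <- function(seed = 42) {
  lengths <- c(TIGR02044 = 135, TIGR01480 = 516, COG2217 = 834,
               TIGR01386 = 480, TIGR01387 = 227, COG3696 = 1047,
               COG0845 = 407, TIGR01845 = 457, COG5569 = 110,
               COG3667 = 296, COG2372 = 126, COG1276 = 309,
               `PF11106.8` = 144, COG0739 = 170, TIGR00003 = 68,
               TIGR02698 = 145, COG1937 = 103)
  withr::with_seed(seed, {
    vapply(lengths, function(L)
      paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = ""),
      character(1))
  })
}

#' Mutate a protein sequence by point substitutions
#'
#' Each site independently mutates with probability `divergence` to a
#' uniformly chosen different residue (substitution-only, no indels), so the
#' Hamming distance to the input is exactly the number of mutated sites.
#'
#' @param sequence Amino-acid string.
#' @param divergence Per-site substitution probability in `[0, 1)`.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(sequence, divergence) {
  if (divergence < 0 || divergence >= 1)
    stop("divergence must be in [0, 1)")
  chars <- strsplit(sequence, "")[[1]]
  hit <- stats::runif(length(chars)) < divergence
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(AA_ALPHABET20, a), 1), character(1))
  }
  paste(chars, collapse = "")
}

#' Specification for a synthetic proteome
#'
#' Defaults encode the planted-homolog study condition: 100 background decoys
#' of 100-900 residues plus one planted homolog at 10% substitution
#' divergence for each of five catalog families spanning the size range
#' (CueR, Cu(I)-ATPase, CusA, PcoC, CopZ).
#'
#' @param n_decoys Number of background decoy proteins.
#' @param decoy_length_range Inclusive decoy length range.
#' @param planted List of `list(model, n_copies, divergence,
#'   seed_sequence = NULL)`; `seed_sequence` defaults to the catalog founder.
#' @param background Length-20 residue sampling distribution (uniform by
#'   default).
#' @param family_seed Seed for [catalog_seed_sequences].
#' @return A `proteome_spec` list.
#' @export
proteome_spec <- function(n_decoys = 100,
                          decoy_length_range = c(100, 900),
                          planted = default_planted_homologs(),
                          background = rep(1 / 20, 20),
                          family_seed = 42) {
  list(n_decoys = n_decoys, decoy_length_range = decoy_length_range,
       planted = planted, background = background, family_seed = family_seed)
}

#' @rdname proteome_spec
#' @export
default_planted_homologs <- function() {
  lapply(c("TIGR02044", "COG2217", "COG3696", "COG2372", "TIGR00003"),
         function(acc) list(model = acc, n_copies = 1, divergence = 0.1))
}

#' Simulate a proteome with planted homologs among decoys
#'
#' Decoys are sampled from the background residue distribution; planted
#' homologs are substitution-mutated copies of the family seed sequences.
#'
#' @param spec A [proteome_spec].
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return `list(proteome, truth)`: a named character vector of sequences and
#'   a truth table `data.frame(protein_id, origin, source_model, divergence)`.
#' @export
simulate_proteome <- function(spec = proteome_spec(), seed = 42) {
  for (p in spec$planted)
    if (p$divergence < 0 || p$divergence >= 1)
      stop("divergence must be in [0, 1)")
  seeds <- catalog_seed_sequences(spec$family_seed)
  withr::with_seed(seed, {
    decoys <- character(spec$n_decoys)
    if (spec$n_decoys > 0) {
      lens <- sample(seq(spec$decoy_length_range[1], spec$decoy_length_range[2]),
                     spec$n_decoys, replace = TRUE)
      decoys <- vapply(lens, function(L)
        paste(sample(AA_ALPHABET20, L, replace = TRUE, prob = spec$background),
              collapse = ""), character(1))
    }
    names(decoys) <- sprintf("decoy_%03d", seq_len(spec$n_decoys))
    planted <- character(0)
    truth_rows <- list()
    for (p in spec$planted) {
      seedseq <- if (!is.null(p$seed_sequence)) p$seed_sequence
                 else seeds[[p$model]]
      if (is.null(seedseq)) stop("no seed sequence for model ", p$model)
      n_copies <- if (is.null(p$n_copies)) 1L else p$n_copies
      for (ci in seq_len(n_copies)) {
        id <- sprintf("planted_%s_%d", p$model, ci)
        planted[id] <- mutate_sequence(seedseq, p$divergence)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          protein_id = id, origin = "planted", source_model = p$model,
          divergence = p$divergence, stringsAsFactors = FALSE)
      }
    }
    truth <- rbind(
      if (spec$n_decoys > 0)
        data.frame(protein_id = names(decoys), origin = "decoy",
                   source_model = NA_character_, divergence = NA_real_,
                   stringsAsFactors = FALSE),
      if (length(truth_rows)) do.call(rbind, truth_rows))
    list(proteome = c(decoys, planted), truth = truth)
  })
}

#' Build calibrated profile HMMs for catalog families
#'
#' The fixture builder behind the search tests: for each accession, a small
#' alignment of low-divergence variants of the family seed is generated, a
#' profile built from it, and the Gumbel location calibrated from a 200-decoy
#' run with `lambda = ln 2`.
#'
#' @param accessions Catalog accessions to model.
#' @param seed Integer seed.
#' @param n_variants Seed-alignment depth. Default 3.
#' @param variant_divergence Within-family divergence of the alignment.
#'   Default 0.05.
#' @param alpha Pseudocount for profile construction. Default 1.
#' @param n_decoys Calibration decoys. Default 200.
#' @param family_seed Seed for [catalog_seed_sequences].
#' @return Named list of calibrated [profile_hmm] objects.
#' @export
simulate_model_set <- function(accessions, seed = 42, n_variants = 3,
                               variant_divergence = 0.05, alpha = 1,
                               n_decoys = 200, family_seed = 42) {
  seeds <- catalog_seed_sequences(family_seed)
  unknown <- setdiff(accessions, names(seeds))
  if (length(unknown)) stop("unknown accessions: ", paste(unknown, collapse = ", "))
  models <- withr::with_seed(seed, {
    lapply(accessions, function(acc) {
      aln <- c(seeds[[acc]],
               vapply(seq_len(n_variants - 1), function(i)
                 mutate_sequence(seeds[[acc]], variant_divergence), character(1)))
      build_profile_from_alignment(aln, alpha = alpha,
                                   name = paste0("sim_", acc), accession = acc,
                                   background = rep(1 / 20, 20))
    })
  })
  models <- lapply(seq_along(models), function(i)
    calibrate_model(models[[i]], n_decoys = n_decoys,
                    seed = seed + i))
  stats::setNames(models, accessions)
}

#' Write a proteome to FASTA
#'
#' @param proteome Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Annotated replicons with planted clusters

ROLE_PRODUCTS <- c(
  merR = "MerR family transcriptional regulator",
  copA = "copper-translocating P-type ATPase",
  cupredoxin = "cupredoxin domain-containing protein",
  duf2933_hypothetical = "DUF2933 domain-containing protein",
  icmt = "isoprenylcysteine carboxylmethyltransferase")

DECOY_PRODUCTS <- c(
  "ribosomal protein L3", "DNA gyrase subunit B", "elongation factor Tu",
  "ABC transporter permease", "transcription termination factor Rho",
  "outer membrane porin", "alanine--tRNA ligase", "chaperonin GroEL",
  "acyl carrier protein", "phosphofructokinase")

#' Specification for a synthetic annotated genome
#'
#' The default emulates a strain with a chromosome and a mega-plasmid
#' carrying five planted merR-copA clusters: 2 full and 3 partial, some on
#' genomic islands and some plasmid-borne. The plasmid's full cluster sits on
#' an island and uses a bare "hypothetical protein" product for the DUF2933
#' role, exercising the contextual role rule.
#'
#' @param replicons List of replicon specs: `list(id, class, n_genes,
#'   clusters = list(list(roles, after_gene, strand, on_gi,
#'   duf2933_product)))`.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(replicons = NULL) {
  if (is.null(replicons)) {
    full <- c("merR", "copA", "cupredoxin", "duf2933_hypothetical", "icmt")
    replicons <- list(
      list(id = "chromosome_1", class = "chromosome", n_genes = 40,
           clusters = list(
             list(roles = full, after_gene = 5, strand = "+", on_gi = FALSE),
             list(roles = c("copA", "cupredoxin", "duf2933_hypothetical", "icmt"),
                  after_gene = 18, strand = "-", on_gi = TRUE),
             list(roles = c("merR", "copA", "cupredoxin"),
                  after_gene = 30, strand = "+", on_gi = FALSE))),
      list(id = "plasmid_p178", class = "plasmid", n_genes = 25,
           clusters = list(
             list(roles = full, after_gene = 4, strand = "+", on_gi = TRUE,
                  duf2933_product = "hypothetical protein"),
             list(roles = c("merR", "copA", "icmt"),
                  after_gene = 16, strand = "+", on_gi = TRUE))))
  }
  list(replicons = replicons)
}

#' Simulate an annotated genome with planted merR-copA clusters
#'
#' Genes are laid out sequentially (about 900 bp each with short intergenic
#' gaps); cluster genes carry products matching the role keyword rules, all
#' other genes innocuous decoy products. Genomic-island intervals (BED,
#' 0-based half-open) cover the planted on-island clusters plus one decoy
#' island per replicon.
#'
#' @param spec A [genome_spec].
#' @param seed Integer seed.
#' @return List with `sequences` (named character, DNA), `features` (the
#'   gene table of [read_gene_features]), `gi_intervals`, `manifest`
#'   (replicon classes), and `truth` (one row per planted cluster:
#'   completeness, missing roles, on-island flag, class, members).
#' @export
simulate_annotated_genome <- function(spec = genome_spec(), seed = 42) {
  gene_len <- 900L
  gene_gap <- 150L
  pitch <- gene_len + gene_gap
  withr::with_seed(seed, {
    feats <- list(); gis <- list(); truths <- list(); seqs <- character(0)
    for (rp in spec$replicons) {
      n <- rp$n_genes
      # check planted clusters fit and do not overlap
      spans <- lapply(rp$clusters, function(cl)
        seq(cl$after_gene + 1L, cl$after_gene + length(cl$roles)))
      allg <- unlist(spans)
      if (any(allg > n))
        stop(sprintf("replicon %s: planted cluster exceeds gene count", rp$id))
      if (anyDuplicated(allg))
        stop(sprintf("replicon %s: planted clusters overlap", rp$id))
      products <- sample(DECOY_PRODUCTS, n, replace = TRUE)
      roles_truth <- rep("none", n)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      for (cl in rp$clusters) {
        idx <- seq(cl$after_gene + 1L, cl$after_gene + length(cl$roles))
        prods <- ROLE_PRODUCTS[cl$roles]
        if (!is.null(cl$duf2933_product))
          prods[cl$roles == "duf2933_hypothetical"] <- cl$duf2933_product
        products[idx] <- prods
        roles_truth[idx] <- cl$roles
        strands[idx] <- cl$strand
      }
      start <- 101L + (seq_len(n) - 1L) * pitch
      end <- start + gene_len - 1L
      ids <- sprintf("%s_%04d", toupper(rp$id), seq_len(n))
      feats[[rp$id]] <- data.frame(
        feature_id = ids, replicon_id = rp$id, start = start, end = end,
        strand = strands, product = unname(products), stringsAsFactors = FALSE)
      # genomic islands: one per on-island cluster (+/- 50 bp margin) plus a
      # decoy island in the trailing gene-free margin
      for (cl in rp$clusters) {
        if (!isTRUE(cl$on_gi)) next
        idx <- seq(cl$after_gene + 1L, cl$after_gene + length(cl$roles))
        gis[[length(gis) + 1L]] <- data.frame(
          replicon_id = rp$id,
          start = max(0L, start[idx[1]] - 51L),     # BED 0-based
          end = end[idx[length(idx)]] + 50L, stringsAsFactors = FALSE)
      }
      rep_len <- 200L + n * pitch + 5000L
      gis[[length(gis) + 1L]] <- data.frame(
        replicon_id = rp$id, start = rep_len - 3000L, end = rep_len - 1000L,
        stringsAsFactors = FALSE)
      for (cl in rp$clusters) {
        idx <- seq(cl$after_gene + 1L, cl$after_gene + length(cl$roles))
        missing <- setdiff(CLUSTER_ROLES, cl$roles)
        truths[[length(truths) + 1L]] <- data.frame(
          replicon_id = rp$id, replicon_class = rp$class,
          anchor_copA = ids[idx][cl$roles == "copA"][1],
          completeness = if (length(missing)) "partial" else "full",
          missing_roles = paste(missing, collapse = ";"),
          on_genomic_island = isTRUE(cl$on_gi),
          start = start[idx[1]], end = end[idx[length(idx)]],
          members = paste(ids[idx], collapse = ";"), stringsAsFactors = FALSE)
      }
      seqs[rp$id] <- paste(sample(c("A", "C", "G", "T"), rep_len,
                                  replace = TRUE), collapse = "")
    }
    list(sequences = seqs,
         features = do.call(rbind, c(feats, list(make.row.names = FALSE))),
         gi_intervals = do.call(rbind, gis),
         manifest = data.frame(
           replicon_id = vapply(spec$replicons, `[[`, "", "id"),
           class = vapply(spec$replicons, `[[`, "", "class"),
           stringsAsFactors = FALSE),
         truth = do.call(rbind, truths))
  })
}

#' Write a simulated genome as FASTA + GFF3 + BED + manifest
#'
#' @param sim Output of [simulate_annotated_genome].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_genome_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fna")
  gff <- file.path(dir, "genome.gff3")
  bed <- file.path(dir, "islands.bed")
  manifest <- file.path(dir, "replicons.tsv")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$sequences), fasta)
  f <- sim$features
  attr_col <- sprintf("ID=%s;locus_tag=%s;product=%s",
                      f$feature_id, f$feature_id, f$product)
  gff_df <- data.frame(f$replicon_id, "copperscan_sim", "CDS", f$start, f$end,
                       ".", f$strand, "0", attr_col)
  writeLines(c("##gff-version 3",
               apply(gff_df, 1, paste, collapse = "\t")), gff)
  utils::write.table(sim$gi_intervals, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$manifest, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(fasta = fasta, gff = gff, bed = bed, manifest = manifest)
}

# ---------------------------------------------------------------------------
# qPCR CT tables with planted effects

#' Specification for a synthetic CT table
#'
#' Defaults emulate a copper-induction experiment: two plasmid-borne copA
#' variants strongly induced (about 12-fold) at 100 uM and 1 mM with damped
#' induction at 3 mM, a chromosomal copA copy flat-to-repressed, a stable
#' reference gene with a CT standard deviation of half a cycle, three
#' biological replicates, and 0.2 cycles of target-level noise.
#'
#' @param strain Strain label.
#' @param conditions Treated copper concentration labels.
#' @param control Control condition label.
#' @param timepoints Sampling timepoints.
#' @param n_replicates Biological replicates per condition (`>= 2`).
#' @param reference_gene Reference gene name.
#' @param mu_ref,mu_target Mean CT of reference and targets (cycles).
#' @param reference_sd Reference CT standard deviation (cycles).
#' @param noise_sd Target CT noise standard deviation (cycles).
#' @param log2fc `data.frame(gene, condition, log2fc)` of planted effects.
#' @return A `ct_spec` list.
#' @export
ct_spec <- function(strain = "synthetic_strain",
                    conditions = c("100uM", "1mM", "3mM"),
                    control = "control",
                    timepoints = "30min",
                    n_replicates = 3,
                    reference_gene = "pfk",
                    mu_ref = 15, mu_target = 20,
                    reference_sd = 0.5, noise_sd = 0.2,
                    log2fc = NULL) {
  if (is.null(log2fc)) {
    log2fc <- rbind(
      data.frame(gene = "copA_v1", condition = c("100uM", "1mM", "3mM"),
                 log2fc = c(3.6, 3.5, 0.8)),
      data.frame(gene = "copA_v2", condition = c("100uM", "1mM", "3mM"),
                 log2fc = c(2.2, 2.6, 0.9)),
      data.frame(gene = "copA_chr", condition = c("100uM", "1mM", "3mM"),
                 log2fc = c(0, -0.8, 0)))
  }
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (reference_sd < 0 || noise_sd < 0) stop("standard deviations must be >= 0")
  list(strain = strain, conditions = conditions, control = control,
       timepoints = timepoints, n_replicates = n_replicates,
       reference_gene = reference_gene, mu_ref = mu_ref,
       mu_target = mu_target, reference_sd = reference_sd,
       noise_sd = noise_sd, log2fc = log2fc)
}

#' Simulate a qPCR CT table with planted log2 fold changes
#'
#' Reference CT is drawn `Normal(mu_ref, reference_sd)` per condition and
#' replicate; target CT in condition `c` is
#' `mu_target - log2fc(c) + Normal(0, noise_sd)` (control has `log2fc = 0`),
#' so delta-delta-CT analysis recovers the planted effect.
#'
#' @param spec A [ct_spec].
#' @param seed Integer seed.
#' @return `list(records, truth)`: CT records in the [read_ct_table] layout
#'   and the planted-effect table.
#' @export
simulate_ct_table <- function(spec = ct_spec(), seed = 42) {
  if (spec$reference_sd < 0 || spec$noise_sd < 0)
    stop("standard deviations must be >= 0")
  genes <- unique(spec$log2fc$gene)
  conds <- c(spec$control, spec$conditions)
  withr::with_seed(seed, {
    rows <- list()
    for (tp in spec$timepoints) {
      for (cond in conds) {
        for (r in seq_len(spec$n_replicates)) {
          ref_ct <- stats::rnorm(1, spec$mu_ref, spec$reference_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            strain = spec$strain, gene = spec$reference_gene,
            condition = cond, timepoint = tp, replicate = r, ct = ref_ct,
            stringsAsFactors = FALSE)
          for (g in genes) {
            fc <- 0
            if (cond != spec$control) {
              m <- spec$log2fc$gene == g & spec$log2fc$condition == cond
              fc <- if (any(m)) spec$log2fc$log2fc[m][1] else 0
            }
            rows[[length(rows) + 1L]] <- data.frame(
              strain = spec$strain, gene = g, condition = cond,
              timepoint = tp, replicate = r,
              ct = spec$mu_target - fc + stats::rnorm(1, 0, spec$noise_sd),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    list(records = do.call(rbind, rows), truth = spec$log2fc)
  })
}

#' Write a CT table as CSV
#'
#' @param records CT records.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
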