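# Role assignment, core-cluster detection, and genomic-island annotation.

feature_row <- function(id, start, product, replicon = "rep1", strand = "+") {
  data.frame(feature_id = id, replicon_id = replicon, start = start,
             end = start + 899L, strand = strand, product = product,
             stringsAsFactors = FALSE)
}

five_gene_cluster <- function(first_start = 1000L, replicon = "rep1",
                              products = c("MerR family transcriptional regulator",
                                           "copper-translocating P-type ATPase",
                                           "cupredoxin domain-containing protein",
                                           "DUF2933 domain-containing protein",
                                           "isoprenylcysteine carboxylmethyltransferase")) {
  do.call(rbind, lapply(seq_along(products), function(i)
    feature_row(sprintf("g%02d", i), first_start + (i - 1L) * 1050L,
                products[i], replicon)))
}

test_that("products map to their roles; unrelated products map to none", {
  f <- rbind(feature_row("a", 100, "copper-translocating P-type ATPase"),
             feature_row("b", 1200, "protein containing plastocyanin domain"),
             feature_row("c", 2400, "ribosomal protein L3"),
             feature_row("d", 3600, "cation transport ATPase"))
  r <- assign_roles(f)
  expect_equal(r$role, c("copA", "cupredoxin", "none", "copA"))
})

test_that("a bare hypothetical protein gets the DUF2933 role only between cupredoxin and icmt", {
  prods <- c("MerR family transcriptional regulator",
             "copper-translocating P-type ATPase",
             "cupredoxin domain-containing protein",
             "hypothetical protein",
             "isoprenylcysteine carboxylmethyltransferase")
  r <- assign_roles(five_gene_cluster(products = prods))
  expect_equal(r$role[4], "duf2933_hypothetical")
  # the same product elsewhere stays role-less
  lone <- rbind(feature_row("x", 100, "ribosomal protein L3"),
                feature_row("y", 1200, "hypothetical protein"),
                feature_row("z", 2400, "DNA gyrase subunit B"))
  expect_equal(assign_roles(lone)$role[2], "none")
})

test_that("ambiguous role rules are an error", {
  rules <- default_role_rules()
  rules$merR <- c(rules$merR, "atpase")  # collides with copA
  f <- feature_row("a", 100, "copper-translocating P-type ATPase")
  expect_error(assign_roles(f, rules), "ambiguous")
})

test_that("a contiguous five-role run is one full cluster", {
  f <- assign_roles(five_gene_cluster())
  calls <- detect_core_clusters(f)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$completeness, "full")
  expect_equal(calls$anchor_copA, "g02")
  expect_equal(calls$missing_roles[[1]], character(0))
  expect_equal(calls$members[[1]]$feature_id, sprintf("g%02d", 1:5))
})

test_that("a four-role run without merR is a partial cluster missing merR", {
  prods <- c("copper-translocating P-type ATPase",
             "cupredoxin domain-containing protein",
             "DUF2933 domain-containing protein",
             "isoprenylcysteine carboxylmethyltransferase")
  f <- assign_roles(do.call(rbind, lapply(seq_along(prods), function(i)
    feature_row(sprintf("p%02d", i), 1000 + (i - 1) * 1050, prods[i]))))
  calls <- detect_core_clusters(f)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$completeness, "partial")
  expect_equal(calls$missing_roles[[1]], "merR")
})

test_that("more than max_intervening role-less genes break the run", {
  f <- rbind(
    feature_row("m", 1000, "MerR family transcriptional regulator"),
    feature_row("x1", 2050, "ribosomal protein L3"),
    feature_row("x2", 3100, "DNA gyrase subunit B"),
    feature_row("x3", 4150, "elongation factor Tu"),
    feature_row("c", 5200, "copper-translocating P-type ATPase"))
  calls <- detect_core_clusters(assign_roles(f), max_intervening = 1)
  expect_equal(nrow(calls), 0)  # copA-only run fails min_roles
  # with one intervening gene the pair reconnects (still below min_roles = 3)
  f2 <- rbind(
    feature_row("m", 1000, "MerR family transcriptional regulator"),
    feature_row("x1", 2050, "ribosomal protein L3"),
    feature_row("c", 3100, "copper-translocating P-type ATPase"),
    feature_row("cu", 4150, "cupredoxin domain-containing protein"))
  calls2 <- detect_core_clusters(assign_roles(f2), max_intervening = 1)
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$n_roles, 3)
})

test_that("unsorted input and multi-replicon input are rejected", {
  f <- assign_roles(five_gene_cluster())
  expect_error(detect_core_clusters(f[rev(seq_len(nrow(f))), ]), "sorted")
  f2 <- assign_roles(rbind(five_gene_cluster(),
                           feature_row("other", 100, "ribosomal protein L3",
                                       replicon = "rep2")))
  expect_error(detect_core_clusters(f2), "one replicon")
})

test_that("cluster calls are invariant under whole-replicon translation", {
  f1 <- assign_roles(five_gene_cluster(first_start = 1000L))
  f2 <- assign_roles(five_gene_cluster(first_start = 250000L))
  c1 <- detect_core_clusters(f1)
  c2 <- detect_core_clusters(f2)
  expect_equal(c1$completeness, c2$completeness)
  expect_equal(c2$start - c1$start, 249000L)
  expect_equal(c1$members[[1]]$feature_id, c2$members[[1]]$feature_id)
})

test_that("genomic-island overlap requires every member midpoint inside an island", {
  f <- assign_roles(five_gene_cluster())
  calls <- detect_core_clusters(f)
  manifest <- data.frame(replicon_id = "rep1", class = "plasmid")
  # island covering the whole cluster
  gi_all <- data.frame(replicon_id = "rep1", start = 900L, end = 6000L)
  a <- annotate_gi_overlap(calls, gi_all, manifest)
  expect_true(a$on_genomic_island)
  expect_equal(a$replicon_class, "plasmid")
  # island covering only 4 of 5 members -> FALSE under the strict rule
  gi4 <- data.frame(replicon_id = "rep1", start = 900L,
                    end = f$start[5] - 10L)
  expect_false(annotate_gi_overlap(calls, gi4, manifest)$on_genomic_island)
  # ... but TRUE in the lenient any-overlap mode
  expect_true(annotate_gi_overlap(calls, gi4, manifest,
                                  mode = "any_overlap")$on_genomic_island)
  # empty interval set -> FALSE
  expect_false(annotate_gi_overlap(calls, gi_all[0, ], manifest)$on_genomic_island)
  # intervals on unknown replicons warn and are ignored
  gi_bad <- rbind(gi_all, data.frame(replicon_id = "nope", start = 0L, end = 10L))
  expect_warning(annotate_gi_overlap(calls, gi_bad, manifest), "unknown replicon")
})

test_that("generated genomes round trip through the GFF3/BED readers and the detector", {
  sim <- simulate_annotated_genome(genome_spec(), seed = 81)
  dir <- withr::local_tempdir()
  paths <- write_genome_fixture(sim, dir)
  feats <- read_gene_features(paths["gff"])
  expect_equal(nrow(feats), nrow(sim$features))
  expect_setequal(feats$feature_id, sim$features$feature_id)
  gi <- read_gi_intervals(paths["bed"])
  expect_equal(nrow(gi), nrow(sim$gi_intervals))
  expect_equal(gi$start, sim$gi_intervals$start)  # BED stays 0-based
  mf <- read_replicon_manifest(paths["manifest"])
  calls <- annotate_gi_overlap(
    detect_core_clusters_all(assign_roles(feats)), gi, mf)
  truth <- sim$truth[order(sim$truth$replicon_id, sim$truth$start), ]
  calls <- calls[order(calls$replicon_id, calls$start), ]
  expect_equal(nrow(calls), nrow(truth))
  expect_equal(calls$completeness, truth$completeness)
  expect_equal(calls$anchor_copA, truth$anchor_copA)
  expect_equal(calls$on_genomic_island, truth$on_genomic_island)
  expect_equal(calls$replicon_class, truth$replicon_class)
})
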