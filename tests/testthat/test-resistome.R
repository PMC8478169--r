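# Duplicate-hit resolution, tabulation, and E-value sweeps.

test_that("a protein hit by two models keeps only the smallest-e-value row", {
  h <- data.frame(protein_id = c("P1", "P1"),
                  model_accession = c("COG2217", "TIGR01480"),
                  evalue = c(1e-45, 1e-38))
  d <- deduplicate_hits(h)
  expect_equal(nrow(d), 1)
  expect_equal(d$model_accession, "COG2217")
})

test_that("single-hit tables pass through unchanged and ties break lexicographically", {
  h1 <- data.frame(protein_id = "P1", model_accession = "COG2217", evalue = 1e-40)
  expect_equal(deduplicate_hits(h1), h1)
  h2 <- data.frame(protein_id = c("P1", "P1"),
                   model_accession = c("B_MODEL", "A_MODEL"),
                   evalue = c(1e-40, 1e-40))
  expect_equal(deduplicate_hits(h2)$model_accession, "A_MODEL")
})

test_that("the default catalog has 17 unique accessions in the four categories", {
  cat <- default_model_catalog()
  expect_equal(nrow(cat), 17)
  expect_equal(anyDuplicated(cat$model_accession), 0)
  expect_setequal(unique(cat$system_category),
                  c("Cue", "Cus", "CopPco", "Multisystem"))
  # the sensor-kinase model spans CusS/PcoS/CopS and is Multisystem
  expect_equal(cat$system_category[cat$model_accession == "TIGR01386"],
               "Multisystem")
})

test_that("tabulation groups by catalog category and reports zero categories", {
  h <- data.frame(protein_id = c("P1", "P2", "P3", "P4"),
                  model_accession = c("TIGR01386", "COG2217", "COG2217", "COG2217"),
                  evalue = c(1e-40, 1e-35, 1e-33, 1e-31))
  tab <- tabulate_hits(h, species_label = "strainA")
  expect_equal(sum(tab$n_hits), 4)
  expect_equal(tab$n_hits[tab$model_accession == "TIGR01386"], 1L)
  expect_equal(tab$n_hits[tab$model_accession == "COG2217"], 3L)
  tot <- category_totals(tab)
  expect_equal(tot$n_hits[tot$system_category == "Multisystem"], 1L)
  expect_equal(tot$n_hits[tot$system_category == "Cue"], 3L)
  expect_equal(tot$n_hits[tot$system_category == "Cus"], 0L)
  expect_equal(nrow(tot), 4)
})

test_that("an accession missing from the catalog is a named error", {
  h <- data.frame(protein_id = "P1", model_accession = "PF99999", evalue = 1e-40)
  expect_error(tabulate_hits(h), "PF99999")
})

test_that("empty hit tables tabulate to all-zero counts", {
  tab <- tabulate_hits(constructed_hit_table()[0, ], species_label = "s")
  expect_equal(sum(tab$n_hits), 0)
  expect_equal(nrow(tab), 17)
})

test_that("tabulation is invariant to input row order", {
  h <- constructed_hit_table()
  withr::with_seed(61, {
    perm <- sample(nrow(h))
  })
  t1 <- tabulate_hits(deduplicate_hits(h), species_label = "s")
  t2 <- tabulate_hits(deduplicate_hits(h[perm, ]), species_label = "s")
  expect_equal(t1, t2, ignore_attr = TRUE)
})

test_that("after dedup the category counts sum to the number of distinct proteins", {
  h <- constructed_hit_table()
  d <- deduplicate_hits(h)
  tab <- tabulate_hits(d, species_label = "s")
  expect_equal(sum(tab$n_hits), length(unique(h$protein_id)))
})

test_that("the sweep matches a brute-force filter-dedup-count oracle per threshold", {
  h <- constructed_hit_table()
  cat <- default_model_catalog()
  thresholds <- c(1e-30, 1e-25, 1e-20, 1e-15, 1e-10)
  sw <- evalue_sweep(h, cat, thresholds, species_label = "s")
  for (t in thresholds) {
    want <- oracle_category_counts(h, cat, t)
    got <- sw$by_category[sw$by_category$threshold == t, ]
    for (cc in names(want))
      expect_equal(got$n_hits[got$system_category == cc], unname(want[cc]),
                   info = sprintf("category %s at threshold %g", cc, t))
  }
})

test_that("distinct hit proteins are non-decreasing as the threshold loosens", {
  h <- constructed_hit_table()
  sw <- evalue_sweep(h, thresholds = 10^seq(-30, -10, by = 5),
                     species_label = "s")
  expect_true(all(diff(sw$n_proteins$n_proteins) >= 0))
})

test_that("a single-threshold sweep equals tabulate(dedup(filter))", {
  h <- constructed_hit_table()
  sw <- evalue_sweep(h, thresholds = 1e-20, species_label = "s")
  direct <- tabulate_hits(deduplicate_hits(h[h$evalue <= 1e-20, ]),
                          species_label = "s")
  expect_equal(sw$by_model$n_hits, direct$n_hits)
  # a threshold below every hit gives an all-zero row
  sw0 <- evalue_sweep(h, thresholds = 1e-60, species_label = "s")
  expect_equal(sum(sw0$by_model$n_hits), 0)
  expect_error(evalue_sweep(h, thresholds = numeric(0)), "empty threshold")
})

test_that("the default catalog round-trips through its config serialization", {
  cat <- default_model_catalog()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_catalog(cat, path)
  expect_equal(read_model_catalog(path), cat)
})
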