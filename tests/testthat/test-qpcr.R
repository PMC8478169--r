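# Reference stability, delta-delta-CT, and the normality-gated test.

ct_rows <- function(gene, condition, cts, replicate = seq_along(cts),
                    strain = "S", timepoint = "30min") {
  data.frame(strain = strain, gene = gene, condition = condition,
             timepoint = timepoint, replicate = replicate, ct = cts,
             stringsAsFactors = FALSE)
}

test_that("reference stability is the sample SD with a strict 1-cycle bound", {
  rec <- ct_rows("pfk", "control", c(15, 15, 15))
  s <- reference_stability(rec, "pfk")
  expect_equal(s$sd, 0)
  expect_true(s$stable)
  # CT {15,16,17}: sample SD exactly 1 -> not stable under the strict bound
  s2 <- reference_stability(ct_rows("pfk", "control", c(15, 16, 17)), "pfk")
  expect_equal(s2$sd, 1)
  expect_false(s2$stable)
  # the reported reference-gene SDs of the motivating assay are all stable
  for (sd_val in c(0.6, 0.44, 0.52)) expect_true(sd_val < 1)
  expect_error(reference_stability(ct_rows("pfk", "control", 15), "pfk"),
               "at least 2")
})

test_that("the closed-form delta-delta-CT example gives fold 8", {
  rec <- rbind(ct_rows("tgt", "control", c(20, 20, 20)),
               ct_rows("pfk", "control", c(15, 15, 15)),
               ct_rows("tgt", "treated", c(17, 17, 17)),
               ct_rows("pfk", "treated", c(15, 15, 15)))
  r <- suppressWarnings(
    delta_delta_ct(rec, "tgt", "pfk", "treated", "control",
                   check_reference = FALSE))
  expect_equal(r$ddct, -3)
  expect_equal(r$fold_change, 8)
  expect_equal(r$log2_fold_change, 3)
})

test_that("treated identical to control gives ddCT 0 and fold 1", {
  rec <- rbind(ct_rows("tgt", "control", c(20.1, 19.9, 20.0)),
               ct_rows("pfk", "control", c(15, 15.1, 14.9)),
               ct_rows("tgt", "treated", c(20.1, 19.9, 20.0)),
               ct_rows("pfk", "treated", c(15, 15.1, 14.9)))
  r <- delta_delta_ct(rec, "tgt", "pfk", "treated", "control")
  expect_equal(r$ddct, 0)
  expect_equal(r$fold_change, 1)
})

test_that("fold change and ddCT satisfy the algebraic identity and swap antisymmetry", {
  sim <- simulate_ct_table(ct_spec(), seed = 91)
  for (g in unique(sim$truth$gene)) {
    r <- delta_delta_ct(sim$records, g, "pfk", "1mM", "control")
    expect_equal(r$fold_change * 2^(r$ddct), 1)
    r_swap <- delta_delta_ct(sim$records, g, "pfk", "control", "1mM")
    expect_equal(r_swap$ddct, -r$ddct)
  }
})

test_that("a missing reference CT names the offending replicate", {
  rec <- rbind(ct_rows("tgt", "control", c(20, 20, 20)),
               ct_rows("pfk", "control", c(15, 15), replicate = c(1, 2)),
               ct_rows("tgt", "treated", c(17, 17, 17)),
               ct_rows("pfk", "treated", c(15, 15, 15)))
  expect_error(
    delta_delta_ct(rec, "tgt", "pfk", "treated", check_reference = FALSE),
    "replicate 3")
})

test_that("an unstable reference gene is refused", {
  rec <- rbind(ct_rows("tgt", "control", c(20, 20, 20)),
               ct_rows("pfk", "control", c(12, 15, 18)),
               ct_rows("tgt", "treated", c(17, 17, 17)),
               ct_rows("pfk", "treated", c(12, 15, 18)))
  expect_error(delta_delta_ct(rec, "tgt", "pfk", "treated"), "not stable")
})

test_that("normal-looking groups are tested by Welch t, skewed groups by Mann-Whitney", {
  withr::with_seed(92, {
    a <- rnorm(8, 0, 1)
    b <- rnorm(8, 1.5, 1)
  })
  # verify the gate premise with the stats oracle, then the branch
  expect_gte(shapiro.test(a)$p.value, 0.05)
  expect_gte(shapiro.test(b)$p.value, 0.05)
  r <- expression_test(a, b)
  expect_equal(r$test_used, "t_test")
  withr::with_seed(93, {
    skew <- exp(rnorm(12, 0, 2))
    while (shapiro.test(skew)$p.value >= 0.05) skew <- exp(rnorm(12, 0, 2))
  })
  r2 <- expression_test(skew, a)
  expect_equal(r2$test_used, "mann_whitney")
})

test_that("identical groups are never significant and small groups fall back with a warning", {
  x <- c(1.0, 1.2, 0.9, 1.1)
  r <- expression_test(x, x)
  expect_gt(r$p_value, 0.9)
  expect_false(r$significant)
  expect_warning(r2 <- expression_test(c(1, 2), c(3, 4)), "smaller than 3")
  expect_equal(r2$test_used, "mann_whitney")
  expect_error(expression_test(numeric(0), x), "empty group")
})

test_that("planted effects are recovered within a half cycle at realistic noise", {
  spec <- ct_spec(log2fc = data.frame(gene = "g1", condition = "100uM",
                                      log2fc = 3.0),
                  conditions = "100uM", noise_sd = 0.2, reference_sd = 0.1)
  sim <- simulate_ct_table(spec, seed = 94)
  r <- delta_delta_ct(sim$records, "g1", "pfk", "100uM", "control")
  expect_lt(abs(r$log2_fold_change - 3.0), 0.5)
})

test_that("analyze_expression runs the grid and BH adjustment is available", {
  sim <- simulate_ct_table(ct_spec(), seed = 95)
  res <- analyze_expression(sim$records, unique(sim$truth$gene), "pfk")
  expect_equal(nrow(res), length(unique(sim$truth$gene)) * 3)
  expect_true(all(res$test_used %in% c("t_test", "mann_whitney")))
  res_bh <- analyze_expression(sim$records, unique(sim$truth$gene), "pfk",
                               p_adjust = "BH")
  expect_true(all(res_bh$p_adjusted >= res_bh$p_value - 1e-12))
})

test_that("CT tables round trip through CSV", {
  sim <- simulate_ct_table(ct_spec(), seed = 96)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(sim$records, path)
  got <- read_ct_table(path)
  expect_equal(got$ct, sim$records$ct)
  expect_error(read_ct_table({
    p <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(x = 1), p, row.names = FALSE)
    p
  }), "needs columns")
})
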