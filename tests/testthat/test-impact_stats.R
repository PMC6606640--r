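test_that("Fisher's exact test matches hand-enumerable tables", {
  # margins (3,3)/(3,3): four tables with probs (1,9,9,1)/20; the observed
  # diagonal table has point prob 1/20, so the two-sided tail is 2/20
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))$p_value, 0.1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2x2")
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(0, 3, 0, 4), 2))$p_value,
                 "degenerate")
  expect_equal(p0, 1)
})

test_that("Fisher p-values agree with stats::fisher.test on random tables", {
  set.seed(2024)
  for (i in 1:200) {
    m <- matrix(rpois(4, sample(c(2, 8, 25), 1)), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_2x2(m)$p_value,
                 fisher.test(m)$p.value, tolerance = 1e-10)
  }
})

test_that("Fisher p-values equal exhaustive enumeration and obey symmetry", {
  set.seed(99)
  for (i in 1:150) {
    m <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    p <- fisher_exact_2x2(m)$p_value
    expect_equal(p, fisher_oracle(m), tolerance = 1e-12)
    # invariance under swapping rows and under swapping columns
    expect_equal(fisher_exact_2x2(m[2:1, ])$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(m[, 2:1])$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(t(m))$p_value, p, tolerance = 1e-12)
  }
})

test_that("Mood's median test handles identical, separated and tied samples", {
  x <- c(1, 2, 3, 4, 5)
  same <- moods_median_test(x, x)
  expect_equal(same$p_value, 1)

  sep <- moods_median_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$p_value, 0.1)  # 2x2 is [[0,3],[3,0]], see Fisher case
  expect_equal(sep$medians, c(2, 11))

  expect_warning(tied <- moods_median_test(rep(4, 5), rep(4, 7)),
                 "grand median")
  expect_equal(tied$p_value, 1)

  expect_error(moods_median_test(numeric(0), x), "at least one")
})

test_that("Mood's median test is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(40); y <- rnorm(35, 0.8)
  p0 <- moods_median_test(x, y)$p_value
  expect_equal(moods_median_test(exp(x), exp(y))$p_value, p0)
  expect_equal(moods_median_test(x^3, y^3)$p_value, p0)
  expect_equal(moods_median_test(qnorm(pnorm(x)), qnorm(pnorm(y)))$p_value,
               p0)
  p_chi <- moods_median_test(x, y, backend = "chisq")$p_value
  expect_equal(moods_median_test(2 * x + 1, 2 * y + 1,
                                 backend = "chisq")$p_value, p_chi)
})

test_that("Mood's exact p agrees with a permutation oracle on a large shift", {
  set.seed(31)
  x <- rnorm(400); y <- rnorm(400, 1.5)
  res <- moods_median_test(x, y)
  expect_lt(res$p_value, 1e-10)
  expect_lt(res$medians[1], res$medians[2])

  # moderate shift where Monte-Carlo comparison is informative
  set.seed(32)
  x <- rnorm(60); y <- rnorm(60, 0.45)
  res <- moods_median_test(x, y)
  grand <- median(c(x, y))
  above <- c(x, y) > grand
  nx <- length(x)
  n_perm <- 1e4
  obs <- dhyper(sum(x > grand), sum(above), sum(!above), nx)
  perm <- replicate(n_perm, {
    k <- sum(sample(above, nx))
    dhyper(k, sum(above), sum(!above), nx)
  })
  p_perm <- mean(perm <= obs * (1 + 1e-7))
  mc_err <- 4 * sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(res$p_value - p_perm), mc_err + 1e-6)
})

test_that("impact tables join properties and compute blosum/entropy", {
  aln <- toy_fviii_alignment()
  calls <- suppressMessages(
    classify_dataset(toy_fviii_variants(), list(F8 = aln)))
  props <- data.frame(gene = "F8", wt = "L", pos = 3L, mut = "V",
                      ddg = 1.2, rsa = 30, stringsAsFactors = FALSE)
  rec <- suppressMessages(build_impact_table(calls, props, list(F8 = aln)))
  i <- which(rec$pos == 3)
  expect_equal(rec$ddg[i], 1.2)
  expect_equal(rec$rsa[i], 30)
  expect_equal(rec$blosum[i], blosum62("L", "V"))
  expect_equal(rec$entropy[i],
               shannon_entropy(column_profile(aln, rec$column[i])))
  # calls absent from the property table keep NA ddg/rsa
  expect_true(all(is.na(rec$ddg[-i])))

  dup <- rbind(props, props)
  expect_error(suppressMessages(build_impact_table(calls, dup, list(F8 = aln))),
               "duplicate")
  empty <- calls[0, ]
  expect_equal(nrow(build_impact_table(empty, props, list(F8 = aln))), 0L)
})

test_that("group comparisons detect planted shifts in the right direction", {
  cfg <- simulation_config(seed = 21L, n_species = 12L, seq_length = 1200L,
                           n_variants = 970L, cpd_fraction = 120 / 970)
  sim <- gen_msa(cfg)
  tabs <- gen_variant_and_property_tables(cfg, sim$truth)
  calls <- suppressMessages(
    classify_dataset(tabs$variants, list(F8 = sim$aln)))
  rec <- build_impact_table(calls, tabs$props, list(F8 = sim$aln))
  res <- compare_cpd_vs_nocpd(rec, "ddg")
  expect_lt(res$p_value, 0.001)
  expect_lt(res$medians[1], res$medians[2])  # CPDs milder

  sev <- compare_mild_vs_severe(rec, "ddg")
  expect_lt(sev$p_value, 0.05)
  expect_lt(sev$medians[1], sev$medians[2])  # severe CPDs more destabilizing
})

test_that("comparisons error out when a group lacks usable values", {
  rec <- data.frame(gene = "F8", wt = "L", pos = 1:6, mut = "V",
                    severity = c("mild", "mild", "mild", "severe",
                                 "severe", "severe"),
                    is_cpd = c(TRUE, rep(FALSE, 5)),
                    ddg = rnorm(6), stringsAsFactors = FALSE)
  rec$rsa <- NA_real_
  expect_error(compare_cpd_vs_nocpd(rec, "ddg"), "insufficient")
  expect_error(compare_cpd_vs_nocpd(rec, "rsa"), "insufficient")
  all_mild <- transform(rec, is_cpd = TRUE, severity = "mild")
  expect_error(compare_mild_vs_severe(all_mild, "ddg"), "insufficient")
})

test_that("overlap_fraction counts values below the reference median", {
  expect_equal(overlap_fraction(5, c(1, 2, 3, 10)), 75)
  set.seed(8)
  z <- rnorm(4000)
  expect_lt(abs(overlap_fraction(z, z) - 50), 3)
  # analytic check: median(a) = 1 exactly, so fraction of b below it is
  # the standard normal CDF at 1
  a <- c(0, 1, 2)
  b <- rnorm(20000)
  expect_lt(abs(overlap_fraction(a, b) - 100 * pnorm(1)), 2)
  expect_error(overlap_fraction(numeric(0), 1), "non-empty")
})

test_that("the comparison battery reports one row per feasible contrast", {
  cfg <- small_sim_config(seed = 23L, n_variants = 120L)
  sim <- gen_msa(cfg)
  tabs <- gen_variant_and_property_tables(cfg, sim$truth)
  calls <- suppressMessages(
    classify_dataset(tabs$variants, list(F8 = sim$aln)))
  rec <- build_impact_table(calls, tabs$props, list(F8 = sim$aln))
  out <- impact_comparison_table(rec)
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  expect_true(all(out$property %in% c("ddg", "rsa", "blosum", "entropy")))
  expect_true(all(out$comparison %in% c("cpd_vs_nocpd", "mild_vs_severe")))
  expect_equal(sum(out$comparison == "cpd_vs_nocpd"), 4L)
})
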