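test_that("enumeration yields exactly the consistent assignment vectors", {
  a <- enumerate_assignments(randomization_scheme(1, 1))
  expect_equal(nrow(a), 2L)
  expect_setequal(apply(a, 1, paste, collapse = ""), c("TC", "CT"))

  a2 <- enumerate_assignments(randomization_scheme(3, 3))
  expect_equal(nrow(a2), choose(6, 3))
  expect_true(all(rowSums(a2 == "T") == 3))
  expect_equal(anyDuplicated(apply(a2, 1, paste, collapse = "")), 0L)

  a3 <- enumerate_assignments(randomization_scheme(0, 3))
  expect_equal(nrow(a3), 1L)
  expect_true(all(a3 == "C"))

  # stratified: per-stratum counts preserved in every vector
  sch <- randomization_scheme(c(1, 2), c(2, 1))
  a4 <- enumerate_assignments(sch)
  expect_equal(nrow(a4), choose(3, 1) * choose(3, 2))
  expect_true(all(rowSums(a4[, 1:3] == "T") == 1))
  expect_true(all(rowSums(a4[, 4:6] == "T") == 2))

  expect_error(enumerate_assignments(randomization_scheme(15, 15)),
               "monte_carlo")
})

test_that("exact permutation p-values match direct enumeration oracles", {
  y <- c(1, 1, 1, 0, 0, 0)
  z <- c("C", "C", "C", "T", "T", "T")
  r <- permutation_pvalue(y, z, "diff_props")
  expect_equal(r$p_value, 0.05)
  expect_equal(r$n_permutations, 20L)
  expect_true(r$p_value %in% r$attainable_p)
  expect_equal(r$p_value, oracle_perm_p(y, z, diff_props))

  expect_warning(rc <- permutation_pvalue(rep(2, 6), z, "diff_means"),
                 NA)  # constant y is not degenerate, just ties everywhere
  expect_equal(rc$p_value, 1)

  for (seed in 1:10) {
    yy <- with_seed_for_test(seed, stats::rnorm(7))
    zz <- with_seed_for_test(seed + 50, sample(rep(c("T", "C"), c(3, 4))))
    for (nm in c("diff_means", "wilcoxon")) {
      expect_equal(permutation_pvalue(yy, zz, nm)$p_value,
                   oracle_perm_p(yy, zz, function(y, z)
                     get_statistic(nm)$evaluate(y, z)))
    }
  }
})

test_that("permutation p with diff_props equals the one-sided Fisher tail", {
  for (seed in 1:15) {
    n_T <- with_seed_for_test(seed, sample(1:5, 1))
    n_C <- with_seed_for_test(seed + 1, sample(1:5, 1))
    y <- with_seed_for_test(seed + 2, stats::rbinom(n_T + n_C, 1, 0.5))
    z <- rep(c("T", "C"), c(n_T, n_C))
    tab <- rbind(c(sum(y[z == "T"]), n_T - sum(y[z == "T"])),
                 c(sum(y[z == "C"]), n_C - sum(y[z == "C"])))
    p_perm <- permutation_pvalue(y, z, "diff_props")$p_value
    expect_equal(p_perm, fisher_exact_one_sided(tab))
    # independent oracle: stats::fisher.test
    expect_equal(p_perm, stats::fisher.test(tab, alternative = "less")$p.value,
                 tolerance = 1e-12)
  }
})

test_that("fisher_exact_one_sided handles worked tables and empty margins", {
  expect_equal(fisher_exact_one_sided(rbind(c(0, 3), c(3, 0))), 0.05)
  expect_equal(fisher_exact_one_sided(rbind(c(3, 0), c(3, 0))), 1)
  expect_equal(fisher_exact_one_sided(rbind(c(0, 3), c(1, 2))), 0.5)
  expect_equal(fisher_exact_one_sided(rbind(c(0, 0), c(2, 1))), 1)
  expect_equal(fisher_exact_one_sided(rbind(c(2, 1), c(0, 3)), "more_T"),
               stats::fisher.test(rbind(c(2, 1), c(0, 3)),
                                  alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("stratified test restricts to per-stratum-count-preserving vectors", {
  # the degenerate two-stage design: one consistent vector, p = 1
  y <- c(1, 1, 1, 0, 0, 0)
  z <- c("C", "C", "C", "T", "T", "T")
  r <- stratified_permutation_pvalue(y, z, c(1, 1, 1, 2, 2, 2), "diff_props")
  expect_equal(r$n_permutations, 1L)
  expect_equal(r$p_value, 1)

  # single stratum reduces exactly to the plain engine
  for (seed in 1:5) {
    yy <- with_seed_for_test(seed, stats::rnorm(6))
    zz <- rep(c("T", "C"), 3)
    expect_identical(
      stratified_permutation_pvalue(yy, zz, rep(1, 6), "diff_means")$p_value,
      permutation_pvalue(yy, zz, "diff_means")$p_value)
  }

  # two strata each (1,1): 4 vectors; p = k/4 on injective outcomes
  y4 <- c(3.2, 1.1, 7.5, 0.4)
  z4 <- c("T", "C", "T", "C")
  r4 <- stratified_permutation_pvalue(y4, z4, c(1, 1, 2, 2), "diff_means")
  expect_equal(r4$n_permutations, 4L)
  expect_true(r4$p_value %in% c(0.25, 0.5, 0.75, 1))
  expect_equal(r4$p_value,
               oracle_strat_perm_p(y4, z4, c(1, 1, 2, 2), diff_means))

  expect_error(
    stratified_permutation_pvalue(y4, z4, c(1, 1, 2, 2),
                                  scheme = randomization_scheme(c(2, 0), c(0, 2))),
    "inconsistent")
})

test_that("Monte-Carlo p-values track the exact test within binomial error", {
  miss <- 0L
  for (seed in 1:20) {
    y <- with_seed_for_test(seed, stats::rnorm(8))
    z <- rep(c("T", "C"), 4)
    pe <- permutation_pvalue(y, z, "diff_means")$p_value
    B <- 4000L
    pm <- permutation_pvalue(y, z, "diff_means", mode = "monte_carlo",
                             B = B, seed = seed)$p_value
    if (abs(pm - pe) > 3 * sqrt(pe * (1 - pe) / B) + 1 / B) miss <- miss + 1L
    expect_gte(pm, 1 / (B + 1))
  }
  expect_lte(miss, 1L)  # >= 95% of seeded runs inside the 3-SE band
})

test_that("Monte-Carlo sampling is seed-stable and respects strata", {
  y <- with_seed_for_test(1, stats::rnorm(10))
  z <- rep(c("T", "C"), 5)
  s <- rep(c(1, 2), each = 5)
  a <- stratified_permutation_pvalue(y, z, s, "diff_means",
                                     mode = "monte_carlo", B = 500, seed = 7)
  b <- stratified_permutation_pvalue(y, z, s, "diff_means",
                                     mode = "monte_carlo", B = 500, seed = 7)
  expect_identical(a$p_value, b$p_value)
  # wilcoxon exercises the generic (non-linear) sampling path
  g <- stratified_permutation_pvalue(y, z, s, "wilcoxon",
                                     mode = "monte_carlo", B = 2000, seed = 3)
  ge <- stratified_permutation_pvalue(y, z, s, "wilcoxon")
  expect_lt(abs(g$p_value - ge$p_value), 0.05)
})

test_that("attainable size never exceeds alpha and matches hand values", {
  y <- c(1, 1, 1, 0, 0, 0)
  sch <- randomization_scheme(3, 3)
  expect_equal(attainable_size(y, "diff_props", sch, 0.05), 0.05)
  expect_equal(attainable_size(y, "diff_props", sch, 0.04), 0)
  expect_equal(attainable_size(rep(1, 6), "diff_props", sch, 0.2), 0)
  for (seed in 1:10) {
    yy <- with_seed_for_test(seed, stats::rnorm(8))
    alpha <- with_seed_for_test(seed + 30, stats::runif(1, 0.01, 0.2))
    expect_lte(attainable_size(yy, "diff_means", randomization_scheme(4, 4),
                               alpha),
               alpha + 1e-12)
  }
})

test_that("degenerate statistics propagate as p = 1 with a warning flag", {
  d <- test_statistic("always_degenerate", "smaller",
                      function(y, z) structure(NA_real_, degenerate = TRUE))
  expect_warning(r <- permutation_pvalue(stats::rnorm(4), rep(c("T", "C"), 2), d),
                 "degenerate")
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
})
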