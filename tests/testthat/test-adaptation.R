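test_that("blinded views hide labels but not values, and survive relabeling", {
  td <- random_null_trial(1, with_drug = TRUE)
  v <- blinded_view(td)
  expect_equal(v$n, 8L)
  expect_equal(nrow(v$outcomes), 8L)
  expect_null(v$arm)
  expect_identical(v, blinded_view(relabel(td)))
  # the drug-level leak is through values: 4 positive, 4 zero rows visible
  expect_equal(sum(v$outcomes[, "drug"] > 0), 4L)
  expect_equal(sum(v$outcomes[, "drug"] == 0), 4L)
})

test_that("min-variance rule picks the smallest lumped variance on available cases", {
  plan <- analysis_plan("a")
  mk_view <- function(M) blinded_view(trial_data(seq_len(nrow(M)),
                                                 rep(c("T", "C"), nrow(M) / 2),
                                                 outcomes = M))
  rule <- rule_min_variance(c("a", "b"))
  M <- cbind(a = c(-2, 0, 2, -2, 0, 2), b = c(-1, 0, 1, -1, 0, 1) / 2)
  expect_equal(rule$decide(mk_view(M), plan)$endpoint, "b")
  # tie -> first candidate
  M2 <- cbind(a = M[, 1], b = M[, 1])
  expect_equal(rule$decide(mk_view(M2), plan)$endpoint, "a")
  # variances on available cases only
  M3 <- cbind(a = c(stats::qnorm((1:5) / 6) * sqrt(2), NA),
              b = stats::qnorm((1:6) / 7) * sqrt(3))
  va <- stats::var(M3[1:5, "a"]); vb <- stats::var(M3[, "b"])
  expect_lt(va, vb)
  expect_equal(rule$decide(mk_view(M3), plan)$endpoint, "a")
})

test_that("outlier rule switches to wilcoxon only when the lumped data demand it", {
  plan <- analysis_plan("y", "diff_means")
  rule <- rule_outlier_switch(k = 5)
  mk_view <- function(y) blinded_view(trial_data(seq_along(y),
                                                 rep(c("T", "C"), length(y) / 2),
                                                 outcomes = cbind(y = y)))
  out <- rule$decide(mk_view(c(0.1, -0.2, 0.05, 40.0)), plan)
  expect_equal(out$statistic, "wilcoxon")
  expect_equal(rule$decide(mk_view(rep(1.5, 6)), plan)$statistic, "diff_means")
  clean <- with_seed_for_test(8, stats::rnorm(100))
  expect_equal(rule$decide(mk_view(clean), plan)$statistic, "diff_means")
  # simulated false-trigger rate on clean Gaussian data is small
  trig <- vapply(1:200, function(s) {
    y <- with_seed_for_test(s, stats::rnorm(100))
    rule$decide(mk_view(y), plan)$statistic == "wilcoxon"
  }, logical(1))
  expect_lte(mean(trig), 0.01)
})

test_that("threshold-feasibility rule relaxes an impossible event threshold", {
  sch <- randomization_scheme(3, 3)
  rule <- rule_threshold_feasibility(fallback_threshold = 5, scheme = sch)
  plan <- analysis_plan("sbp>=10", "diff_props", alpha = 0.05,
                        threshold = 10, source = "sbp")
  mk_trial <- function(sbp) trial_data(seq_along(sbp), rep(c("T", "C"), 3),
                                       outcomes = cbind(sbp = sbp))
  # m = 0 events at 10; several at 5 -> switch (minimum p at 10 is 1)
  v <- blinded_view(mk_trial(c(6, 7, 8, 2, 9, 5)))
  out <- rule$decide(v, plan)
  expect_equal(out$threshold, 5)
  # m = 3 at 10: minimum Fisher p = 1/C(6,3) = 0.05 <= alpha -> unchanged
  v3 <- blinded_view(mk_trial(c(11, 12, 13, 2, 3, 4)))
  expect_equal(rule$decide(v3, plan)$threshold, 10)
  # m = 1 at 10: minimum p = 0.5 -> switch
  v1 <- blinded_view(mk_trial(c(11, 2, 3, 4, 6, 7)))
  expect_equal(rule$decide(v1, plan)$threshold, 5)
  # fallback infeasible too -> unchanged with warning
  vbad <- blinded_view(mk_trial(c(1, 2, 3, 1, 2, 3)))
  expect_warning(keep <- rule$decide(vbad, plan), "infeasible")
  expect_equal(keep$threshold, 10)
})

test_that("drug-level adversary reconstructs arms and picks the favorable endpoint", {
  M <- cbind(drug = c(1, 1, 1, 0, 0, 0),
             a = c(1, 2, 3, 4, 4, 4),   # reconstructed effect -2
             b = c(0, 1, 2, 6, 6, 6))   # reconstructed effect -5
  td <- trial_data(1:6, c("T", "T", "T", "C", "C", "C"), outcomes = M)
  plan <- analysis_plan("a", "diff_means")
  rule <- rule_drug_level_adversary("drug", c("a", "b"))
  expect_true(rule$adversarial)
  expect_equal(rule$decide(blinded_view(td), plan)$endpoint, "b")
  # identical endpoints -> first
  M2 <- M; M2[, "b"] <- M2[, "a"]
  td2 <- trial_data(1:6, td$arm, outcomes = M2)
  expect_equal(rule$decide(blinded_view(td2), plan)$endpoint, "a")
  # no separation -> first
  M3 <- M; M3[, "drug"] <- 1
  td3 <- trial_data(1:6, td$arm, outcomes = M3)
  expect_equal(rule$decide(blinded_view(td3), plan)$endpoint, "a")
})

test_that("correlation-leak rule finds the endpoint with the larger |t| from summaries alone", {
  # The summary-measure leak: two lumped correlations suffice to deduce which
  # endpoint shows the stronger apparent treatment effect (larger absolute
  # t-statistic), without ever seeing a subject-level label.
  plan <- analysis_plan("a", "diff_means")
  r_cor <- rule_correlation_leak("drug", c("a", "b"))
  agree <- vapply(1:60, function(s) {
    td <- generate_trial(
      generator_config(5, 5, list(ep_continuous("a"), ep_continuous("b"),
                                  ep_drug_level("drug", sdlog = 0.05))),
      seed = s)
    tt <- vapply(c("a", "b"), function(ep) {
      abs(stats::t.test(td$outcomes[td$arm == "T", ep],
                        td$outcomes[td$arm == "C", ep],
                        var.equal = TRUE)$statistic)
    }, numeric(1))
    r_cor$decide(blinded_view(td), plan)$endpoint == c("a", "b")[which.max(tt)]
  }, logical(1))
  expect_gte(mean(agree), 0.9)
  # degenerate correlation -> first candidate
  td0 <- trial_data(1:4, c("T", "T", "C", "C"),
                    outcomes = cbind(drug = c(1, 1, 0, 0), a = rep(2, 4),
                                     b = c(1, 2, 3, 4)))
  expect_equal(r_cor$decide(blinded_view(td0), plan)$endpoint, "b")
})

test_that("every shipped rule is invariant under arm relabeling", {
  plan <- analysis_plan("a", "diff_means")
  plan_thr <- analysis_plan("a>=0.5", "diff_props", threshold = 0.5, source = "a")
  rules <- list(rule_identity(),
                rule_min_variance(c("a", "b")),
                rule_outlier_switch(),
                rule_drug_level_adversary("drug", c("a", "b")),
                rule_correlation_leak("drug", c("a", "b")),
                rule_threshold_feasibility(0, randomization_scheme(4, 4)))
  for (seed in 1:25) {
    td <- random_null_trial(seed, with_drug = TRUE)
    v1 <- blinded_view(td)
    v2 <- blinded_view(relabel(td))
    for (i in seq_along(rules)) {
      p0 <- if (rules[[i]]$name == "threshold_feasibility") plan_thr else plan
      expect_identical(suppressWarnings(rules[[i]]$decide(v1, p0)),
                       suppressWarnings(rules[[i]]$decide(v2, p0)))
    }
  }
})

test_that("run_adaptive_analysis with the identity rule equals the fixed-design test", {
  td <- random_null_trial(3)
  plan <- analysis_plan("a", "diff_means")
  res <- run_adaptive_analysis(td, rule_identity(), plan)
  ref <- permutation_pvalue(td$outcomes[, "a"], td$arm, "diff_means")
  expect_identical(res$p_value, ref$p_value)
  expect_identical(res$reject, ref$p_value <= 0.05)
  expect_equal(res$plan$endpoint, "a")
})

test_that("the threshold scenario runs end to end at the relaxed cut", {
  sbp <- c(6, 7, 8, 2, 9, 5)   # no 10+ increases; events at 5: subjects 1,2,3,4(no),5,6
  td <- trial_data(1:6, c("T", "T", "T", "C", "C", "C"),
                   outcomes = cbind(sbp = sbp))
  plan <- analysis_plan("sbp>=10", "diff_props", threshold = 10, source = "sbp")
  rule <- rule_threshold_feasibility(5, randomization_scheme(3, 3))
  res <- run_adaptive_analysis(td, rule, plan)
  expect_equal(res$plan$threshold, 5)
  y5 <- as.numeric(sbp >= 5)
  expect_identical(res$p_value,
                   permutation_pvalue(y5, td$arm, "diff_props")$p_value)
})

test_that("rules cannot change alpha and adversaries warn", {
  td <- random_null_trial(4, with_drug = TRUE)
  plan <- analysis_plan("a", "diff_means", alpha = 0.05)
  sneaky <- adaptation_rule("sneaky", function(view, plan) {
    plan$alpha <- 0.5
    plan
  }, reads = "nothing")
  res <- run_adaptive_analysis(td, sneaky, plan)
  expect_equal(res$plan$alpha, 0.05)
  expect_warning(
    run_adaptive_analysis(td, rule_drug_level_adversary("drug", c("a", "b")),
                          plan),
    "adversarial")
})

test_that("adaptive analyses keep conditional size <= alpha on enumerable fixtures", {
  # For every assignment vector of a small trial, run the full adaptive
  # analysis with the rule; the rejection fraction over all consistent
  # vectors (the conditional size given the lumped data) must be <= alpha.
  plan <- analysis_plan("a", "diff_means", alpha = 0.1)
  rules <- list(rule_min_variance(c("a", "b")), rule_outlier_switch())
  for (seed in 1:4) {
    base <- random_null_trial(seed, n_T = 3, n_C = 3)
    for (rule in rules) {
      rej <- vapply(oracle_assignments(6, 3), function(zz) {
        tr <- base; tr$arm <- zz
        run_adaptive_analysis(tr, rule, plan)$reject
      }, logical(1))
      expect_lte(mean(rej), 0.1 + 1e-12)
    }
  }
})
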