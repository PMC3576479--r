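#' Simulation scenario
#'
#' Bundles everything one Monte-Carlo operating-characteristic run needs: the
#' trial generator configuration, the adaptation rule, the original analysis
#' plan, engine options, the number of replications and the seed. The
#' `null_structure` tag documents what the configuration encodes — a strong
#' null (treatment affects nothing), a weak null (treatment affects some
#' endpoints but not the one tested), or an alternative — and is carried into
#' reports.
#'
#' @param label scenario identifier used in reports.
#' @param config a [generator_config()].
#' @param rule an [adaptation_rule].
#' @param plan the original [analysis_plan].
#' @param reps Monte-Carlo replications.
#' @param seed base seed; replication `b` uses a sub-seed derived from
#'   `(seed, b)`, so results are independent of evaluation order.
#' @param mode,B engine options per replication.
#' @param null_structure free documentation tag.
#' @return An object of class `scenario`.
#' @export
scenario <- function(label, config, rule, plan, reps = 10000L, seed = 1L,
                     mode = "exact", B = 10000L, null_structure = "strong") {
  stopifnot(inherits(config, "generator_config"),
            inherits(rule, "adaptation_rule"),
            inherits(plan, "analysis_plan"), reps >= 1)
  structure(list(label = label, config = config, rule = rule, plan = plan,
                 reps = as.integer(reps), seed = as.integer(seed),
                 mode = mode, B = as.integer(B),
                 null_structure = null_structure),
            class = "scenario")
}

#' Monte-Carlo rejection rate of a fixed or adaptive analysis
#'
#' Each replication generates a fresh trial from the scenario's configuration
#' (with a per-replication sub-seed), runs the full blinded-adaptive analysis
#' ([run_adaptive_analysis()]), and records whether the chosen test rejected
#' and which plan the rule chose (the "branch"). Failed replications are
#' recorded and excluded — their count is part of the result and should be 0
#' in any run used for inference about operating characteristics.
#'
#' @param sc a [scenario].
#' @return An object of class `simulation_result`: `rejection_rate`,
#'   `mc_standard_error` (`sqrt(r(1-r)/reps)`), `reps`, `seed`,
#'   `branch_frequencies` (named, sums to 1 over completed reps),
#'   `rejections_by_branch` (per-branch rejection probability, so under a
#'   weak null the type I error is the sum over branches testing an
#'   unaffected endpoint), `n_failed`, `label`, `null_structure`.
#' @export
simulate_rejection_rate <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  rej <- logical(sc$reps)
  branch <- character(sc$reps)
  failed <- 0L
  for (b in seq_len(sc$reps)) {
    res <- tryCatch(suppressWarnings({
      trial <- generate_trial(sc$config, seed = derive_seed(sc$seed, b))
      run_adaptive_analysis(trial, sc$rule, sc$plan, mode = sc$mode, B = sc$B,
                            seed = derive_seed(sc$seed, b + sc$reps))
    }), error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
      branch[b] <- NA_character_
      next
    }
    rej[b] <- res$reject
    branch[b] <- paste0(res$plan$endpoint, "/", res$plan$statistic,
                        if (!is.null(res$plan$threshold))
                          paste0("@", res$plan$threshold) else "")
  }
  ok <- !is.na(branch)
  r <- mean(rej[ok])
  n <- sum(ok)
  structure(list(rejection_rate = r,
                 mc_standard_error = sqrt(r * (1 - r) / n),
                 reps = n, seed = sc$seed,
                 branch_frequencies = table(branch[ok]) / n,
                 rejections_by_branch =
                   tapply(rej[ok], branch[ok], sum) / n,
                 n_failed = failed, label = sc$label,
                 null_structure = sc$null_structure),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s null): rejection rate %.4f (MC SE %.4f, %d reps%s)\n",
              x$label, x$null_structure, x$rejection_rate,
              x$mc_standard_error, x$reps,
              if (x$n_failed) sprintf(", %d failed", x$n_failed) else ""))
  bf <- sort(x$branch_frequencies, decreasing = TRUE)
  cat("  branches:",
      paste(sprintf("%s %.3f", names(bf), as.numeric(bf)), collapse = "; "),
      "\n")
  invisible(x)
}

#' Tabulate simulation results
#'
#' @param results list of [simulate_rejection_rate()] results (may be empty).
#' @return A data frame with columns `scenario`, `rate`, `se`, `reps`,
#'   `seed`, `branch_frequencies` (branches collapsed as
#'   `name:freq` pairs separated by `|`).
#' @export
scenario_report <- function(results) {
  cols <- c("scenario", "rate", "se", "reps", "seed", "branch_frequencies")
  if (!length(results)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    df$rate <- numeric(0); df$se <- numeric(0)
    df$reps <- integer(0); df$seed <- integer(0)
    return(df)
  }
  do.call(rbind, lapply(results, function(r) {
    data.frame(scenario = r$label,
               rate = signif(r$rejection_rate, 6),
               se = signif(r$mc_standard_error, 6),
               reps = r$reps, seed = r$seed,
               branch_frequencies = paste(
                 sprintf("%s:%g", names(r$branch_frequencies),
                         signif(as.numeric(r$branch_frequencies), 6)),
                 collapse = "|"),
               stringsAsFactors = FALSE)
  }))
}

#' @rdname scenario_report
#' @param report a data frame from `scenario_report()`.
#' @param path CSV output path.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The per-arm-counts-known sample-size adversary
#'
#' Demonstrates why knowledge of per-arm sample sizes at an interim breaks
#' the plain permutation test and how stratification repairs it. The design
#' is a binary-outcome trial with `n_T` treatment and `n_C` control subjects
#' enrolled in uniformly random order; after `split_after` subjects the
#' adversary observes the per-arm counts so far and the lumped event total,
#' and computes the conditional probability (under the known null event rate
#' `p`) that completing the design as planned would reject. If that
#' probability is exactly 0 — rejection already impossible — the adversary
#' extends the second stage by up to `extension_cap` extra subjects, choosing
#' the extension that maximizes the conditional rejection probability,
#' thereby buying back type I error that the fixed design had already spent.
#' Otherwise the design is left alone.
#'
#' Every simulated trial is analyzed three ways: the plain (unstratified)
#' one-sided Fisher-equivalent test on the possibly extended data, the
#' stratified permutation test conditioning on the per-arm counts in each
#' stage, and the fixed (never-extended) design's test. The plain test's rate
#' exceeds the fixed design's exact size; the stratified test stays at or
#' below `alpha`.
#'
#' @param reps,seed Monte-Carlo replications and base seed.
#' @param n_T,n_C planned per-arm sizes.
#' @param split_after interim position (subjects observed at adaptation).
#' @param p common null event probability.
#' @param alpha one-sided level.
#' @param extension_cap maximum number of extra subjects.
#' @return An object of class `size_adversary_sim` with elements
#'   `rate_plain`, `rate_stratified`, `rate_fixed` (each with `se_`
#'   counterparts), `fixed_exact_size`, `extension_freq`, `reps`, `seed`.
#' @export
simulate_size_adversary <- function(reps = 10000L, seed = 1L, n_T = 3L,
                                    n_C = 3L, split_after = 3L, p = 0.5,
                                    alpha = 0.05, extension_cap = 8L) {
  n <- n_T + n_C
  stopifnot(split_after >= 1, split_after < n)

  # Decision table over interim states (n_T1, lumped events m1). The adversary
  # knows per-arm counts but only lumped events; its conditional rejection
  # probability averages over the hypergeometric split of events across arms.
  avg_crp <- function(n_T1, n_C1, m1, n_T2, n_C2) {
    es <- max(0L, m1 - n_C1):min(n_T1, m1)
    w <- choose(n_T1, es) * choose(n_C1, m1 - es) / choose(n_T1 + n_C1, m1)
    sum(w * vapply(es, function(e) {
      as.numeric(conditional_rejection_probability(
        interim_state(n_T1, n_C1, e, m1 - e, n_T2, n_C2, p_T = p,
                      alpha = alpha)))
    }, numeric(1)))
  }
  exts <- expand.grid(a = 0:extension_cap, b = 0:extension_cap)
  exts <- exts[exts$a + exts$b <= extension_cap & exts$a + exts$b > 0, ]
  decision <- list()
  for (n_T1 in max(0L, split_after - n_C):min(split_after, n_T)) {
    n_C1 <- split_after - n_T1
    for (m1 in 0:split_after) {
      base_T2 <- n_T - n_T1; base_C2 <- n_C - n_C1
      key <- paste(n_T1, m1)
      if (avg_crp(n_T1, n_C1, m1, base_T2, base_C2) > 1e-15) {
        decision[[key]] <- c(0L, 0L)
      } else {
        crps <- mapply(function(a, b) avg_crp(n_T1, n_C1, m1,
                                              base_T2 + a, base_C2 + b),
                       exts$a, exts$b)
        best <- which.max(crps)
        decision[[key]] <- if (crps[best] > 1e-15)
          c(exts$a[best], exts$b[best]) else c(0L, 0L)
      }
    }
  }

  rej_plain <- rej_strat <- rej_fixed <- logical(reps)
  ext_used <- character(reps)
  for (b in seq_len(reps)) {
    res <- with_seed(derive_seed(seed, b), {
      arm <- sample(rep(c("T", "C"), c(n_T, n_C)))
      y <- as.numeric(stats::runif(n) < p)
      n_T1 <- sum(arm[seq_len(split_after)] == "T")
      m1 <- sum(y[seq_len(split_after)])
      ext <- decision[[paste(n_T1, m1)]]
      arm2 <- c(arm, rep(c("T", "C"), ext))
      y2 <- c(y, as.numeric(stats::runif(sum(ext)) < p))
      stratum <- rep(c(1L, 2L), c(split_after, length(arm2) - split_after))
      tab_all <- rbind(c(sum(y2[arm2 == "T"]), sum(arm2 == "T") - sum(y2[arm2 == "T"])),
                       c(sum(y2[arm2 == "C"]), sum(arm2 == "C") - sum(y2[arm2 == "C"])))
      tab_fix <- rbind(c(sum(y[arm == "T"]), n_T - sum(y[arm == "T"])),
                       c(sum(y[arm == "C"]), n_C - sum(y[arm == "C"])))
      p_strat <- stratified_permutation_pvalue(y2, arm2, stratum,
                                               statistic = "diff_props")$p_value
      list(plain = fisher_exact_one_sided(tab_all) <= alpha + 1e-12,
           strat = p_strat <= alpha + 1e-12,
           fixed = fisher_exact_one_sided(tab_fix) <= alpha + 1e-12,
           ext = paste(ext, collapse = "+"))
    })
    rej_plain[b] <- res$plain; rej_strat[b] <- res$strat
    rej_fixed[b] <- res$fixed; ext_used[b] <- res$ext
  }
  rate <- function(x) mean(x)
  se <- function(x) sqrt(mean(x) * (1 - mean(x)) / reps)
  # exact size of the never-extended design: sum over outcome tables
  sz <- 0
  for (eT in 0:n_T) for (eC in 0:n_C) {
    if (fisher_exact_one_sided(rbind(c(eT, n_T - eT), c(eC, n_C - eC))) <=
        alpha + 1e-12)
      sz <- sz + stats::dbinom(eT, n_T, p) * stats::dbinom(eC, n_C, p)
  }
  structure(list(rate_plain = rate(rej_plain), se_plain = se(rej_plain),
                 rate_stratified = rate(rej_strat), se_stratified = se(rej_strat),
                 rate_fixed = rate(rej_fixed), se_fixed = se(rej_fixed),
                 fixed_exact_size = sz,
                 extension_freq = table(ext_used) / reps,
                 reps = reps, seed = seed, alpha = alpha),
            class = "size_adversary_sim")
}

#' @export
print.size_adversary_sim <- function(x, ...) {
  cat(sprintf("Sample-size adversary with per-arm counts known (alpha = %g, %d reps)\n",
              x$alpha, x$reps))
  cat(sprintf("  fixed design:    rate %.4f (exact size %.6f)\n",
              x$rate_fixed, x$fixed_exact_size))
  cat(sprintf("  plain test:      rate %.4f (SE %.4f)  <- inflated by the adversary\n",
              x$rate_plain, x$se_plain))
  cat(sprintf("  stratified test: rate %.4f (SE %.4f)  <- conditions on per-arm counts\n",
              x$rate_stratified, x$se_stratified))
  invisible(x)
}

.config_from_list <- function(g) {
  eps <- lapply(g$endpoints, function(e) {
    switch(e$type,
           continuous = ep_continuous(e$name, e$mean_T %||% 0, e$mean_C %||% 0,
                                      e$sd %||% 1),
           binary = ep_binary(e$name, e$p_T %||% 0.5, e$p_C %||% 0.5),
           drug_level = ep_drug_level(e$name, e$meanlog %||% 0, e$sdlog %||% 0.25),
           stopf("unknown endpoint type '%s'", e$type))
  })
  generator_config(unlist(g$n_T), unlist(g$n_C), eps, rho = g$rho %||% 0,
                   missingness = g$missingness,
                   split_after = g$split_after,
                   seed = g$seed %||% 1L)
}

#' @rdname read_scenario
#' @export
read_generator_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  .config_from_list(j$generator %||% j)
}

#' Read a scenario from a JSON file
#'
#' The JSON mirrors the scenario constructor: `label`, `generator`
#' (`n_T`, `n_C`, `rho`, `split_after`, `seed`, `endpoints` — a list of
#' objects with `name`, `type` and type-specific parameters — and optional
#' `missingness`), `rule` (`name` plus arguments), `plan`, `reps`, `seed`,
#' `mode`, `B`, `null_structure`.
#'
#' @param path JSON file path.
#' @return A [scenario].
#' @export
read_scenario <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  config <- .config_from_list(j$generator)
  r <- j$rule
  rule <- switch(r$name,
    identity = rule_identity(),
    min_variance = rule_min_variance(unlist(r$candidates)),
    outlier_switch = rule_outlier_switch(r$k %||% 5),
    threshold_feasibility = rule_threshold_feasibility(
      r$fallback_threshold,
      randomization_scheme(unlist(r$scheme$n_T), unlist(r$scheme$n_C))),
    drug_level_adversary = rule_drug_level_adversary(r$drug, unlist(r$candidates)),
    correlation_leak = rule_correlation_leak(r$drug, unlist(r$candidates)),
    stopf("unknown rule '%s'", r$name))
  p <- j$plan
  plan <- analysis_plan(p$endpoint, p$statistic %||% "diff_means",
                        p$direction, p$alpha %||% 0.05,
                        threshold = p$threshold, source = p$source)
  scenario(j$label %||% basename(path), config, rule, plan,
           reps = j$reps %||% 10000L, seed = j$seed %||% 1L,
           mode = j$mode %||% "exact", B = j$B %||% 10000L,
           null_structure = j$null_structure %||% "strong")
}
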