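#' Analysis plan
#'
#' What the final analysis will do: which endpoint, which test statistic,
#' its one-sided orientation, and the significance level. The level is fixed
#' at design time — an adaptation may change the endpoint, statistic or a
#' derived-endpoint threshold, never `alpha`. A binary endpoint derived from
#' a continuous column (e.g. "systolic change >= 10 mmHg") is expressed with
#' `source` and `threshold`; the event indicator is `source >= threshold`.
#'
#' @param endpoint endpoint name (for derived endpoints, a display name; the
#'   data column is `source`).
#' @param statistic statistic registry name (see [get_statistic()]).
#' @param direction one-sided orientation; default is the statistic's.
#' @param alpha one-sided significance level in (0, 1).
#' @param threshold,source optional derived-binary-endpoint definition.
#' @return An object of class `analysis_plan`.
#' @export
analysis_plan <- function(endpoint, statistic = "diff_means", direction = NULL,
                          alpha = 0.05, threshold = NULL, source = NULL) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (!is.null(threshold) && is.null(source))
    stopf("a derived endpoint needs both threshold and source")
  st <- get_statistic(statistic, direction)
  structure(list(endpoint = endpoint, statistic = st$name,
                 direction = st$direction, alpha = alpha,
                 threshold = threshold, source = source),
            class = "analysis_plan")
}

#' @export
print.analysis_plan <- function(x, ...) {
  ep <- if (is.null(x$threshold)) x$endpoint else
    sprintf("%s (event: %s >= %g)", x$endpoint, x$source, x$threshold)
  cat(sprintf("Analysis plan: endpoint %s, statistic %s (%s), alpha = %g\n",
              ep, x$statistic, x$direction, x$alpha))
  invisible(x)
}

# outcome vector the plan actually tests
.plan_outcome <- function(outcomes, plan) {
  if (!is.null(plan$threshold)) {
    src <- outcomes[, plan$source]
    return(ifelse(is.na(src), NA_real_, as.numeric(src >= plan$threshold)))
  }
  if (!plan$endpoint %in% colnames(outcomes))
    stopf("endpoint '%s' not present in the trial", plan$endpoint)
  outcomes[, plan$endpoint]
}

# Label-free digest of the lumped outcome values: identical for a trial and
# any arm-relabeled copy of it, so it can key the blinded row shuffle.
.blind_key <- function(M) {
  v <- sort(as.vector(M[!is.na(M)]))
  h <- sum((v %% 7919) * (seq_along(v) %% 101)) + 13 * sum(is.na(M)) + length(v)
  as.integer(abs(h * 1e4) %% 2147483629)
}

#' Blinded (lumped) view of a trial
#'
#' What a still-blinded investigator may examine before deciding on an
#' adaptation: the pooled outcome values with arm labels removed and subject
#' order shuffled by a keyed permutation (the key is a digest of the outcome
#' values themselves, so enrollment order cannot be used as a side channel
#' and a trial and its arm-relabeled copy yield identical views); per-endpoint
#' lumped missingness counts; the total sample size; and per-stratum totals.
#' Per-arm counts — per stratum or overall — are deliberately absent from
#' this type: a view never contains arm labels in any form. Note that
#' blinding hides labels, not values: a drug-level endpoint's lumped values
#' (positive for treated subjects, zero otherwise) still unblind whoever
#' looks at them.
#'
#' @param trial a [trial_data] object.
#' @return An object of class `blinded_view`: `outcomes` (shuffled lumped
#'   matrix), `n`, `n_missing` (per endpoint), `stratum_sizes`.
#' @export
blinded_view <- function(trial) {
  M <- trial$outcomes
  perm <- with_seed(.blind_key(M), sample.int(nrow(M)))
  structure(list(outcomes = M[perm, , drop = FALSE],
                 n = nrow(M),
                 n_missing = colSums(is.na(M)),
                 stratum_sizes = as.integer(table(trial$stratum))),
            class = "blinded_view")
}

#' @export
print.blinded_view <- function(x, ...) {
  cat(sprintf("Blinded view: %d lumped subjects, endpoints: %s\n",
              x$n, paste(colnames(x$outcomes), collapse = ", ")))
  invisible(x)
}

#' Adaptation rules
#'
#' An adaptation rule is a deterministic mapping from the [blinded_view] of a
#' trial and the original [analysis_plan] to a possibly modified plan (same
#' `alpha`, possibly different endpoint/statistic/threshold). Each rule
#' declares which view components it reads (`reads`): the hypothesis a
#' significant adaptive analysis rejects is "the treatment has no effect on
#' any data the rule examined", so the declaration makes the scope of that
#' conclusion auditable. Rules constructed here are either legitimate blinded
#' practice or deliberately adversarial (`adversarial = TRUE`), the latter
#' existing to demonstrate in simulation how blinded-looking data can leak
#' arm information.
#'
#' @param name rule name.
#' @param decide `function(view, plan)` returning an [analysis_plan].
#' @param reads character vector describing the view components read.
#' @param adversarial flag for rules that exist to demonstrate inflation.
#' @return An object of class `adaptation_rule`.
#' @export
adaptation_rule <- function(name, decide, reads, adversarial = FALSE) {
  structure(list(name = name, decide = decide, reads = reads,
                 adversarial = adversarial),
            class = "adaptation_rule")
}

#' @export
print.adaptation_rule <- function(x, ...) {
  cat(sprintf("Adaptation rule '%s'%s; reads: %s\n", x$name,
              if (x$adversarial) " [ADVERSARIAL]" else "",
              paste(x$reads, collapse = ", ")))
  invisible(x)
}

#' @rdname adaptation_rule
#' @export
rule_identity <- function() {
  adaptation_rule("identity", function(view, plan) plan, reads = character())
}

#' Blinded endpoint selection by smallest lumped variance
#'
#' Chooses, among the candidate continuous endpoints, the one whose lumped
#' (both arms pooled) sample variance is smallest — the classic blinded
#' tie-breaker between two candidate primary endpoints measured with
#' different reliability. Variances use available cases; a fully missing
#' candidate is excluded with a warning; ties go to the earlier candidate in
#' the configured order.
#'
#' @param candidates character vector of candidate endpoint names, in
#'   tie-break priority order.
#' @return An [adaptation_rule].
#' @export
rule_min_variance <- function(candidates) {
  if (length(candidates) < 2L) stopf("need at least 2 candidate endpoints")
  adaptation_rule(
    "min_variance",
    function(view, plan) {
      v <- vapply(candidates, function(ep) {
        x <- view$outcomes[, ep]
        stats::var(x[!is.na(x)])
      }, numeric(1))
      ok <- !is.na(v)
      if (!all(ok)) {
        warning("candidate(s) fully missing, excluded: ",
                paste(candidates[!ok], collapse = ", "), call. = FALSE)
      }
      pick <- candidates[ok][which.min(v[ok])]   # which.min takes first on ties
      plan$endpoint <- pick
      plan
    },
    reads = sprintf("outcomes[%s]", candidates))
}

#' Outlier-triggered switch from the t-type to the rank statistic
#'
#' Examines the lumped values of the planned endpoint; if any value deviates
#' from the lumped median by more than `k` median absolute deviations
#' (consistency-scaled, so k plays the role of a z-score cut under
#' normality), the apparent outliers call the planned
#' mean-difference analysis into question and the statistic is switched to
#' the Wilcoxon rank sum. If the MAD is zero on non-constant data the
#' criterion falls back to the interquartile range. Constant data never
#' trigger a switch.
#'
#' @param k deviation multiplier (default 5).
#' @return An [adaptation_rule].
#' @export
rule_outlier_switch <- function(k = 5) {
  adaptation_rule(
    "outlier_switch",
    function(view, plan) {
      if (plan$statistic != "diff_means") return(plan)
      x <- view$outcomes[, plan$endpoint]
      x <- x[!is.na(x)]
      med <- stats::median(x)
      s <- stats::mad(x, center = med)   # consistency-scaled MAD
      if (s == 0) {
        if (all(x == x[1L])) return(plan)        # constant data: nothing to flag
        s <- stats::IQR(x)
      }
      trigger <- if (s == 0) any(x != med) else any(abs(x - med) > k * s)
      if (trigger) plan$statistic <- "wilcoxon"
      plan
    },
    reads = "outcomes[planned endpoint]")
}

#' Relax an infeasible binary-endpoint threshold
#'
#' For a binary endpoint derived from a continuous column at a threshold
#' (e.g. "increase >= 10 mmHg"): from the lumped data alone one can compute
#' the total number of events `m` and hence the smallest one-sided Fisher
#' p-value any unblinded split could possibly attain (all `m` events in the
#' unfavorable arm). If even that minimum exceeds `alpha`, significance is
#' literally impossible at the planned threshold, and the endpoint is
#' re-derived at the clinically acceptable fallback threshold. If the
#' fallback is infeasible too, the plan is returned unchanged with a warning.
#'
#' @param fallback_threshold relaxed threshold to switch to.
#' @param scheme the design's [randomization_scheme] (per-arm sizes are part
#'   of the design, known without unblinding).
#' @return An [adaptation_rule].
#' @export
rule_threshold_feasibility <- function(fallback_threshold, scheme) {
  adaptation_rule(
    "threshold_feasibility",
    function(view, plan) {
      if (is.null(plan$threshold)) stopf("plan has no derived binary endpoint")
      n_T <- sum(scheme$n_T); n_C <- sum(scheme$n_C)
      min_p <- function(thr) {
        src <- view$outcomes[, plan$source]
        m <- sum(src >= thr, na.rm = TRUE)
        n <- n_T + n_C
        if (plan$direction == "smaller") {
          stats::phyper(0, m, n - m, n_T)           # all events in C
        } else {
          stats::phyper(m - 1, m, n - m, n_T, lower.tail = FALSE)  # all in T
        }
      }
      if (min_p(plan$threshold) <= plan$alpha + 1e-12) return(plan)
      if (min_p(fallback_threshold) > plan$alpha + 1e-12) {
        warning("fallback threshold also infeasible; plan unchanged",
                call. = FALSE)
        return(plan)
      }
      plan$threshold <- fallback_threshold
      plan$endpoint <- sprintf("%s>=%g", plan$source, fallback_threshold)
      plan
    },
    reads = "outcomes[source column] (event totals only)")
}

#' Adversarial rules: unblinding through values and through summaries
#'
#' `rule_drug_level_adversary()` reconstructs the arm labels from a
#' drug-level endpoint (positive level = treated), evaluates every candidate
#' clinical endpoint's statistic under the reconstructed labels, and picks
#' the endpoint with the most favorable apparent effect. It is the canonical
#' demonstration that a "blinded" view can completely unblind: the rule only
#' ever sees lumped values, yet behaves like an unblinded analyst, and its
#' simulated false positive rate exceeds any fixed design's.
#' `rule_correlation_leak()` reaches the same endpoint choice while reading
#' only two lumped summary numbers — the sample correlations between drug
#' level and each clinical endpoint — showing that restricting attention to
#' summary measures is no safeguard. Both are flagged adversarial and exist
#' for the simulation laboratory.
#'
#' If the drug level fails to separate the arms (no positive values, or no
#' zeros), or a correlation is undefined, the first candidate is selected.
#'
#' @param drug name of the drug-level endpoint.
#' @param candidates clinical endpoint names (tie-break order).
#' @return An [adaptation_rule] with `adversarial = TRUE`.
#' @export
rule_drug_level_adversary <- function(drug, candidates) {
  if (length(candidates) < 2L) stopf("need at least 2 clinical endpoints")
  adaptation_rule(
    "drug_level_adversary",
    function(view, plan) {
      lev <- view$outcomes[, drug]
      zhat <- ifelse(!is.na(lev) & lev > 0, "T", "C")
      plan$endpoint <- candidates[1L]
      if (length(unique(zhat)) < 2L) return(plan)   # failed to separate
      st <- get_statistic(plan$statistic, plan$direction)
      tv <- vapply(candidates, function(ep) {
        tryCatch(as.numeric(st$evaluate(view$outcomes[, ep], zhat)),
                 error = function(e) NA_real_)
      }, numeric(1))
      if (all(is.na(tv))) return(plan)
      pick <- if (st$direction == "smaller") which.min(tv) else which.max(tv)
      plan$endpoint <- candidates[pick]
      plan
    },
    reads = c(sprintf("outcomes[%s]", drug), sprintf("outcomes[%s]", candidates)),
    adversarial = TRUE)
}

#' @rdname rule_drug_level_adversary
#' @export
rule_correlation_leak <- function(drug, candidates) {
  if (length(candidates) < 2L) stopf("need at least 2 clinical endpoints")
  adaptation_rule(
    "correlation_leak",
    function(view, plan) {
      lev <- view$outcomes[, drug]
      r <- vapply(candidates, function(ep) {
        x <- view$outcomes[, ep]
        ok <- !is.na(x) & !is.na(lev)
        if (sum(ok) < 2L || stats::sd(x[ok]) == 0 || stats::sd(lev[ok]) == 0)
          return(NA_real_)
        abs(stats::cor(lev[ok], x[ok]))
      }, numeric(1))
      plan$endpoint <- if (all(is.na(r))) candidates[1L] else
        candidates[which.max(r)]                    # first on ties
      plan
    },
    reads = sprintf("cor(%s, %s) [lumped summary]", drug, candidates),
    adversarial = TRUE)
}

#' Run a blinded-adaptive analysis end to end
#'
#' Applies the rule to the [blinded_view] of the trial (the rule never sees
#' arm labels), then tests the chosen endpoint with the chosen statistic by
#' the exact or Monte-Carlo permutation test — stratified whenever the trial
#' has more than one enrollment stratum, i.e. whenever per-arm counts were
#' known at the adaptation time. `alpha` is taken from the original plan and
#' cannot be changed by the rule.
#'
#' Because the rule may have examined several endpoints, a significant result
#' rejects only the hypothesis that treatment has no effect on *any* data the
#' rule read; the decision record therefore carries the rule's declared
#' inputs.
#'
#' @param trial a [trial_data] object.
#' @param rule an [adaptation_rule].
#' @param plan the original [analysis_plan].
#' @param mode,B,seed,cap passed to the permutation engine.
#' @return An object of class `adaptive_analysis`: `plan` (chosen), `test`
#'   (the [permutation_pvalue] result), `p_value`, `reject`, `rule`,
#'   `inputs_read`, `adversarial`.
#' @export
run_adaptive_analysis <- function(trial, rule, plan,
                                  mode = c("exact", "monte_carlo"),
                                  B = 10000L, seed = NULL, cap = 1e6) {
  mode <- match.arg(mode)
  stopifnot(inherits(rule, "adaptation_rule"), inherits(plan, "analysis_plan"))
  if (rule$adversarial)
    warning(sprintf("rule '%s' is adversarial: it exists to demonstrate type I error inflation",
                    rule$name), call. = FALSE)
  chosen <- rule$decide(blinded_view(trial), plan)
  chosen$alpha <- plan$alpha                       # alpha is immutable
  y <- .plan_outcome(trial$outcomes, chosen)
  stat <- get_statistic(chosen$statistic, chosen$direction)
  multi <- length(unique(trial$stratum)) > 1L
  res <- if (multi) {
    stratified_permutation_pvalue(y, trial$arm, trial$stratum, stat,
                                  mode = mode, B = B, seed = seed, cap = cap)
  } else {
    permutation_pvalue(y, trial$arm, stat, mode = mode, B = B, seed = seed,
                       cap = cap)
  }
  structure(list(plan = chosen, test = res, p_value = res$p_value,
                 reject = res$p_value <= chosen$alpha, rule = rule$name,
                 inputs_read = rule$reads, adversarial = rule$adversarial),
            class = "adaptive_analysis")
}

#' @export
print.adaptive_analysis <- function(x, ...) {
  cat(sprintf("Adaptive analysis (rule '%s'%s)\n", x$rule,
              if (x$adversarial) ", ADVERSARIAL" else ""))
  print(x$plan)
  cat(sprintf("  p = %g -> %s at alpha = %g\n", x$p_value,
              if (x$reject) "reject" else "do not reject", x$plan$alpha))
  if (x$reject) {
    cat("  Conclusion scope: treatment affects at least one of the data components\n")
    cat(sprintf("  examined by the rule: %s\n",
                paste(x$inputs_read, collapse = ", ")))
  }
  invisible(x)
}
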