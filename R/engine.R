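#' Randomization scheme: per-stratum arm counts
#'
#' A permutation test conditions on the outcomes and treats every arm-label
#' vector consistent with the randomization scheme — the per-stratum counts of
#' T and C — as equally likely. With a single stratum that is the usual
#' two-sample permutation set; with several strata (the per-arm counts known
#' at the time of an adaptation) the set is restricted to vectors preserving
#' the counts within every stratum.
#'
#' @param n_T,n_C integer vectors of per-stratum arm counts (equal length;
#'   stratum `s` has `n_T[s]` treatment and `n_C[s]` control subjects).
#' @return An object of class `randomization_scheme`.
#' @examples
#' randomization_scheme(3, 3)        # plain 3-vs-3
#' randomization_scheme(c(0, 3), c(3, 0))  # the degenerate two-stage design
#' @export
randomization_scheme <- function(n_T, n_C) {
  if (length(n_T) != length(n_C)) stopf("n_T and n_C must have equal length")
  if (any(n_T < 0) || any(n_C < 0)) stopf("counts must be nonnegative")
  structure(list(n_T = as.integer(n_T), n_C = as.integer(n_C)),
            class = "randomization_scheme")
}

#' @rdname randomization_scheme
#' @param trial a [trial_data] object; counts are read off its arm and
#'   stratum vectors.
#' @export
scheme_from_trial <- function(trial) {
  s <- sort(unique(trial$stratum))
  randomization_scheme(
    n_T = vapply(s, function(k) sum(trial$arm == "T" & trial$stratum == k), 0L),
    n_C = vapply(s, function(k) sum(trial$arm == "C" & trial$stratum == k), 0L))
}

#' @rdname randomization_scheme
#' @param scheme a `randomization_scheme`.
#' @return `n_assignments()` gives the number of consistent assignment
#'   vectors: the product over strata of binomial coefficients.
#' @export
n_assignments <- function(scheme) {
  prod(choose(scheme$n_T + scheme$n_C, scheme$n_T))
}

#' @export
print.randomization_scheme <- function(x, ...) {
  cat(sprintf("Randomization scheme: %d strat%s, T = (%s), C = (%s), %s consistent vectors\n",
              length(x$n_T), if (length(x$n_T) == 1L) "um" else "a",
              paste(x$n_T, collapse = ","), paste(x$n_C, collapse = ","),
              format(n_assignments(x))))
  invisible(x)
}

# stratum index list in stratum-label order
.stratum_idx <- function(stratum) {
  lapply(sort(unique(stratum)), function(s) which(stratum == s))
}

.check_consistent <- function(z, stratum, scheme) {
  idx <- .stratum_idx(stratum)
  if (length(idx) != length(scheme$n_T))
    stopf("data have %d strata but the scheme has %d", length(idx), length(scheme$n_T))
  for (s in seq_along(idx)) {
    zT <- sum(z[idx[[s]]] == "T")
    if (zT != scheme$n_T[s] || length(idx[[s]]) - zT != scheme$n_C[s])
      stopf("observed assignment is inconsistent with the scheme in stratum %d", s)
  }
  invisible(TRUE)
}

# Logical matrix (assignments x subjects), TRUE = treatment, enumerating every
# vector with the scheme's per-stratum counts at the given subject positions.
.enumerate_T <- function(idx_list, n_T, cap = 1e6) {
  N <- prod(vapply(seq_along(idx_list),
                   function(s) choose(length(idx_list[[s]]), n_T[s]), 0))
  if (N > cap)
    stopf("%s consistent assignment vectors exceed the exact-mode cap (%s); use mode = 'monte_carlo'",
          format(N), format(cap))
  N <- as.integer(N)
  n <- sum(lengths(idx_list))
  combs <- lapply(seq_along(idx_list),
                  function(s) utils::combn(length(idx_list[[s]]), n_T[s]))
  grid <- expand.grid(lapply(combs, function(m) seq_len(ncol(m))),
                      KEEP.OUT.ATTRS = FALSE)
  Tmat <- matrix(FALSE, N, n)
  for (s in seq_along(idx_list)) {
    k <- nrow(combs[[s]])
    if (k == 0L) next
    pos <- combs[[s]][, grid[[s]], drop = FALSE]       # k x N local positions
    Tmat[cbind(rep(seq_len(N), each = k), idx_list[[s]][as.vector(pos)])] <- TRUE
  }
  Tmat
}

#' Enumerate all consistent assignment vectors
#'
#' Subjects are ordered stratum by stratum. The number of vectors is the
#' product over strata of binomial coefficients; above `cap` the function
#' refuses and directs the caller to Monte-Carlo mode.
#'
#' @param scheme a [randomization_scheme].
#' @param cap exact-mode cap on the number of vectors.
#' @return Character matrix, one row per consistent vector, entries `"T"`/`"C"`.
#' @examples
#' enumerate_assignments(randomization_scheme(1, 1))
#' @export
enumerate_assignments <- function(scheme, cap = 1e6) {
  stratum <- rep(seq_along(scheme$n_T), scheme$n_T + scheme$n_C)
  Tmat <- .enumerate_T(.stratum_idx(stratum), scheme$n_T, cap)
  out <- matrix("C", nrow(Tmat), ncol(Tmat))
  out[Tmat] <- "T"
  out
}

# Statistic values over enumerated assignments; linear statistics (mean and
# proportion differences on complete data) go through one matrix product.
.stat_values <- function(y, Tmat, statistic) {
  if (statistic$name %in% c("diff_means", "diff_props") && !anyNA(y)) {
    nT <- sum(Tmat[1L, ])
    nC <- ncol(Tmat) - nT
    sT <- as.vector(Tmat %*% y)
    return(sT / nT - (sum(y) - sT) / nC)
  }
  vapply(seq_len(nrow(Tmat)), function(i) {
    as.numeric(statistic$evaluate(y, ifelse(Tmat[i, ], "T", "C")))
  }, numeric(1))
}

.tol_at <- function(t) 1e-12 * max(1, abs(t))

.pval_from_tv <- function(tv, t_obs, direction) {
  tol <- .tol_at(t_obs)
  if (direction == "smaller") mean(tv <= t_obs + tol) else mean(tv >= t_obs - tol)
}

# Sorted attainable p-values of the exact test (one per tied group of
# statistic values, in extremity order).
.attainable_p <- function(tv, direction) {
  st <- sort(tv, decreasing = (direction == "larger"))
  n <- length(st)
  if (n == 1L) return(1)
  gap <- abs(diff(st)) > 1e-12 * pmax(1, abs(st[-n]))
  grp <- cumsum(c(TRUE, gap))
  unique(cumsum(tabulate(grp)) / n)
}

.new_perm_test <- function(p, n_perm, method, t_obs, attainable, statistic,
                           stratified, degenerate = FALSE) {
  structure(list(p_value = p, n_permutations = n_perm, method = method,
                 observed_statistic = t_obs, attainable_p = attainable,
                 statistic = statistic$name, direction = statistic$direction,
                 stratified = stratified, degenerate = degenerate),
            class = "perm_test")
}

# Shared engine behind the plain and stratified public entry points.
.perm_test <- function(y, z, stratum, statistic, mode, B, seed, cap) {
  statistic <- get_statistic(statistic)
  scheme <- randomization_scheme(
    n_T = vapply(.stratum_idx(stratum), function(i) sum(z[i] == "T"), 0L),
    n_C = vapply(.stratum_idx(stratum), function(i) sum(z[i] == "C"), 0L))
  t_obs <- statistic$evaluate(y, z)
  stratified <- length(scheme$n_T) > 1L
  if (is_degenerate(t_obs)) {
    warning("degenerate statistic: p-value set to 1", call. = FALSE)
    return(.new_perm_test(1, n_assignments(scheme), mode, NA_real_, NULL,
                          statistic, stratified, degenerate = TRUE))
  }
  t_obs <- as.numeric(t_obs)
  idx <- .stratum_idx(stratum)
  if (mode == "exact") {
    Tmat <- .enumerate_T(idx, scheme$n_T, cap)
    tv <- .stat_values(y, Tmat, statistic)
    p <- .pval_from_tv(tv, t_obs, statistic$direction)
    .new_perm_test(p, nrow(Tmat), "exact", t_obs,
                   .attainable_p(tv, statistic$direction), statistic, stratified)
  } else {
    tv <- with_seed(seed, .mc_stat_values(y, idx, scheme, statistic, B))
    k <- if (statistic$direction == "smaller") {
      sum(tv <= t_obs + .tol_at(t_obs))
    } else {
      sum(tv >= t_obs - .tol_at(t_obs))
    }
    .new_perm_test((1 + k) / (1 + B), B, "monte_carlo", t_obs, NULL,
                   statistic, stratified)
  }
}

# B statistic values under uniformly sampled consistent assignments
# (independent Fisher-Yates draws within each stratum).
.mc_stat_values <- function(y, idx, scheme, statistic, B) {
  n <- length(y)
  one_stratum <- length(idx) == 1L
  linear <- statistic$name %in% c("diff_means", "diff_props") && !anyNA(y)
  if (linear) {
    nT <- sum(scheme$n_T); nC <- sum(scheme$n_C); tot <- sum(y)
    sT <- vapply(seq_len(B), function(b) {
      sel <- if (one_stratum) idx[[1L]][sample.int(n, nT)] else {
        unlist(lapply(seq_along(idx),
                      function(s) idx[[s]][sample.int(length(idx[[s]]), scheme$n_T[s])]))
      }
      sum(y[sel])
    }, numeric(1))
    return(sT / nT - (tot - sT) / nC)
  }
  vapply(seq_len(B), function(b) {
    zb <- rep("C", n)
    for (s in seq_along(idx)) {
      zb[idx[[s]][sample.int(length(idx[[s]]), scheme$n_T[s])]] <- "T"
    }
    as.numeric(statistic$evaluate(y, zb))
  }, numeric(1))
}

#' Permutation p-value, plain or stratified
#'
#' `permutation_pvalue()` is the ordinary two-sample permutation
#' (randomization) test: conditioning on the outcomes `y`, every relabeling
#' of subjects with the observed total arm counts is equally likely, and the
#' p-value is the fraction of relabelings whose statistic is at least as
#' extreme (in the statistic's declared direction, ties included) as the
#' observed one. `stratified_permutation_pvalue()` restricts the relabelings
#' to those preserving the per-arm counts within every stratum — the right
#' test when per-arm sample sizes were known at the time of an adaptation.
#' With a single stratum the two are identical.
#'
#' In `"exact"` mode all consistent vectors are enumerated (up to `cap`) and
#' the attainable p-value grid is returned; in `"monte_carlo"` mode `B`
#' vectors are sampled uniformly and the add-one estimator `(1 + k)/(1 + B)`
#' is used, which never reports 0 and keeps the test valid.
#'
#' @param y numeric outcome vector (`NA` = missing).
#' @param z observed arm labels, `"T"`/`"C"`.
#' @param stratum integer stratum label per subject.
#' @param statistic a [test_statistic] or a registry name
#'   (see [get_statistic()]).
#' @param scheme optional [randomization_scheme]; when supplied, `z` (and
#'   `stratum`) are checked for consistency against it.
#' @param mode `"exact"` or `"monte_carlo"`.
#' @param B Monte-Carlo draws.
#' @param seed seed for Monte-Carlo sampling.
#' @param cap exact-mode cap on enumerated vectors.
#' @return An object of class `perm_test`: `p_value`, `n_permutations`,
#'   `method`, `observed_statistic`, `attainable_p` (exact mode),
#'   `statistic`, `direction`, `stratified`, `degenerate`.
#' @examples
#' y <- c(1, 1, 1, 0, 0, 0)               # three events, then three non-events
#' z <- c("C", "C", "C", "T", "T", "T")
#' permutation_pvalue(y, z, statistic = "diff_props")   # p = 1/20
#' @export
permutation_pvalue <- function(y, z, statistic = "diff_means", scheme = NULL,
                               mode = c("exact", "monte_carlo"), B = 10000L,
                               seed = NULL, cap = 1e6) {
  mode <- match.arg(mode)
  stratum <- rep(1L, length(y))
  if (!is.null(scheme)) .check_consistent(z, stratum, scheme)
  .perm_test(y, z, stratum, statistic, mode, B, seed, cap)
}

#' @rdname permutation_pvalue
#' @export
stratified_permutation_pvalue <- function(y, z, stratum,
                                          statistic = "diff_means",
                                          scheme = NULL,
                                          mode = c("exact", "monte_carlo"),
                                          B = 10000L, seed = NULL, cap = 1e6) {
  mode <- match.arg(mode)
  if (length(stratum) != length(y)) stopf("stratum must have one label per subject")
  if (!is.null(scheme)) .check_consistent(z, stratum, scheme)
  .perm_test(y, z, as.integer(stratum), statistic, mode, B, seed, cap)
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s%s permutation test (%s, %s values favor treatment)\n",
              if (x$stratified) "Stratified " else "",
              x$method, x$statistic, x$direction))
  cat(sprintf("  observed statistic = %s over %s assignment%s\n",
              format(x$observed_statistic), format(x$n_permutations),
              if (x$method == "exact") "s" else " draws"))
  cat(sprintf("  p-value = %g%s\n", x$p_value,
              if (x$degenerate) " (degenerate statistic)" else ""))
  invisible(x)
}

#' One-sided Fisher exact p-value for a 2x2 table
#'
#' Hypergeometric tail probability of tables at least as extreme as the one
#' observed, in the stated direction, with all margins fixed. This equals the
#' exact permutation test of the difference in proportions on the underlying
#' subject-level data. An empty margin leaves a single possible table and
#' p = 1.
#'
#' @param table 2x2 integer matrix: rows T, C; columns events, non-events.
#' @param direction `"fewer_T"` (fewer events on treatment are favorable, the
#'   lower hypergeometric tail) or `"more_T"`.
#' @return The one-sided p-value.
#' @examples
#' fisher_exact_one_sided(rbind(T = c(0, 3), C = c(3, 0)))  # 1/20
#' @export
fisher_exact_one_sided <- function(table, direction = c("fewer_T", "more_T")) {
  direction <- match.arg(direction)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) || any(table != round(table)))
    stopf("table must be a 2x2 matrix of nonnegative integer counts")
  x_T <- table[1L, 1L]
  m <- sum(table[, 1L])          # total events
  n <- sum(table)
  n_T <- sum(table[1L, ])
  if (direction == "fewer_T") {
    stats::phyper(x_T, m, n - m, n_T)
  } else {
    stats::phyper(x_T - 1, m, n - m, n_T, lower.tail = FALSE)
  }
}

#' Attainable size of the exact permutation test
#'
#' The conditional type I error rate of the level-`alpha` permutation test
#' given the outcomes: the fraction of consistent assignment vectors whose
#' own permutation p-value is at most `alpha`. Because p-values are uniform
#' on the attainable grid under the null, this can never exceed `alpha` —
#' the conditional validity guarantee of the randomization test.
#'
#' @inheritParams permutation_pvalue
#' @param alpha nominal one-sided level.
#' @param stratum optional stratum labels (default: one stratum); the scheme
#'   must match the per-stratum sizes.
#' @return The attainable size, a number in `[0, alpha]`.
#' @examples
#' attainable_size(c(1, 1, 1, 0, 0, 0), "diff_props",
#'                 randomization_scheme(3, 3), alpha = 0.05)
#' @export
attainable_size <- function(y, statistic, scheme, alpha, stratum = NULL,
                            cap = 1e6) {
  statistic <- get_statistic(statistic)
  stratum <- stratum %||% rep(1L, length(y))
  idx <- .stratum_idx(stratum)
  if (length(idx) != length(scheme$n_T) ||
      any(lengths(idx) != scheme$n_T + scheme$n_C))
    stopf("scheme does not match the per-stratum sample sizes")
  Tmat <- .enumerate_T(idx, scheme$n_T, cap)
  tv <- .stat_values(y, Tmat, statistic)
  # p-value of every assignment, via tied-group cumulative fractions
  o <- order(tv, decreasing = (statistic$direction == "larger"))
  st <- tv[o]
  nv <- length(st)
  gap <- if (nv > 1L) abs(diff(st)) > 1e-12 * pmax(1, abs(st[-nv])) else logical(0)
  grp <- cumsum(c(TRUE, gap))
  pgrp <- cumsum(tabulate(grp)) / nv
  pv <- numeric(nv)
  pv[o] <- pgrp[grp]
  mean(pv <= alpha + 1e-12)
}
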