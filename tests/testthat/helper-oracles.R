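# Independent brute-force oracles, written without touching engine internals.

# All assignment vectors with n_T treatment labels among n subjects.
oracle_assignments <- function(n, n_T) {
  sets <- utils::combn(n, n_T)
  lapply(seq_len(ncol(sets)), function(j) {
    z <- rep("C", n); z[sets[, j]] <- "T"; z
  })
}

# Exact one-sided permutation p-value by direct enumeration.
oracle_perm_p <- function(y, z, stat_fun, direction = "smaller") {
  zs <- oracle_assignments(length(y), sum(z == "T"))
  tv <- vapply(zs, function(zz) as.numeric(stat_fun(y, zz)), numeric(1))
  t0 <- as.numeric(stat_fun(y, z))
  if (direction == "smaller") mean(tv <= t0 + 1e-12) else mean(tv >= t0 - 1e-12)
}

# Stratified enumeration: cartesian product of per-stratum assignments.
oracle_strat_perm_p <- function(y, z, stratum, stat_fun, direction = "smaller") {
  strata <- sort(unique(stratum))
  per <- lapply(strata, function(s) {
    idx <- which(stratum == s)
    sets <- utils::combn(length(idx), sum(z[idx] == "T"))
    lapply(seq_len(ncol(sets)), function(j) idx[sets[, j]])
  })
  grids <- expand.grid(lapply(per, seq_along))
  tv <- vapply(seq_len(nrow(grids)), function(i) {
    zz <- rep("C", length(y))
    for (s in seq_along(per)) zz[per[[s]][[grids[i, s]]]] <- "T"
    as.numeric(stat_fun(y, zz))
  }, numeric(1))
  t0 <- as.numeric(stat_fun(y, z))
  if (direction == "smaller") mean(tv <= t0 + 1e-12) else mean(tv >= t0 - 1e-12)
}

# Genuine per-vector enumeration of second-stage outcomes for the conditional
# rejection probability: every vector in {0,1}^(n_T2+n_C2) with its Bernoulli
# probability and the one-sided Fisher decision on the completed trial.
oracle_crp <- function(n_T1, n_C1, e_T1, e_C1, n_T2, n_C2, p_T, p_C, alpha) {
  k <- n_T2 + n_C2
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  total <- 0
  for (i in seq_len(nrow(grid))) {
    v <- grid[i, ]
    vT <- if (n_T2) v[seq_len(n_T2)] else integer(0)
    vC <- if (n_C2) v[n_T2 + seq_len(n_C2)] else integer(0)
    pr <- prod(ifelse(vT == 1, p_T, 1 - p_T)) * prod(ifelse(vC == 1, p_C, 1 - p_C))
    tab <- rbind(c(e_T1 + sum(vT), n_T1 + n_T2 - e_T1 - sum(vT)),
                 c(e_C1 + sum(vC), n_C1 + n_C2 - e_C1 - sum(vC)))
    p <- stats::fisher.test(tab, alternative = "less")$p.value
    if (p <= alpha + 1e-12) total <- total + pr
  }
  total
}

with_seed_for_test <- function(seed, code) withr::with_seed(seed, code)

# A small random trial with two correlated continuous endpoints under the
# strong null; used by blinding-contract and property tests.
random_null_trial <- function(seed, n_T = 4, n_C = 4, with_drug = FALSE) {
  eps <- list(ep_continuous("a"), ep_continuous("b", sd = 2))
  if (with_drug) eps <- c(eps, list(ep_drug_level("drug")))
  generate_trial(generator_config(n_T, n_C, eps, rho = 0.3), seed = seed)
}

# Flip every arm label.
relabel <- function(trial) {
  trial$arm <- ifelse(trial$arm == "T", "C", "T")
  trial
}
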