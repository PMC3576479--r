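#' Endpoint specifications for the synthetic trial generator
#'
#' Three endpoint kinds cover the designs the package studies:
#' * `ep_continuous()` — Gaussian margins with arm-specific means and a common
#'   standard deviation. All continuous endpoints in one trial share a single
#'   exchangeable pairwise correlation (Gaussian copula), set in
#'   [generator_config()].
#' * `ep_binary()` — independent Bernoulli events with arm-specific
#'   probabilities (`p_T` is the treatment-arm event probability).
#' * `ep_drug_level()` — level of the experimental drug in the blood: strictly
#'   positive (log-normal) in every treatment subject and exactly zero in
#'   every control subject. Its blinded, lumped values therefore reveal the
#'   arm labels; it exists to drive the adversarial adaptation rules.
#'
#' @param name endpoint (column) name.
#' @param mean_T,mean_C,sd continuous margins per arm.
#' @param p_T,p_C event probabilities per arm.
#' @param meanlog,sdlog log-normal parameters of the treatment-arm drug level.
#' @return An endpoint spec (a list) consumed by [generator_config()].
#' @export
ep_continuous <- function(name, mean_T = 0, mean_C = 0, sd = 1) {
  stopifnot(sd > 0)
  list(name = name, type = "continuous", mean_T = mean_T, mean_C = mean_C, sd = sd)
}

#' @rdname ep_continuous
#' @export
ep_binary <- function(name, p_T = 0.5, p_C = 0.5) {
  if (p_T < 0 || p_T > 1 || p_C < 0 || p_C > 1)
    stopf("event probabilities must be in [0, 1]")
  list(name = name, type = "binary", p_T = p_T, p_C = p_C)
}

#' @rdname ep_continuous
#' @export
ep_drug_level <- function(name = "drug_level", meanlog = 0, sdlog = 0.25) {
  list(name = name, type = "drug_level", meanlog = meanlog, sdlog = sdlog)
}

#' Configuration for the synthetic trial generator
#'
#' @param n_T,n_C per-arm sizes. Vectors give fixed per-arm counts per
#'   enrollment stratum (stratum `s` holds `n_T[s]` treatment and `n_C[s]`
#'   control subjects). Scalars with `split_after` instead emulate complete
#'   randomization with a known interim: the `n_T + n_C` arm labels are placed
#'   in uniformly random enrollment order and stratum 1 is the first
#'   `split_after` subjects, so the interim per-arm counts vary from trial to
#'   trial as they would in practice.
#' @param endpoints list of endpoint specs from [ep_continuous()],
#'   [ep_binary()], [ep_drug_level()].
#' @param rho exchangeable pairwise correlation among continuous endpoints.
#'   Must keep the correlation matrix positive semi-definite
#'   (`rho >= -1/(k-1)` for `k` continuous endpoints).
#' @param missingness named list, one entry per endpoint to be thinned:
#'   either a single rate or `c(T = rate_T, C = rate_C)` for arm-dependent
#'   (potentially informative) missingness.
#' @param split_after integer: interim position for the random-split mode.
#' @param seed default seed used by [generate_trial()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_T, n_C, endpoints, rho = 0,
                             missingness = NULL, split_after = NULL, seed = 1L) {
  if (length(n_T) != length(n_C)) stopf("n_T and n_C must have equal length")
  if (any(n_T < 0) || any(n_C < 0)) stopf("arm counts must be nonnegative")
  if (sum(n_T) + sum(n_C) < 2L) stopf("need at least 2 subjects in total")
  if (any(n_T + n_C == 0L)) stopf("every stratum needs at least one subject")
  if (!is.null(split_after)) {
    if (length(n_T) != 1L)
      stopf("split_after requires scalar n_T, n_C (complete randomization)")
    if (split_after < 1L || split_after >= n_T + n_C)
      stopf("split_after must be in [1, n - 1]")
  }
  nms <- vapply(endpoints, `[[`, "", "name")
  if (anyDuplicated(nms)) stopf("duplicate endpoint names")
  k <- sum(vapply(endpoints, `[[`, "", "type") == "continuous")
  if (k > 1L && (rho > 1 || rho < -1 / (k - 1)))
    stopf("rho = %g makes the %d-endpoint correlation matrix indefinite", rho, k)
  if (!is.null(missingness)) {
    if (is.null(names(missingness)) || !all(names(missingness) %in% nms))
      stopf("missingness must be a named list over endpoint names")
    for (r in missingness)
      if (any(r < 0) || any(r > 1)) stopf("missingness rates must be in [0, 1]")
  }
  structure(list(n_T = as.integer(n_T), n_C = as.integer(n_C),
                 endpoints = endpoints, rho = rho, missingness = missingness,
                 split_after = if (is.null(split_after)) NULL else as.integer(split_after),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic two-arm trial
#'
#' Reproducible given the seed. Under a strong-null configuration (identical
#' margins in both arms, no arm-dependent missingness) the joint outcome
#' distribution does not depend on the arm assignment, which is exactly the
#' exchangeability a permutation test requires; a drug-level endpoint breaks
#' the strong null by construction.
#'
#' @param config a [generator_config()].
#' @param seed overrides `config$seed`.
#' @return A [trial_data] object. Arm order within the trial is randomized.
#' @export
generate_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  seed <- seed %||% config$seed
  with_seed(seed, {
    if (is.null(config$split_after)) {
      arm <- unlist(lapply(seq_along(config$n_T), function(s) {
        sample(rep(c("T", "C"), c(config$n_T[s], config$n_C[s])))
      }))
      stratum <- rep(seq_along(config$n_T), config$n_T + config$n_C)
    } else {
      arm <- sample(rep(c("T", "C"), c(config$n_T, config$n_C)))
      stratum <- rep(c(1L, 2L), c(config$split_after,
                                  length(arm) - config$split_after))
    }
    n <- length(arm)
    isT <- arm == "T"

    types <- vapply(config$endpoints, `[[`, "", "type")
    cont <- which(types == "continuous")
    Zc <- NULL
    if (length(cont)) {
      k <- length(cont)
      Z <- matrix(stats::rnorm(n * k), n, k)
      if (k > 1L && config$rho != 0) {
        R <- matrix(config$rho, k, k); diag(R) <- 1
        Z <- Z %*% chol(R)
      }
      Zc <- Z
    }
    M <- matrix(NA_real_, n, length(config$endpoints),
                dimnames = list(NULL, vapply(config$endpoints, `[[`, "", "name")))
    ci <- 0L
    for (j in seq_along(config$endpoints)) {
      ep <- config$endpoints[[j]]
      M[, j] <- switch(ep$type,
        continuous = {
          ci <- ci + 1L
          mu <- ifelse(isT, ep$mean_T, ep$mean_C)
          mu + ep$sd * Zc[, ci]
        },
        binary = {
          p <- ifelse(isT, ep$p_T, ep$p_C)
          as.numeric(stats::runif(n) < p)
        },
        drug_level = ifelse(isT, stats::rlnorm(n, ep$meanlog, ep$sdlog), 0),
        stopf("unknown endpoint type '%s'", ep$type))
    }
    if (!is.null(config$missingness)) {
      for (nm in names(config$missingness)) {
        r <- config$missingness[[nm]]
        rate <- if (length(r) == 1L) rep(r, n) else ifelse(isT, r[["T"]], r[["C"]])
        M[stats::runif(n) < rate, nm] <- NA
      }
    }
    trial_data(sprintf("s%03d", seq_len(n)), arm, stratum, M)
  })
}
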