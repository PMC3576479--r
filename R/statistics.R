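#' Test statistics t(y, z)
#'
#' Each test statistic is a pure function of an outcome vector `y` and an arm
#' assignment vector `z` (labels `"T"`/`"C"`), so the permutation engine can
#' re-evaluate it under every consistent relabeling. The statistic carries its
#' own one-sided orientation (`direction`): `"smaller"` means smaller values
#' favor treatment (e.g. a larger drop in blood pressure, fewer events), so
#' the permutation p-value counts relabelings with a statistic at least as
#' small as observed; `"larger"` is the mirror image. Carrying the direction
#' on the statistic rather than at each call site prevents sign errors when an
#' adaptation rule switches statistics.
#'
#' Missing values are excluded per endpoint (available-case); the number of
#' exclusions is attached as attribute `n_excluded` because missingness counts
#' are themselves information a blinded adaptation may have examined.
#'
#' @param name identifier, used in plans and reports.
#' @param direction `"smaller"` or `"larger"` (which tail favors treatment).
#' @param evaluate `function(y, z)` returning a single number.
#' @return `test_statistic()` returns an object of class `test_statistic`.
#' @seealso [get_statistic()] for the by-name registry.
#' @export
test_statistic <- function(name, direction = c("smaller", "larger"), evaluate) {
  direction <- match.arg(direction)
  structure(list(name = name, direction = direction, evaluate = evaluate),
            class = "test_statistic")
}

#' @export
print.test_statistic <- function(x, ...) {
  cat(sprintf("Test statistic '%s' (%s values favor treatment)\n",
              x$name, x$direction))
  invisible(x)
}

# Available-case split of y by arm; errors if an arm has no observed value.
.split_arms <- function(y, z) {
  keep <- !is.na(y)
  yT <- y[keep & z == "T"]
  yC <- y[keep & z == "C"]
  if (!length(yT) || !length(yC))
    stopf("an arm has no non-missing values for this endpoint")
  structure(list(yT = yT, yC = yC), n_excluded = sum(!keep))
}

#' Difference in means / proportions
#'
#' `diff_means()` returns `mean(T) - mean(C)` on available cases; on 0/1 data
#' `diff_props()` is the same quantity, the event-rate difference T minus C
#' (its permutation test is equivalent to Fisher's exact test).
#'
#' @param y numeric outcome vector (0/1 for `diff_props`); `NA` allowed.
#' @param z arm labels, `"T"`/`"C"`.
#' @return A single number with attribute `n_excluded`.
#' @export
diff_means <- function(y, z) {
  a <- .split_arms(y, z)
  structure(mean(a$yT) - mean(a$yC), n_excluded = attr(a, "n_excluded"))
}

#' @rdname diff_means
#' @export
diff_props <- function(y, z) {
  obs <- y[!is.na(y)]
  if (length(obs) && !all(obs %in% c(0, 1)))
    stopf("diff_props needs a binary (0/1) outcome")
  diff_means(y, z)
}

#' Wilcoxon rank sum (treatment arm)
#'
#' Sum of the treatment-arm ranks among the pooled non-missing values, with
#' mid-ranks for ties. Over both arms ranks always total n(n+1)/2.
#'
#' @inheritParams diff_means
#' @export
wilcoxon_rank_sum <- function(y, z) {
  keep <- !is.na(y)
  a <- .split_arms(y, z)  # validates both arms non-empty
  r <- rank(y[keep])
  structure(sum(r[z[keep] == "T"]), n_excluded = sum(!keep))
}

#' Signed-rank statistic for paired (crossover) differences
#'
#' Zero differences are excluded before ranking the absolute values (the
#' standard convention: a subject with identical scores on treatment and
#' placebo carries no information about direction). Returns the sum of the
#' ranks attached to positive differences. When every difference is zero the
#' statistic is degenerate — there is nothing left to rank — and the function
#' returns `NA` flagged with attribute `degenerate = TRUE`, which the engine
#' distinguishes from an error and propagates as p = 1.
#'
#' @param d numeric vector of paired (treatment minus control) differences.
#' @return The positive-rank sum, or a degenerate-flagged `NA`.
#' @export
signed_rank_paired <- function(d) {
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (!length(d))
    return(structure(NA_real_, degenerate = TRUE, n_zero = n_zero))
  r <- rank(abs(d))
  structure(sum(r[d > 0]), degenerate = FALSE, n_zero = n_zero)
}

#' @rdname signed_rank_paired
#' @param x a statistic value.
#' @export
is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))

#' Look up a test statistic by name
#'
#' Registry used wherever plans or scenario configs name a statistic:
#' `"diff_means"`, `"diff_props"`, `"wilcoxon"` (rank sum), `"signed_rank"`.
#' Default orientations assume smaller outcomes favor treatment (blood
#' pressure changes, event indicators); pass `direction` to flip.
#'
#' @param name statistic name.
#' @param direction optional override of the default orientation.
#' @return A [test_statistic] object.
#' @export
get_statistic <- function(name, direction = NULL) {
  if (inherits(name, "test_statistic")) {
    if (!is.null(direction)) name$direction <- match.arg(direction, c("smaller", "larger"))
    return(name)
  }
  ev <- switch(name,
    diff_means = diff_means,
    diff_props = diff_props,
    wilcoxon = wilcoxon_rank_sum,
    signed_rank = function(y, z) signed_rank_paired(y),
    stopf("unknown statistic '%s'", name))
  test_statistic(name, direction %||% "smaller", ev)
}
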