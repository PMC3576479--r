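#' Two-arm trial data
#'
#' Container for per-subject data from a randomized two-arm trial: the arm
#' assignment vector (labels `"T"` and `"C"`), an enrollment stratum per
#' subject (enrollment period relative to a potential adaptation; a single
#' stratum means the blind was complete throughout), and a subject-by-endpoint
#' outcome matrix. Missing outcome values are `NA`. Binary endpoints must
#' contain only 0, 1 and `NA`.
#'
#' @param subject_id character or integer vector of unique subject identifiers.
#' @param arm character vector of arm labels, each `"T"` or `"C"`.
#' @param stratum integer vector of stratum labels (contiguous, starting at 1).
#'   A scalar is recycled. Default: one stratum.
#' @param outcomes numeric matrix (or data frame) of outcomes, one column per
#'   endpoint, with column names.
#' @return An object of class `trial_data` with elements `subject_id`, `arm`,
#'   `stratum`, `outcomes`.
#' @examples
#' td <- trial_data(1:6, rep(c("C", "T"), each = 3),
#'                  outcomes = cbind(resp = c(1, 1, 1, 0, 0, 0)))
#' td
#' @export
trial_data <- function(subject_id, arm, stratum = 1L, outcomes) {
  if (is.data.frame(outcomes)) outcomes <- as.matrix(outcomes)
  if (is.null(dim(outcomes))) outcomes <- cbind(y = outcomes)
  n <- length(subject_id)
  if (length(stratum) == 1L) stratum <- rep(as.integer(stratum), n)
  x <- structure(
    list(subject_id = as.character(subject_id),
         arm = as.character(arm),
         stratum = as.integer(stratum),
         outcomes = outcomes),
    class = "trial_data")
  validate_trial_data(x)
}

#' @rdname trial_data
#' @param x a `trial_data` object.
#' @export
validate_trial_data <- function(x) {
  n <- length(x$subject_id)
  if (n < 2L) stopf("a trial needs at least 2 subjects, got %d", n)
  if (length(x$arm) != n || length(x$stratum) != n || nrow(x$outcomes) != n)
    stopf("subject_id, arm, stratum and outcomes must all have length/rows %d", n)
  bad <- which(!x$arm %in% c("T", "C"))
  if (length(bad))
    stopf("unknown arm label '%s' in row %d (arms must be 'T' or 'C')",
          x$arm[bad[1]], bad[1])
  if (anyDuplicated(x$subject_id))
    stopf("duplicate subject_id: '%s'",
          x$subject_id[anyDuplicated(x$subject_id)])
  s <- sort(unique(x$stratum))
  if (!identical(s, seq_along(s)))
    stopf("strata must be contiguous integers starting at 1")
  if (is.null(colnames(x$outcomes)))
    stopf("outcome columns must be named")
  for (j in colnames(x$outcomes)) {
    v <- x$outcomes[, j]
    obs <- v[!is.na(v)]
    if (length(obs) && all(obs %in% c(0, 1))) next  # valid binary (or constant)
    if (!is.numeric(v)) stopf("endpoint '%s' is not numeric", j)
  }
  x
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Two-arm trial: n = %d (T = %d, C = %d), %d strat%s, endpoints: %s\n",
              length(x$arm), sum(x$arm == "T"), sum(x$arm == "C"),
              length(unique(x$stratum)),
              if (length(unique(x$stratum)) == 1L) "um" else "a",
              paste(colnames(x$outcomes), collapse = ", ")))
  invisible(x)
}

#' @export
summary.trial_data <- function(object, ...) {
  counts <- table(stratum = object$stratum, arm = object$arm)
  miss <- colSums(is.na(object$outcomes))
  out <- list(counts = counts, missing = miss, n = length(object$arm))
  class(out) <- "summary.trial_data"
  out
}

#' @export
print.summary.trial_data <- function(x, ...) {
  cat("Per-stratum arm counts:\n")
  print(x$counts)
  cat("Missing values per endpoint:\n")
  print(x$missing)
  invisible(x)
}

#' Read and write trial data as CSV
#'
#' The CSV dialect is RFC-4180 with a header row. Columns are `subject_id`,
#' `arm`, `stratum`, then one column per endpoint. Missing outcome cells are
#' encoded by `missing_token` (default: the empty string), so a
#' `write_trial()` / `read_trial()` round trip reproduces the table
#' cell-for-cell.
#'
#' @param path file path.
#' @param missing_token string encoding a missing outcome cell.
#' @return `read_trial()` returns a validated [trial_data] object.
#' @export
read_trial <- function(path, missing_token = "") {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character())
  need <- c("subject_id", "arm", "stratum")
  if (!all(need %in% names(df)))
    stopf("CSV must have columns %s", paste(need, collapse = ", "))
  eps <- setdiff(names(df), need)
  if (!length(eps)) stopf("CSV has no endpoint columns")
  bad <- which(!df$arm %in% c("T", "C"))
  if (length(bad))
    stopf("unknown arm label '%s' in data row %d", df$arm[bad[1]], bad[1])
  out <- sapply(eps, function(j) {
    v <- df[[j]]
    v[v == missing_token] <- NA
    as.numeric(v)
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(df), dimnames = list(NULL, eps))
  trial_data(df$subject_id, df$arm, as.integer(df$stratum), out)
}

#' @rdname read_trial
#' @param trial a [trial_data] object.
#' @export
write_trial <- function(trial, path, missing_token = "") {
  M <- trial$outcomes
  chr <- apply(M, 2, function(v) {
    s <- as.character(v)
    s[is.na(v)] <- missing_token
    s
  })
  if (is.null(dim(chr))) chr <- matrix(chr, nrow = nrow(M), dimnames = dimnames(M))
  df <- data.frame(subject_id = trial$subject_id, arm = trial$arm,
                   stratum = trial$stratum, chr, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = missing_token)
  invisible(path)
}
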