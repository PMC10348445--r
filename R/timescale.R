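#' Sample autocorrelation function of a signal
#'
#' Standard biased ACF estimator
#' \deqn{\hat\rho(k) = \sum_t (x_t - \bar x)(x_{t+k} - \bar x) /
#'   \sum_t (x_t - \bar x)^2,}
#' which is bounded by 1 in magnitude. One time bin equals one sampling
#' interval (TR).
#'
#' @param signal numeric vector, length >= 3, nonzero variance.
#' @param max_lag largest lag estimated; default `min(T - 1, 100)`.
#' @param tr_seconds sampling interval in seconds (time per bin).
#' @return an `acf_series`: list with `lags` (0..max_lag), `values`
#'   (`values[1] == 1` at lag 0) and `tr_seconds`.
#' @export
sample_acf <- function(signal, max_lag = NULL, tr_seconds = 1) {
  signal <- as.numeric(signal)
  if (length(signal) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  if (!all(is.finite(signal))) stop("non-finite signal values", call. = FALSE)
  if (stats::var(signal) == 0) {
    stop("constant signal has no autocorrelation", call. = FALSE)
  }
  if (is.null(max_lag)) max_lag <- min(length(signal) - 1L, 100L)
  stopifnot(max_lag >= 1, tr_seconds > 0)
  a <- stats::acf(signal, lag.max = max_lag, plot = FALSE, demean = TRUE)
  structure(list(lags = 0:max_lag, values = as.numeric(a$acf),
                 tr_seconds = tr_seconds),
            class = "acf_series")
}

#' Intrinsic neural timescale from an ACF
#'
#' Sums the initial positive lobe of the autocorrelation function: with
#' `k*` the smallest lag >= 1 at which the ACF is zero or below (taken as
#' `max_lag + 1` when the ACF never touches zero), the timescale is
#' \deqn{INT = TR \times \sum_{k=1}^{k^*-1} \rho(k),}
#' in seconds. The lag-0 term (identically 1) is excluded by default; set
#' `include_lag0 = TRUE` to add one TR-worth of area for sensitivity checks.
#' A signal whose lag-1 autocorrelation is already nonpositive has INT 0
#' (or TR, with lag 0 included). Short timescales indicate fast, unstable
#' fluctuations; long timescales indicate slowly varying activity.
#'
#' @param acf an [sample_acf()] result.
#' @param include_lag0 include the lag-0 term in the sum.
#' @return timescale in seconds (nonnegative).
#' @export
intrinsic_timescale <- function(acf, include_lag0 = FALSE) {
  stopifnot(inherits(acf, "acf_series"))
  v <- acf$values[-1L]  # lags 1..L
  hit <- which(v <= 0)
  upto <- if (length(hit)) hit[1] - 1L else length(v)
  s <- if (upto >= 1L) sum(v[seq_len(upto)]) else 0
  if (include_lag0) s <- s + 1
  acf$tr_seconds * s
}

#' Intrinsic timescale map over signal units
#'
#' Applies [sample_acf()] + [intrinsic_timescale()] to every column of a
#' timepoints x units signal matrix (units may be network nodes, regions or
#' voxels). Constant columns are flagged and receive `NA`.
#'
#' @param signals T x U numeric matrix; column names label the units.
#' @param tr_seconds sampling interval in seconds.
#' @param max_lag passed to [sample_acf()].
#' @param include_lag0 passed to [intrinsic_timescale()].
#' @param subject_id optional label.
#' @return a `timescale_map`: list with `unit_ids`, `int_values` (named,
#'   seconds), `tr_seconds`, `subject_id`.
#' @export
timescale_map <- function(signals, tr_seconds = 1, max_lag = NULL,
                          include_lag0 = FALSE, subject_id = NULL) {
  signals <- as.matrix(signals)
  units <- colnames(signals)
  if (is.null(units)) units <- paste0("unit", seq_len(ncol(signals)))
  vars <- apply(signals, 2, stats::var)
  if (all(vars == 0)) stop("all signal columns are constant", call. = FALSE)
  vals <- vapply(seq_len(ncol(signals)), function(j) {
    if (vars[j] == 0) return(NA_real_)
    intrinsic_timescale(sample_acf(signals[, j], max_lag, tr_seconds),
                        include_lag0)
  }, numeric(1))
  names(vals) <- units
  structure(list(unit_ids = units, int_values = vals,
                 tr_seconds = tr_seconds, subject_id = subject_id),
            class = "timescale_map")
}

#' Mean timescale over a named unit subset
#'
#' Network-level timescale: arithmetic mean of the intrinsic timescales of
#' the member units (e.g., all nodes of the dorsal attention network).
#'
#' @param map a [timescale_map()].
#' @param units character vector of member unit ids.
#' @export
network_timescale <- function(map, units) {
  stopifnot(inherits(map, "timescale_map"))
  missing <- setdiff(units, map$unit_ids)
  if (length(missing)) {
    stop("unknown units: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  mean(map$int_values[units])
}
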