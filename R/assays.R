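#' Total area under an electropherogram trace
#'
#' Trapezoidal integral of fluorescence over the full (possibly non-uniform)
#' size axis. Used for loading normalization: samples are conventionally
#' rescaled to their total AUC rather than to instrument concentration
#' estimates.
#'
#' @param trace an [electropherogram()] (or any data.frame with `size_nt`,
#'   `fluorescence`).
#' @return area in fluorescence units x nt.
#' @export
trace_total_auc <- function(trace) {
  x <- trace$size_nt
  y <- trace$fluorescence
  if (is.null(x) || is.null(y) || length(x) < 2) {
    stop("a trace needs at least 2 (size, fluorescence) points")
  }
  if (any(!is.finite(y))) stop("fluorescence must be finite")
  trapezoid(x, y)
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Normalize traces to their mean total AUC
#'
#' Divides each trace by its own total AUC and multiplies by the mean AUC
#' across all input traces, so every output trace has total AUC equal to the
#' input mean. This removes differences in loaded RNA amount while preserving
#' the mean scale of the batch.
#'
#' @param traces list of [electropherogram()] objects.
#' @return list of traces, same order, each with total AUC equal to the input
#'   mean AUC.
#' @export
normalize_traces <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1)
  aucs <- vapply(traces, trace_total_auc, numeric(1))
  if (any(aucs <= 0)) {
    bad <- vapply(traces[aucs <= 0], function(tr) {
      id <- attr(tr, "sample_id"); if (is.null(id)) "<unnamed>" else id
    }, character(1))
    stop("zero or negative total AUC for sample(s): ", paste(bad, collapse = ", "))
  }
  target <- mean(aucs)
  mapply(function(tr, a) {
    tr$fluorescence <- tr$fluorescence / a * target
    tr
  }, traces, aucs, SIMPLIFY = FALSE)
}

#' Regional AUC of a trace
#'
#' Trapezoidal integral restricted to a size interval, with linear
#' interpolation of the trace at the region boundaries; also returns the
#' region's share of the total AUC. This quantifies degradation-fragment
#' abundance in a fixed window (by default the sub-18S smear region where
#' collateral-cleavage fragments accumulate).
#'
#' @param trace an [electropherogram()].
#' @param region numeric pair `c(lo, hi)` in nt; default `c(200, 1700)`.
#' @return list with `area` and `fraction` (of the total AUC).
#' @export
region_auc <- function(trace, region = c(200, 1700)) {
  stopifnot(length(region) == 2, region[2] > region[1])
  total <- trace_total_auc(trace)
  x <- trace$size_nt
  y <- trace$fluorescence
  lo <- max(region[1], x[1])
  hi <- min(region[2], x[length(x)])
  if (hi <= lo) {
    warning("region [", region[1], ", ", region[2], "] outside the trace axis")
    return(list(area = 0, fraction = 0))
  }
  inner <- x > lo & x < hi
  xs <- c(lo, x[inner], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[inner],
          stats::approx(x, y, xout = hi)$y)
  area <- trapezoid(xs, ys)
  list(area = area, fraction = if (total > 0) area / total else NA_real_)
}

#' Initial-slope collateral cleavage rate from a fluorescence time series
#'
#' Least-squares slope of signal vs time over the initial linear window of an
#' in vitro cleavage reporter assay. With `window = "auto"` the window is the
#' longest prefix (at least 3 points) whose own fit has residual RMS below
#' `rms_frac` of the full signal range; a fixed window `c(t0, t1)` (minutes)
#' is also supported.
#'
#' @param series data.frame with increasing `time` (min) and `signal`.
#' @param window `"auto"` or a numeric pair of times.
#' @param rms_frac residual RMS tolerance as a fraction of the signal range.
#' @return slope in signal units per minute.
#' @export
fluorescence_slope <- function(series, window = "auto", rms_frac = 0.02) {
  t <- series$time
  y <- series$signal
  if (is.null(t) || is.null(y) || length(t) < 3) {
    stop("a fluorescence series needs at least 3 points")
  }
  if (any(diff(t) <= 0)) stop("time must be increasing")
  if (identical(window, "auto")) {
    rng <- diff(range(y))
    if (rng == 0) return(0)
    best <- NULL
    for (k in length(t):3) {
      fit <- stats::lm.fit(cbind(1, t[1:k]), y[1:k])
      rms <- sqrt(mean(fit$residuals^2))
      if (rms < rms_frac * rng) { best <- k; break }
    }
    if (is.null(best)) best <- 3L
    idx <- seq_len(best)
  } else {
    idx <- which(t >= window[1] & t <= window[2])
    if (length(idx) < 3) stop("slope window must contain at least 3 points")
  }
  unname(stats::lm.fit(cbind(1, t[idx]), y[idx])$coefficients[2])
}
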