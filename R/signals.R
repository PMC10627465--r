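#' Regularly sampled series
#'
#' Light container for a uniformly sampled scalar or vector-valued signal,
#' the carrier type for all filtering and differentiation primitives.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing and
#'   nominally uniform.
#' @param values Numeric vector (scalar signal) or matrix with one row per
#'   sample (vector signal).
#' @param rate_hz Nominal sampling rate in Hz. If `NULL`, inferred as the
#'   reciprocal of the median sampling interval.
#'
#' @return An object of class `sampled_series`: a list with elements `t`,
#'   `values` (always a matrix, columns = signal components) and `rate_hz`.
#' @export
#' @examples
#' s <- sampled_series(seq(0, 1, by = 1 / 120), sin(2 * pi * seq(0, 1, by = 1 / 120)))
#' s$rate_hz
sampled_series <- function(t, values, rate_hz = NULL) {
  t <- as.numeric(t)
  if (length(t) < 2L) stop("sampled_series needs at least 2 samples")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  if (nrow(values) != length(t)) stop("values must have one row per timestamp")
  med_dt <- stats::median(diff(t))
  if (is.null(rate_hz)) rate_hz <- 1 / med_dt
  if (abs(med_dt - 1 / rate_hz) >= 0.1 / rate_hz) {
    stop("median sampling interval deviates more than 10% from 1/rate_hz")
  }
  structure(list(t = t, values = values, rate_hz = rate_hz),
            class = "sampled_series")
}

#' @export
print.sampled_series <- function(x, ...) {
  cat(sprintf("<sampled_series> %d samples x %d channels @ %.6g Hz, t in [%.4g, %.4g] s\n",
              nrow(x$values), ncol(x$values), x$rate_hz, x$t[1], x$t[length(x$t)]))
  invisible(x)
}

as_series_like <- function(series) {
  if (!inherits(series, "sampled_series")) stop("expected a sampled_series")
  series
}

# Forward-backward filtering of one channel with odd reflection padding at
# the edges, so the two-pass (zero-phase) response applies cleanly up to the
# ends. Each pass filters the deviation from its first padded sample, which
# makes the DC gain exactly 1 and removes the zero-initial-state transient.
filtfilt_reflect <- function(filt, x, pad) {
  n <- length(x)
  p <- min(n - 1L, pad)
  head_ref <- 2 * x[1] - x[(p + 1L):2L]
  tail_ref <- 2 * x[n] - x[(n - 1L):(n - p)]
  xp <- c(head_ref, x, tail_ref)
  y <- as.numeric(signal::filter(filt, xp - xp[1])) + xp[1]
  y <- rev(y)
  y <- rev(as.numeric(signal::filter(filt, y - y[1])) + y[1])
  y[(p + 1L):(p + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter and applies it forward and backward
#' (zero-phase), so event timing is not lag-shifted. Edges are handled by odd
#' reflection padding. Because the filter runs twice, the effective magnitude
#' response is the square of the single-pass response.
#'
#' @param series A [sampled_series()].
#' @param cutoff_hz Cutoff frequency in Hz; must lie strictly below the
#'   Nyquist frequency `rate_hz / 2`.
#' @param order Filter order of each pass (the putting pipeline uses 2).
#'
#' @return A `sampled_series` of the same length and timestamps.
#' @export
butterworth_lowpass <- function(series, cutoff_hz, order = 2L) {
  series <- as_series_like(series)
  nyq <- series$rate_hz / 2
  if (!(cutoff_hz > 0 && cutoff_hz < nyq)) {
    stop(sprintf("cutoff_hz must be in (0, %g) for rate %g Hz", nyq, series$rate_hz))
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  pad <- ceiling(3 * series$rate_hz / cutoff_hz)
  out <- apply(series$values, 2L, function(x) filtfilt_reflect(bf, x, pad))
  sampled_series(series$t, matrix(out, ncol = ncol(series$values)), series$rate_hz)
}

#' Centered five-point moving average
#'
#' The kinematic de-noising filter: a centered five-sample mean, with
#' shrinking (asymmetric) windows at the series ends so length is preserved.
#' At the club's 90 Hz native rate the kernel's nominal cutoff is about 10 Hz.
#'
#' @param series A [sampled_series()] with at least 5 samples.
#' @return A `sampled_series` of the same length and timestamps.
#' @export
moving_average_5pt <- function(series) {
  series <- as_series_like(series)
  n <- nrow(series$values)
  if (n < 5L) stop("moving_average_5pt needs at least 5 samples")
  smooth1 <- function(x) {
    vapply(seq_len(n), function(i) {
      lo <- max(1L, i - 2L)
      hi <- min(n, i + 2L)
      mean(x[lo:hi])
    }, numeric(1))
  }
  out <- apply(series$values, 2L, smooth1)
  sampled_series(series$t, matrix(out, ncol = ncol(series$values)), series$rate_hz)
}

# Central differences on the interior, one-sided at the two ends.
diff_once <- function(t, x) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    d[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

#' Numerical differentiation of a sampled series
#'
#' First or second time derivative by central finite differences on interior
#' samples and one-sided differences at the ends. The second derivative is
#' the first-derivative operator applied twice.
#'
#' @param series A [sampled_series()] with at least 3 samples.
#' @param order Derivative order, 1 (velocity) or 2 (acceleration).
#' @return A `sampled_series` of the same length and timestamps.
#' @export
finite_difference <- function(series, order = 1L) {
  series <- as_series_like(series)
  if (nrow(series$values) < 3L) stop("finite_difference needs at least 3 samples")
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  out <- series$values
  for (k in seq_len(order)) {
    out <- apply(out, 2L, function(x) diff_once(series$t, x))
  }
  sampled_series(series$t, matrix(out, ncol = ncol(series$values)), series$rate_hz)
}
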