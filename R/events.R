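# Kinematic event detection: backswing onset and ball contact from the
# clubhead's x-velocity.

#' Detect swing events from a clubhead trace
#'
#' Low-pass filters the clubhead position (10 Hz zero-phase Butterworth),
#' differentiates the putt-line (x) component, and detects backswing onset
#' and ball contact by peak detection. Backswing onset is the start of the
#' sustained movement episode (|x-velocity| above the rest threshold for at
#' least `sustain_n` samples) that contains the dominant backswing velocity
#' peak. Contact is the first forward crossing of the ball plane after the
#' backswing peak. If the trace holds more than one comparable velocity-peak
#' episode (an ambiguous multi-movement trial), or no clear swing at all,
#' the trial is marked missing.
#'
#' @param club Club trace data frame: columns `t_s`, `x`, `y`, `z`.
#' @param scene A [scene_geometry()] giving the ball plane position.
#' @param rest_threshold Rest threshold on |x-velocity| (m/s).
#' @param sustain_n Minimum number of consecutive samples above threshold.
#' @param cutoff_hz Club filter cutoff (Hz); set `NULL` if already filtered.
#' @param ambiguity_ratio A second movement episode whose peak speed exceeds
#'   this fraction of the dominant peak renders the trial missing.
#' @param min_peak_speed Minimum backswing peak speed (m/s) for a swing to
#'   count at all.
#' @return A `trial_events` list: `status` (`"ok"` or `"missing"`),
#'   `swing_onset_s`, `contact_s` (NA when missing).
#' @export
detect_swing_events <- function(club, scene = scene_geometry(),
                                rest_threshold = 0.05, sustain_n = 3L,
                                cutoff_hz = 10, ambiguity_ratio = 0.5,
                                min_peak_speed = 0.2) {
  stopifnot(all(c("t_s", "x") %in% names(club)))
  t <- club$t_s
  if (t[length(t)] - t[1] < 1) stop("club trace shorter than 1 s")
  rate <- 1 / stats::median(diff(t))
  x <- club$x
  if (!is.null(cutoff_hz)) {
    x <- butterworth_lowpass(sampled_series(t, x, rate), cutoff_hz, 2L)$values[, 1]
  }
  v <- finite_difference(sampled_series(t, x, rate), 1L)$values[, 1]

  missing <- function() structure(list(status = "missing", swing_onset_s = NA_real_,
                                       contact_s = NA_real_), class = "trial_events")

  moving <- abs(v) > rest_threshold
  if (!any(moving)) return(missing())
  # movement episodes: runs of consecutive above-threshold samples
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ep <- data.frame(start = starts[r$values], end = ends[r$values])
  ep <- ep[ep$end - ep$start + 1L >= sustain_n, , drop = FALSE]
  if (!nrow(ep)) return(missing())
  # episodes separated by less than 0.5 s of rest belong to one movement
  # (backswing and downswing are split by the sub-threshold reversal); each
  # cluster of nearby episodes is one candidate swing
  cluster <- cumsum(c(1, as.integer(t[ep$start[-1]] - t[ep$end[-nrow(ep)]] > 0.5)))
  peak_by_cluster <- tapply(vapply(seq_len(nrow(ep)),
                                   function(i) max(abs(v[ep$start[i]:ep$end[i]])),
                                   numeric(1)),
                            cluster, max)
  dom <- as.integer(names(which.max(peak_by_cluster)))
  if (peak_by_cluster[[as.character(dom)]] < min_peak_speed) return(missing())
  rivals <- peak_by_cluster >= ambiguity_ratio * peak_by_cluster[[as.character(dom)]]
  rivals[as.character(dom)] <- FALSE
  if (any(rivals)) return(missing())

  # dominant backswing peak: most negative velocity inside the swing cluster
  epd <- ep[cluster == dom, , drop = FALSE]
  seg <- unlist(lapply(seq_len(nrow(epd)), function(i) epd$start[i]:epd$end[i]))
  i_back <- seg[which.min(v[seg])]
  if (v[i_back] >= 0) return(missing())
  # onset: start of the sustained run that contains the backswing peak
  run <- which(epd$start <= i_back & epd$end >= i_back)
  onset_s <- t[epd$start[run]]

  # contact: first forward (rising) crossing of the ball plane after the
  # backswing peak
  bx <- scene$ball_position[1]
  idx <- i_back:(length(x) - 1L)
  crossing <- idx[x[idx] < bx & x[idx + 1L] >= bx & v[idx] > 0]
  if (!length(crossing)) return(missing())
  i0 <- crossing[1]
  # linear interpolation inside the crossing interval
  frac <- (bx - x[i0]) / (x[i0 + 1L] - x[i0])
  contact_s <- t[i0] + frac * (t[i0 + 1L] - t[i0])
  structure(list(status = "ok", swing_onset_s = onset_s, contact_s = contact_s),
            class = "trial_events")
}

#' @export
print.trial_events <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<trial_events> ok: backswing onset %.3f s, contact %.3f s\n",
                x$swing_onset_s, x$contact_s))
  } else {
    cat("<trial_events> missing (no reliable swing)\n")
  }
  invisible(x)
}
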