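# Brute-force I-DT oracle: same greedy semantics as the production detector,
# but every window's dispersion is recomputed exhaustively from the raw
# samples (no incremental bookkeeping). Returns integer (start, end) index
# pairs so boundary agreement can be checked exactly.
brute_idt <- function(track, min_dur_ms = 100, dispersion_deg = 1.0) {
  t <- track$t_s
  az <- track$az_deg
  el <- track$el_deg
  n <- length(t)
  valid <- if ("valid" %in% names(track)) as.logical(track$valid) else rep(TRUE, n)
  min_dur_s <- min_dur_ms / 1000
  disp <- function(i, j) {
    (max(az[i:j]) - min(az[i:j])) + (max(el[i:j]) - min(el[i:j]))
  }
  res <- list()
  i <- 1L
  while (i <= n) {
    if (!valid[i]) { i <- i + 1L; next }
    j0 <- i
    while (j0 <= n && t[j0] - t[i] < min_dur_s) j0 <- j0 + 1L
    if (j0 > n) break
    if (!all(valid[i:j0])) { i <- i + which(!valid[i:j0])[1]; next }
    if (disp(i, j0) <= dispersion_deg) {
      # exhaustive maximal extension: test every candidate end index
      j <- j0
      for (jj in seq(j0, n)) {
        if (!all(valid[i:jj])) break
        if (disp(i, jj) > dispersion_deg) break
        j <- jj
      }
      res[[length(res) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  res
}

# Random angular tracks mixing stable clusters, jumps, slow drift, jitter and
# occasional invalid samples; the fuzz input for oracle-equivalence checks.
random_track <- function(n, rate_hz = 120, p_invalid = 0.05) {
  t <- seq(0, by = 1 / rate_hz, length.out = n)
  az <- numeric(n)
  el <- numeric(n)
  pos <- c(0, 0)
  i <- 1L
  while (i <= n) {
    len <- min(n - i + 1L, sample(3:60, 1))
    kind <- sample(c("stable", "drift", "jump"), 1, prob = c(0.5, 0.3, 0.2))
    if (kind == "jump") pos <- pos + stats::runif(2, -6, 6)
    drift <- if (kind == "drift") stats::runif(2, -0.05, 0.05) else c(0, 0)
    idx <- i:(i + len - 1L)
    steps <- seq_len(len) - 1L
    az[idx] <- pos[1] + drift[1] * steps + stats::rnorm(len, 0, 0.12)
    el[idx] <- pos[2] + drift[2] * steps + stats::rnorm(len, 0, 0.12)
    pos <- pos + drift * (len - 1L)
    i <- i + len
  }
  valid <- stats::runif(n) > p_invalid
  df <- data.frame(t_s = t, az_deg = az, el_deg = el,
                   angle_to_ball_deg = sqrt(az^2 + el^2), valid = valid)
  class(df) <- c("angular_track", "data.frame")
  df
}

# Minimal angular track built directly from azimuth/elevation series.
make_track <- function(az, el = rep(0, length(az)), rate_hz = 120,
                       valid = rep(TRUE, length(az))) {
  t <- seq(0, by = 1 / rate_hz, length.out = length(az))
  df <- data.frame(t_s = t, az_deg = az, el_deg = el,
                   angle_to_ball_deg = sqrt(az^2 + el^2), valid = valid)
  class(df) <- c("angular_track", "data.frame")
  df
}

# Fixation-table row constructor for quiet-eye unit fixtures.
fx_row <- function(start_s, end_s, angle = 0.5) {
  data.frame(start_s = start_s, end_s = end_s,
             duration_ms = (end_s - start_s) * 1000,
             centroid_az = 0, centroid_el = 0, mean_angle_to_ball = angle,
             start_idx = NA_integer_, end_idx = NA_integer_)
}

events_ok <- function(onset, contact) {
  structure(list(status = "ok", swing_onset_s = onset, contact_s = contact),
            class = "trial_events")
}
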