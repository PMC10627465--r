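# Dispersion-threshold (I-DT) fixation detection on an angular track.

fixation_row <- function(track, i, j) {
  az <- track$az_deg[i:j]
  el <- track$el_deg[i:j]
  data.frame(start_s = track$t_s[i],
             end_s = track$t_s[j],
             duration_ms = (track$t_s[j] - track$t_s[i]) * 1000,
             centroid_az = mean(az),
             centroid_el = mean(el),
             mean_angle_to_ball = mean(track$angle_to_ball_deg[i:j]),
             start_idx = i, end_idx = j)
}

#' Dispersion-threshold (I-DT) fixation detection
#'
#' Classic I-DT: a window covering the minimum duration is grown sample by
#' sample while its spatial dispersion stays at or below the threshold, and
#' emitted as a fixation at the first violation; otherwise the window slides
#' one sample. Dispersion is the original sum-of-ranges metric,
#' `(max az - min az) + (max el - min el)`, in degrees of visual angle.
#' Invalid samples terminate windows and are never interpolated across.
#' Emitted fixations are maximal, non-overlapping and ordered by onset.
#'
#' Optionally, a two-step spatial post-processing pass (in the spirit of
#' two-tolerance dispersion algorithms) repairs boundary artifacts of the
#' greedy window growth: fixation boundaries are first extended over
#' adjacent samples lying within `merge_dist_deg` of the fixation centroid,
#' then adjacent fixations separated by at most `merge_gap_ms` whose
#' centroids lie within `merge_dist_deg` are merged. This absorbs spurious
#' splits of long noisy fixations and their sub-minimum-duration tails; it
#' is off by default (`merge_gap_ms = 0`) so the core routine is the
#' textbook algorithm.
#'
#' @param track An `angular_track` from [world_gaze()].
#' @param min_dur_ms Minimum fixation duration (time span) in ms.
#' @param dispersion_deg Dispersion threshold in degrees.
#' @param merge_gap_ms Maximum gap for post-hoc merging, ms; 0 disables.
#' @param merge_dist_deg Maximum centroid separation for merging, degrees.
#' @return A data frame of class `fixation_set`: `start_s`, `end_s`,
#'   `duration_ms`, `centroid_az`, `centroid_el`, `mean_angle_to_ball`,
#'   plus sample indices `start_idx`, `end_idx`. Zero rows when no window
#'   satisfies the criteria.
#' @export
idt_fixations <- function(track, min_dur_ms = 100, dispersion_deg = 1.0,
                          merge_gap_ms = 0, merge_dist_deg = 0.5 * dispersion_deg) {
  stopifnot(inherits(track, "data.frame"),
            all(c("t_s", "az_deg", "el_deg") %in% names(track)))
  n <- nrow(track)
  empty <- fixation_row(data.frame(t_s = 0, az_deg = 0, el_deg = 0,
                                   angle_to_ball_deg = 0), 1, 1)[0, ]
  if (n == 0L) return(structure(empty, class = c("fixation_set", "data.frame")))
  t <- track$t_s
  az <- track$az_deg
  el <- track$el_deg
  valid <- if ("valid" %in% names(track)) as.logical(track$valid) else rep(TRUE, n)
  min_dur_s <- min_dur_ms / 1000
  fixes <- list()
  i <- 1L
  while (i <= n) {
    if (!valid[i]) { i <- i + 1L; next }
    # smallest window starting at i that spans the minimum duration
    j0 <- i
    while (j0 <= n && t[j0] - t[i] < min_dur_s) j0 <- j0 + 1L
    if (j0 > n) break
    if (!all(valid[i:j0])) {
      # cannot form an uninterrupted minimum window here; skip past the break
      i <- i + which(!valid[i:j0])[1]
      next
    }
    az_min <- min(az[i:j0]); az_max <- max(az[i:j0])
    el_min <- min(el[i:j0]); el_max <- max(el[i:j0])
    if ((az_max - az_min) + (el_max - el_min) <= dispersion_deg) {
      j <- j0
      while (j + 1L <= n && valid[j + 1L]) {
        na_min <- min(az_min, az[j + 1L]); na_max <- max(az_max, az[j + 1L])
        ne_min <- min(el_min, el[j + 1L]); ne_max <- max(el_max, el[j + 1L])
        if ((na_max - na_min) + (ne_max - ne_min) > dispersion_deg) break
        az_min <- na_min; az_max <- na_max; el_min <- ne_min; el_max <- ne_max
        j <- j + 1L
      }
      fixes[[length(fixes) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(fixes)) return(structure(empty, class = c("fixation_set", "data.frame")))
  out <- do.call(rbind, lapply(fixes, function(ij) fixation_row(track, ij[1], ij[2])))
  if (merge_gap_ms > 0 && nrow(out) > 1L) {
    out <- merge_fixations(out, track, merge_gap_ms / 1000, merge_dist_deg)
  }
  rownames(out) <- NULL
  structure(out, class = c("fixation_set", "data.frame"))
}

# Two-step spatial post-processing. Step 1 extends each fixation's
# boundaries over adjacent valid samples within max_dist_deg of its
# centroid (absorbing sub-minimum-duration tails left by dispersion splits
# and mildly smeared boundary samples). Step 2 merges consecutive fixations
# whose separating gap and centroid distance are both small. Statistics are
# recomputed over the member samples; gap samples that were never absorbed
# violated the spatial tolerance and stay out.
merge_fixations <- function(fx, track, max_gap_s, max_dist_deg) {
  n <- nrow(track)
  valid <- if ("valid" %in% names(track)) as.logical(track$valid) else rep(TRUE, n)
  k <- nrow(fx)
  members <- lapply(seq_len(k), function(i) fx$start_idx[i]:fx$end_idx[i])
  within_tol <- function(j, cen) {
    d <- sqrt((track$az_deg[j] - cen[1])^2 + (track$el_deg[j] - cen[2])^2)
    d <= max_dist_deg
  }
  for (i in seq_len(k)) {
    cen <- c(fx$centroid_az[i], fx$centroid_el[i])
    lo_bound <- if (i > 1L) fx$end_idx[i - 1L] + 1L else 1L
    hi_bound <- if (i < k) fx$start_idx[i + 1L] - 1L else n
    j <- fx$start_idx[i]
    while (j - 1L >= lo_bound && valid[j - 1L] && within_tol(j - 1L, cen)) j <- j - 1L
    lo <- j
    j <- fx$end_idx[i]
    while (j + 1L <= hi_bound && valid[j + 1L] && within_tol(j + 1L, cen)) j <- j + 1L
    members[[i]] <- lo:j
  }
  groups <- list(members[[1]])
  if (k > 1L) {
    for (i in 2:k) {
      prev <- groups[[length(groups)]]
      gap <- track$t_s[min(members[[i]])] - track$t_s[max(prev)]
      c_prev <- c(mean(track$az_deg[prev]), mean(track$el_deg[prev]))
      c_i <- c(mean(track$az_deg[members[[i]]]), mean(track$el_deg[members[[i]]]))
      if (gap <= max_gap_s && sqrt(sum((c_prev - c_i)^2)) <= max_dist_deg) {
        groups[[length(groups)]] <- c(prev, members[[i]])
      } else {
        groups[[length(groups) + 1L]] <- members[[i]]
      }
    }
  }
  do.call(rbind, lapply(groups, function(idx) {
    r <- fixation_row(track, min(idx), max(idx))
    r$centroid_az <- mean(track$az_deg[idx])
    r$centroid_el <- mean(track$el_deg[idx])
    r$mean_angle_to_ball <- mean(track$angle_to_ball_deg[idx])
    r
  }))
}
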