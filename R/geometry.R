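# Quaternion and vector helpers. Quaternions are (w, x, y, z) rows; they map
# head-frame vectors into the world frame. The world frame is right-handed:
# x = putt-line axis (ball -> hole), y = up, z = lateral; origin at the ball's
# ground position.

vnorm <- function(v) sqrt(rowSums(v^2))

unit_rows <- function(v) v / vnorm(v)

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Rotate rows of v (n x 3) by rows of q (n x 4 or 1 x 4), vectorized.
quat_rotate <- function(q, v) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4L)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  w <- q[, 1]
  u <- q[, 2:4, drop = FALSE]
  # v' = v + 2 u x (u x v + w v)
  t1 <- cross3(u, v) + w * v
  v + 2 * cross3(u, t1)
}

quat_conjugate <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4L)
  cbind(q[, 1], -q[, 2:4, drop = FALSE])
}

# Rotation matrix (columns = frame axes in world coordinates) -> quaternion.
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

# Rotation by `angle_rad` about unit `axis` applied to rows of v.
rotate_about_axis <- function(v, axis, angle_rad) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
  axis <- axis / sqrt(sum(axis^2))
  n <- length(angle_rad)
  if (nrow(v) == 1L && n > 1L) v <- v[rep(1L, n), , drop = FALSE]
  k <- matrix(axis, nrow = nrow(v), ncol = 3L, byrow = TRUE)
  cs <- cos(angle_rad)
  sn <- sin(angle_rad)
  v * cs + cross3(k, v) * sn + k * (rowSums(k * v) * (1 - cs))
}

# Quaternion for a head that "looks at" direction f (unit, world frame), with
# head-frame forward = +z and head-frame up as close to world up as possible.
look_at_quat <- function(forward, up = c(0, 1, 0)) {
  f <- forward / sqrt(sum(forward^2))
  r <- c(up[2] * f[3] - up[3] * f[2],
         up[3] * f[1] - up[1] * f[3],
         up[1] * f[2] - up[2] * f[1])
  if (sqrt(sum(r^2)) < 1e-8) r <- c(1, 0, 0)
  r <- r / sqrt(sum(r^2))
  u <- c(f[2] * r[3] - f[3] * r[2],
         f[3] * r[1] - f[1] * r[3],
         f[1] * r[2] - f[2] * r[1])
  quat_from_matrix(cbind(r, u, f))
}

angle_between_deg <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3L)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  d <- rowSums(unit_rows(a) * unit_rows(b))
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

#' Scene geometry for a putting trial
#'
#' World-frame positions of ball and hole, the target size, and the observer
#' eye height. Defaults follow a standard 10 ft (3.05 m) putt to a regulation
#' hole (diameter 10.80 cm).
#'
#' @param ball_position 3-vector, metres; ball ground position (frame origin).
#' @param hole_position 3-vector, metres.
#' @param target_radius Target (hole) radius in metres.
#' @param eye_height Observer eye height in metres.
#' @return An object of class `scene_geometry` with an added `putt_distance`
#'   field (planar ball-to-hole distance in the ground plane).
#' @export
scene_geometry <- function(ball_position = c(0, 0, 0),
                           hole_position = c(3.05, 0, 0),
                           target_radius = 0.054,
                           eye_height = 1.6) {
  stopifnot(length(ball_position) == 3L, length(hole_position) == 3L)
  d <- hole_position - ball_position
  putt_distance <- sqrt(d[1]^2 + d[3]^2)
  if (!(putt_distance > 0)) stop("putt_distance must be positive")
  if (!(target_radius > 0)) stop("target_radius must be positive")
  structure(list(ball_position = as.numeric(ball_position),
                 hole_position = as.numeric(hole_position),
                 target_radius = target_radius,
                 eye_height = eye_height,
                 putt_distance = putt_distance),
            class = "scene_geometry")
}

#' @export
print.scene_geometry <- function(x, ...) {
  cat(sprintf("<scene_geometry> putt %.2f m, target radius %.3f m, eye height %.2f m\n",
              x$putt_distance, x$target_radius, x$eye_height))
  invisible(x)
}

# Direction of the fixation target (ball or drifting dot) from an eye point at
# time t. In noisy_dot scenarios the dot's direction rotates away from the
# observer in the sagittal plane at drift_deg_per_s, starting when the
# occlusion (and dot motion) begins at preview_s.
target_direction <- function(eye, t, scene, scenario = NULL) {
  if (is.null(dim(eye))) eye <- matrix(eye, ncol = 3L)
  d0 <- unit_rows(matrix(scene$ball_position, nrow = nrow(eye), ncol = 3L,
                         byrow = TRUE) - eye)
  if (is.null(scenario) || scenario$condition != "noisy_dot" ||
      scenario$drift_deg_per_s == 0) {
    return(d0)
  }
  t0 <- scenario$preview_s
  ang <- pmax(0, t - t0) * scenario$drift_deg_per_s * pi / 180
  # Axis perpendicular to the sagittal plane spanned by the view line and up:
  # rotating about it tips the line of gaze away from the observer.
  up <- c(0, 1, 0)
  out <- d0
  for (i in seq_len(nrow(d0))) {
    ax <- c(d0[i, 2] * up[3] - d0[i, 3] * up[2],
            d0[i, 3] * up[1] - d0[i, 1] * up[3],
            d0[i, 1] * up[2] - d0[i, 2] * up[1])
    if (sqrt(sum(ax^2)) < 1e-9) ax <- c(0, 0, 1)
    out[i, ] <- rotate_about_axis(d0[i, , drop = FALSE], ax, ang[i])
  }
  out
}

#' World-frame gaze geometry
#'
#' Composes each sample's head orientation with the gaze-in-head direction to
#' obtain the world gaze direction, and expresses it as azimuth/elevation in
#' degrees, recentred on the direction from the mean head position to the
#' ball (so angles stay far from wrap-around). Also computes the per-sample
#' visual angle between gaze and the target: the ball, or the instantaneous
#' dot direction in drifting-dot scenarios.
#'
#' @param trace A gaze trace data frame as produced by
#'   [generate_gaze_trace()] or [read_dataset()]: columns `t_s`, `head_x`,
#'   `head_y`, `head_z`, `quat_w`, `quat_x`, `quat_y`, `quat_z`, `gaze_x`,
#'   `gaze_y`, `gaze_z`, `valid`.
#' @param scene A [scene_geometry()].
#' @param scenario Optional [scenario_config()]; when its condition is
#'   `"noisy_dot"` the target criterion tracks the drifting dot.
#' @param unit_tol Tolerance for quaternion and gaze-direction unit norms.
#' @return A data frame of class `angular_track` with columns `t_s`,
#'   `az_deg`, `el_deg`, `angle_to_ball_deg`, `valid`.
#' @export
world_gaze <- function(trace, scene, scenario = NULL, unit_tol = 1e-6) {
  need <- c("t_s", "head_x", "head_y", "head_z", "quat_w", "quat_x", "quat_y",
            "quat_z", "gaze_x", "gaze_y", "gaze_z", "valid")
  miss <- setdiff(need, names(trace))
  if (length(miss)) stop("gaze trace is missing columns: ", paste(miss, collapse = ", "))
  q <- as.matrix(trace[, c("quat_w", "quat_x", "quat_y", "quat_z")])
  g <- as.matrix(trace[, c("gaze_x", "gaze_y", "gaze_z")])
  valid <- as.logical(trace$valid)
  qn <- sqrt(rowSums(q^2))
  gn <- sqrt(rowSums(g^2))
  bad_q <- valid & abs(qn - 1) > unit_tol
  bad_g <- valid & abs(gn - 1) > unit_tol
  if (any(bad_q)) stop(sprintf("non-unit quaternion at sample %d (|q| = %.8f)",
                               which(bad_q)[1], qn[which(bad_q)[1]]))
  if (any(bad_g)) stop(sprintf("non-unit gaze direction at sample %d (|g| = %.8f)",
                               which(bad_g)[1], gn[which(bad_g)[1]]))
  w <- quat_rotate(q / qn, g / gn)
  head_pos <- as.matrix(trace[, c("head_x", "head_y", "head_z")])

  # Reference basis recentred on the ball direction from the mean head position.
  hp0 <- colMeans(head_pos[valid, , drop = FALSE])
  d0 <- scene$ball_position - hp0
  d0 <- d0 / sqrt(sum(d0^2))
  up <- c(0, 1, 0)
  if (abs(sum(up * d0)) > 0.999) up <- c(1, 0, 0)
  u <- up - sum(up * d0) * d0
  u <- u / sqrt(sum(u^2))
  r <- c(u[2] * d0[3] - u[3] * d0[2],
         u[3] * d0[1] - u[1] * d0[3],
         u[1] * d0[2] - u[2] * d0[1])

  gd0 <- w %*% d0
  gr <- w %*% r
  gu <- w %*% u
  az <- atan2(gr, gd0) * 180 / pi
  el <- atan2(gu, sqrt(gd0^2 + gr^2)) * 180 / pi

  tgt <- target_direction(head_pos, trace$t_s, scene, scenario)
  ang <- angle_between_deg(w, tgt)

  out <- data.frame(t_s = trace$t_s, az_deg = as.numeric(az),
                    el_deg = as.numeric(el), angle_to_ball_deg = ang,
                    valid = valid)
  class(out) <- c("angular_track", "data.frame")
  attr(out, "rate_hz") <- 1 / stats::median(diff(trace$t_s))
  out
}

#' De-noise a gaze trace with a zero-phase Butterworth low-pass
#'
#' Applies the gaze denoising filter (second-order low-pass Butterworth,
#' 30 Hz by default) to the world-frame gaze direction, then re-expresses
#' the filtered direction in the head frame so the trace schema is unchanged.
#'
#' @param trace A gaze trace data frame (see [world_gaze()]).
#' @param cutoff_hz Filter cutoff in Hz.
#' @param order Butterworth order per pass.
#' @return A gaze trace with filtered gaze directions.
#' @export
denoise_gaze <- function(trace, cutoff_hz = 30, order = 2L) {
  q <- as.matrix(trace[, c("quat_w", "quat_x", "quat_y", "quat_z")])
  g <- as.matrix(trace[, c("gaze_x", "gaze_y", "gaze_z")])
  w <- quat_rotate(q, g)
  rate <- 1 / stats::median(diff(trace$t_s))
  ser <- sampled_series(trace$t_s, w, rate)
  wf <- butterworth_lowpass(ser, cutoff_hz, order)$values
  wf <- unit_rows(wf)
  gf <- quat_rotate(quat_conjugate(q), wf)
  out <- trace
  out$gaze_x <- gf[, 1]
  out$gaze_y <- gf[, 2]
  out$gaze_z <- gf[, 3]
  out
}
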