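# Putting outcome and swing-quality measures: radial error, the 95%
# confidence ellipse for the mean landing position, and downswing kinematics.

#' Radial error of a putt
#'
#' Planar Euclidean distance (cm) between the ball's rest position and the
#' hole centre. Landing coordinates are expressed relative to the hole
#' centre; putts holed out are assigned coordinates (0, 0) upstream.
#'
#' @param x_cm,z_cm Landing coordinates relative to the hole centre (cm).
#'   Vectors are accepted.
#' @return Radial error(s) in cm.
#' @export
#' @examples
#' radial_error(30, 40)  # 50
radial_error <- function(x_cm, z_cm) {
  stopifnot(is.finite(x_cm), is.finite(z_cm))
  sqrt(x_cm^2 + z_cm^2)
}

#' Confidence ellipse for the mean landing position
#'
#' Hotelling-type confidence region for the bivariate mean of a Gaussian
#' landing-point cloud: the sample covariance is eigen-decomposed and scaled
#' by `p (n - 1) / (n (n - p))` times the F quantile, so the region contains
#' the true mean with the requested probability.
#'
#' @param landings Matrix or data frame with two columns (`x_cm`, `z_cm`) of
#'   landing points relative to the hole centre; at least 3 rows.
#' @param level Coverage probability.
#' @return An `ellipse95` list: `center`, `semi_axes` (major, minor, cm),
#'   `orientation_deg` (principal-axis angle from the x axis), `n`, `level`,
#'   plus the `shape` matrix used by [ellipse_contains()].
#' @export
confidence_ellipse <- function(landings, level = 0.95) {
  xy <- as.matrix(landings)[, 1:2, drop = FALSE]
  n <- nrow(xy)
  if (n < 3L) stop("need at least 3 landings")
  S <- stats::cov(xy)
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[2] <= 1e-12 * max(ev$values[1], 1)) {
    stop("degenerate landing covariance")
  }
  p <- 2
  scale <- p * (n - 1) / (n * (n - p)) * stats::qf(level, p, n - p)
  semi <- sqrt(ev$values * scale)
  v1 <- ev$vectors[, 1]
  structure(list(center = colMeans(xy),
                 semi_axes = semi,
                 orientation_deg = atan2(v1[2], v1[1]) * 180 / pi,
                 n = n, level = level,
                 shape = S * scale),
            class = "ellipse95")
}

#' Test whether a point lies inside a confidence ellipse
#'
#' @param ellipse An `ellipse95` from [confidence_ellipse()].
#' @param point Length-2 numeric point (same coordinates as the landings).
#' @return Logical.
#' @export
ellipse_contains <- function(ellipse, point) {
  d <- as.numeric(point) - ellipse$center
  q <- drop(t(d) %*% solve(ellipse$shape) %*% d)
  q <= 1
}

#' @export
print.ellipse95 <- function(x, ...) {
  cat(sprintf("<ellipse95> %.0f%% region for the mean of %d landings: centre (%.1f, %.1f) cm, semi-axes %.1f x %.1f cm at %.1f deg\n",
              100 * x$level, x$n, x$center[1], x$center[2],
              x$semi_axes[1], x$semi_axes[2], x$orientation_deg))
  invisible(x)
}

#' Downswing kinematics summary
#'
#' Smooths the clubhead positions with the five-point moving average,
#' differentiates, and summarizes swing quality over the downswing window
#' (from the extreme backswing x-displacement to contact): the mean absolute
#' acceleration in the putt-line (x) and lateral (z) planes, and the 3-D
#' clubhead speed at the sample nearest contact. Signed accelerations would
#' cancel over an oscillatory stroke, so magnitudes are averaged.
#'
#' @param club Club trace data frame (`t_s`, `x`, `y`, `z`).
#' @param events A `trial_events` with `status = "ok"`.
#' @param scene A [scene_geometry()] (unused beyond validation; kinematics
#'   are translation-invariant).
#' @return A `kinematics_summary` list: `contact_speed` (m/s),
#'   `accel_x_mean`, `accel_z_mean` (m/s^2).
#' @export
kinematic_summary <- function(club, events, scene = scene_geometry()) {
  if (events$status != "ok") stop("kinematics need usable swing events")
  t <- club$t_s
  rate <- 1 / stats::median(diff(t))
  pos <- sampled_series(t, as.matrix(club[, c("x", "y", "z")]), rate)
  sm <- moving_average_5pt(pos)
  vel <- finite_difference(sm, 1L)
  acc <- finite_difference(sm, 2L)

  in_swing <- t >= events$swing_onset_s & t <= events$contact_s
  if (!any(in_swing)) stop("no club samples inside the swing window")
  i_peak <- which(in_swing)[which.min(sm$values[in_swing, 1])]
  i_contact <- which.min(abs(t - events$contact_s))
  win <- i_peak:i_contact

  structure(list(contact_speed = sqrt(sum(vel$values[i_contact, ]^2)),
                 accel_x_mean = mean(abs(acc$values[win, 1])),
                 accel_z_mean = mean(abs(acc$values[win, 3]))),
            class = "kinematics_summary")
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat(sprintf("<kinematics_summary> contact speed %.3f m/s; mean |accel| x %.3f, z %.3f m/s^2\n",
              x$contact_speed, x$accel_x_mean, x$accel_z_mean))
  invisible(x)
}
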