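# Synthetic VR putting-trial generator. Plants ground-truth fixations, swing
# events and outcome effects so every downstream stage can be verified
# against known truth.

#' Scenario configuration for the synthetic generator
#'
#' Describes one experimental condition. `control` and `occluded` mirror the
#' free-vision and occlusion conditions of the occlusion design (occlusion
#' changes only the visibility channel); `still_dot` / `noisy_dot` mirror the
#' stable versus covertly drifting fixation-dot design, the dot drifting at
#' `drift_deg_per_s` degrees of visual angle per second.
#'
#' @param condition One of `"control"`, `"occluded"`, `"still_dot"`,
#'   `"noisy_dot"`.
#' @param preview_s Preview length before occlusion (seconds).
#' @param drift_deg_per_s Dot drift rate in degrees of visual angle per
#'   second; forced to 0 unless `condition == "noisy_dot"`.
#' @param n_trials Trials per participant in this condition.
#' @param gaze_rate_hz,club_rate_hz Sampling rates (Hz).
#' @param jitter_sd_deg Fixational gaze noise: the root-mean-square angular
#'   deviation from the fixated target, in degrees (isotropic in the tangent
#'   plane, so each tangent component has SD `jitter_sd_deg / sqrt(2)`).
#' @param saccade_dur_ms Saccade duration between planted fixations (ms);
#'   saccades are constant-velocity angular interpolations.
#' @param contact_speed_mps Clubhead speed at ball contact (m/s).
#' @param backswing_s,downswing_s Durations of the two stroke phases (s).
#' @param club_noise_sd_m Gaussian positional tracker noise SD (m); must not
#'   exceed the 0.015 m tracker accuracy.
#' @param head_sway_m Amplitude of the quasi-static low-frequency head sway
#'   (m); millimetres for a standing observer.
#' @param seed Default seed used when the generator is called without one.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(condition = c("control", "occluded", "still_dot", "noisy_dot"),
                            preview_s = 1.5,
                            drift_deg_per_s = 1.5,
                            n_trials = 20L,
                            gaze_rate_hz = 120,
                            club_rate_hz = 90,
                            jitter_sd_deg = 0.2,
                            saccade_dur_ms = 30,
                            contact_speed_mps = 1.8,
                            backswing_s = 0.5,
                            downswing_s = 0.3,
                            club_noise_sd_m = 0.005,
                            head_sway_m = 0.002,
                            seed = 1L) {
  condition <- match.arg(condition)
  if (condition != "noisy_dot") drift_deg_per_s <- 0
  stopifnot(gaze_rate_hz > 0, club_rate_hz > 0, drift_deg_per_s >= 0,
            jitter_sd_deg >= 0, preview_s > 0, n_trials >= 1,
            contact_speed_mps > 0, club_noise_sd_m <= 0.015, head_sway_m >= 0)
  structure(list(condition = condition, preview_s = preview_s,
                 drift_deg_per_s = drift_deg_per_s, n_trials = as.integer(n_trials),
                 gaze_rate_hz = gaze_rate_hz, club_rate_hz = club_rate_hz,
                 jitter_sd_deg = jitter_sd_deg, saccade_dur_ms = saccade_dur_ms,
                 contact_speed_mps = contact_speed_mps, backswing_s = backswing_s,
                 downswing_s = downswing_s, club_noise_sd_m = club_noise_sd_m,
                 head_sway_m = head_sway_m, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Outcome effect model for the synthetic experiment
#'
#' Trial-level radial error follows a linear mixed model,
#' `y_ij = intercept + u0_i + (condition_beta + u1_i) * cond_ij + e_ij`, with
#' participant random intercepts `u0 ~ N(0, sd_intercept^2)`, random slopes
#' `u1 ~ N(0, sd_slope^2)` and residuals `e ~ N(0, residual_sd^2)`. Planted
#' quiet-eye durations are drawn per condition from
#' `N(qe_mean_ms, qe_sd_ms^2)` floored at the 100 ms fixation minimum.
#'
#' @param intercept Grand-mean radial error (cm).
#' @param condition_beta Fixed condition effect (cm).
#' @param sd_intercept,sd_slope Participant random-effect SDs (cm).
#' @param residual_sd Trial residual SD (cm).
#' @param qe_mean_ms Planted quiet-eye mean duration, length 1 or one value
#'   per scenario (ms).
#' @param qe_sd_ms Planted quiet-eye duration SD (ms).
#' @return An `effect_model` list.
#' @export
effect_model <- function(intercept = 90, condition_beta = 18,
                         sd_intercept = 30, sd_slope = 10, residual_sd = 35,
                         qe_mean_ms = c(460, 390), qe_sd_ms = 280) {
  stopifnot(sd_intercept >= 0, sd_slope >= 0, residual_sd >= 0, qe_sd_ms >= 0)
  structure(list(intercept = intercept, condition_beta = condition_beta,
                 sd_intercept = sd_intercept, sd_slope = sd_slope,
                 residual_sd = residual_sd, qe_mean_ms = qe_mean_ms,
                 qe_sd_ms = qe_sd_ms),
            class = "effect_model")
}

# Default standing position of the observer relative to the ball: eyes nearly
# over the ball, slightly behind and to the side, as in an address posture.
default_eye_position <- function(scene) {
  scene$ball_position + c(-0.05, scene$eye_height, 0.30)
}

#' Plan the ground-truth event layout for one trial
#'
#' Lays out a scripted fixation sequence (an early look at the hole, an
#' off-ball preparation fixation, then the final ball-directed quiet-eye
#' fixation spanning swing onset, optionally followed by a look-away), plus
#' backswing onset and contact times. All fixations are non-overlapping,
#' separated by saccades, and lie inside the trial span; the final fixation
#' covers swing onset.
#'
#' @param scenario A [scenario_config()].
#' @param qe_total_ms Planted quiet-eye duration (ms; onset precedes swing
#'   onset, offset may be capped at trial end).
#' @param qe_early_frac Fraction of the planted quiet eye falling before
#'   swing onset.
#' @param swing_onset_s Backswing initiation time (s).
#' @param hole_look Include an initial fixation on the hole. The hole sits
#'   some 60 degrees of visual angle from the ball direction, so the
#'   saccades around this fixation are very large; layouts without it keep
#'   all gaze shifts in the 5-10 degree range.
#' @return A `trial_truth` list: `fixations` (data frame with `start_s`,
#'   `end_s`, `target`, `offset_az`, `offset_el`), `swing_onset_s`,
#'   `contact_s`, `trial_end_s`, `qe_onset_s`, `qe_offset_s`.
#' @export
plan_trial_truth <- function(scenario, qe_total_ms = 460, qe_early_frac = 0.6,
                             swing_onset_s = 2.4, hole_look = TRUE) {
  sac <- scenario$saccade_dur_ms / 1000
  contact_s <- swing_onset_s + scenario$backswing_s + scenario$downswing_s
  trial_end_s <- contact_s + 1.0
  qe_total_s <- qe_total_ms / 1000
  early_s <- min(qe_early_frac * qe_total_s, swing_onset_s - 0.4)
  qe_onset <- swing_onset_s - early_s
  qe_offset <- min(qe_onset + qe_total_s, trial_end_s)

  fx <- list()
  # early look at the hole (offset well away from the ball direction)
  f1_end <- min(1.2, qe_onset - sac - 0.25)
  if (hole_look && f1_end >= 0.15) {
    fx[[length(fx) + 1L]] <- data.frame(start_s = 0, end_s = f1_end,
                                        target = "hole", offset_az = 0, offset_el = 0)
  }
  # preparation fixation near (but not on) the ball: 5 degrees off target
  f2_start <- if (length(fx)) f1_end + sac else 0
  f2_end <- qe_onset - sac
  if (f2_end - f2_start >= 0.15) {
    fx[[length(fx) + 1L]] <- data.frame(start_s = f2_start, end_s = f2_end,
                                        target = "ball", offset_az = 5, offset_el = 0)
  }
  # the quiet-eye fixation itself
  fx[[length(fx) + 1L]] <- data.frame(start_s = qe_onset, end_s = qe_offset,
                                      target = "ball", offset_az = 0, offset_el = 0)
  # optional look-away after quiet-eye offset (8 degrees up, > 3 degree window)
  if (trial_end_s - (qe_offset + sac) >= 0.12) {
    fx[[length(fx) + 1L]] <- data.frame(start_s = qe_offset + sac,
                                        end_s = trial_end_s,
                                        target = "ball", offset_az = 0, offset_el = 8)
  }
  fixations <- do.call(rbind, fx)
  structure(list(fixations = fixations, swing_onset_s = swing_onset_s,
                 contact_s = contact_s, trial_end_s = trial_end_s,
                 qe_onset_s = qe_onset, qe_offset_s = qe_offset),
            class = "trial_truth")
}

# Unit direction from the eye to the planted fixation point at time t,
# applying the planted angular offsets and (for the ball in noisy_dot) the
# dot drift. `eye` is one row per time point (or a single row, recycled).
planted_direction <- function(eye, t, fx_row, scene, scenario) {
  if (is.null(dim(eye))) eye <- matrix(eye, ncol = 3L)
  if (nrow(eye) == 1L && length(t) > 1L) {
    eye <- eye[rep(1L, length(t)), , drop = FALSE]
  }
  if (fx_row$target == "hole") {
    base <- unit_rows(matrix(scene$hole_position, nrow = nrow(eye), ncol = 3L,
                             byrow = TRUE) - eye)
  } else {
    base <- target_direction(eye, t, scene, scenario)
  }
  if (fx_row$offset_az != 0 || fx_row$offset_el != 0) {
    up <- c(0, 1, 0)
    for (i in seq_len(nrow(base))) {
      d <- base[i, ]
      r <- c(up[2] * d[3] - up[3] * d[2], up[3] * d[1] - up[1] * d[3],
             up[1] * d[2] - up[2] * d[1])
      r <- r / sqrt(sum(r^2))
      u <- c(d[2] * r[3] - d[3] * r[2], d[3] * r[1] - d[1] * r[3],
             d[1] * r[2] - d[2] * r[1])
      d <- rotate_about_axis(d, u, fx_row$offset_az * pi / 180)
      d <- rotate_about_axis(d, r, -fx_row$offset_el * pi / 180)
      base[i, ] <- d
    }
  }
  base
}

# slerp between two unit vectors, s in [0, 1]
slerp_rows <- function(a, b, s) {
  ang <- acos(pmin(1, pmax(-1, sum(a * b))))
  if (ang < 1e-9) return(matrix(a, nrow = length(s), ncol = 3L, byrow = TRUE))
  (sin((1 - s) * ang) %o% a + sin(s * ang) %o% b) / sin(ang)
}

#' Generate a synthetic gaze trace for one trial
#'
#' Samples head pose and gaze direction at the gaze rate. During planted
#' fixations the gaze points at the (possibly drifting) fixation target with
#' isotropic angular jitter; between fixations it performs constant-velocity
#' saccadic interpolation. The head is quasi-static (facing down at the
#' ball) with millimetre-scale low-frequency sway. The visibility channel
#' (`visible`) encodes the occlusion manipulation and is the only thing that
#' differs between control and occluded scenarios at a given seed.
#'
#' @param scene A [scene_geometry()].
#' @param scenario A [scenario_config()].
#' @param events A `trial_truth` from [plan_trial_truth()].
#' @param rng_seed Integer seed.
#' @return A data frame (gaze trace schema, see [world_gaze()]) with an
#'   additional `visible` column.
#' @export
generate_gaze_trace <- function(scene, scenario, events, rng_seed = scenario$seed) {
  fx <- events$fixations
  if (any(fx$start_s < 0) || any(fx$end_s > events$trial_end_s + 1e-9)) {
    stop("planted events lie outside the trial time span")
  }
  if (any(fx$end_s <= fx$start_s)) stop("degenerate planted fixation")
  if (is.unsorted(fx$start_s) || any(fx$start_s[-1] < fx$end_s[-nrow(fx)] - 1e-9)) {
    stop("planted fixations must be ordered and non-overlapping")
  }
  rng <- local({ set.seed(rng_seed); NULL })
  set.seed(rng_seed)
  dt <- 1 / scenario$gaze_rate_hz
  t <- seq(0, events$trial_end_s, by = dt)
  n <- length(t)
  eye0 <- default_eye_position(scene)
  # low-frequency head sway, a few millimetres
  sway <- scenario$head_sway_m
  sway_phase <- stats::runif(3, 0, 2 * pi)
  head_pos <- cbind(eye0[1] + sway * sin(2 * pi * 0.25 * t + sway_phase[1]),
                    eye0[2] + 0.5 * sway * sin(2 * pi * 0.20 * t + sway_phase[2]),
                    eye0[3] + sway * sin(2 * pi * 0.30 * t + sway_phase[3]))
  ball_dir <- scene$ball_position - eye0
  q0 <- look_at_quat(ball_dir / sqrt(sum(ball_dir^2)))
  q <- matrix(q0, nrow = n, ncol = 4L, byrow = TRUE)

  # nominal (noise-free) world gaze direction per sample; planted directions
  # are taken from the actual (swaying) eye position, i.e. the simulated
  # observer keeps the target foveated while the head moves
  w <- matrix(NA_real_, n, 3L)
  k <- nrow(fx)
  for (i in seq_len(k)) {
    in_fix <- t >= fx$start_s[i] - 1e-9 & t <= fx$end_s[i] + 1e-9
    if (any(in_fix)) {
      w[in_fix, ] <- planted_direction(head_pos[in_fix, , drop = FALSE],
                                       t[in_fix], fx[i, ], scene, scenario)
    }
    if (i < k) {
      gs <- fx$end_s[i]
      ge <- fx$start_s[i + 1L]
      in_gap <- t > fx$end_s[i] + 1e-9 & t < fx$start_s[i + 1L] - 1e-9
      if (any(in_gap)) {
        gi <- which(in_gap)
        a <- planted_direction(head_pos[gi[1], , drop = FALSE], gs,
                               fx[i, ], scene, scenario)[1, ]
        b <- planted_direction(head_pos[gi[length(gi)], , drop = FALSE], ge,
                               fx[i + 1L, ], scene, scenario)[1, ]
        w[in_gap, ] <- slerp_rows(a, b, (t[in_gap] - gs) / (ge - gs))
      }
    }
  }
  # before the first / after the last fixation: hold the nearest direction
  pre <- t < fx$start_s[1]
  if (any(pre)) {
    w[pre, ] <- planted_direction(head_pos[pre, , drop = FALSE],
                                  rep(fx$start_s[1], sum(pre)), fx[1, ],
                                  scene, scenario)
  }
  post <- t > fx$end_s[k]
  if (any(post)) {
    w[post, ] <- planted_direction(head_pos[post, , drop = FALSE],
                                   t[post], fx[k, ], scene, scenario)
  }

  # isotropic angular jitter: tangent-plane Gaussian with per-component SD
  # jitter_sd / sqrt(2), so the total angular RMS deviation is jitter_sd
  if (scenario$jitter_sd_deg > 0) {
    sdc <- scenario$jitter_sd_deg / sqrt(2) * pi / 180
    e1 <- rnorm(n, 0, sdc)
    e2 <- rnorm(n, 0, sdc)
    up <- c(0, 1, 0)
    r <- cross3(matrix(up, n, 3L, byrow = TRUE), w)
    r <- unit_rows(r)
    u <- cross3(w, r)
    w <- unit_rows(w + r * e1 + u * e2)
  }

  # express in head frame
  g <- quat_rotate(quat_conjugate(q), w)
  visible <- if (scenario$condition %in% c("occluded", "noisy_dot", "still_dot")) {
    t <= scenario$preview_s
  } else {
    rep(TRUE, n)
  }
  data.frame(t_s = t,
             head_x = head_pos[, 1], head_y = head_pos[, 2], head_z = head_pos[, 3],
             quat_w = q[, 1], quat_x = q[, 2], quat_y = q[, 3], quat_z = q[, 4],
             gaze_x = g[, 1], gaze_y = g[, 2], gaze_z = g[, 3],
             valid = TRUE, visible = visible)
}

#' Generate a synthetic clubhead trace for one trial
#'
#' The clubhead rests at the address position until swing onset, performs a
#' half-cosine backswing along the putt-line (x) axis, a sinusoidal
#' downswing that crosses the ball plane exactly at `contact_s` with the
#' configured contact speed, and a symmetric follow-through, after which it
#' comes to rest. Gaussian positional noise (SD at most the 0.015 m tracker
#' accuracy) is added to all axes.
#'
#' @inheritParams generate_gaze_trace
#' @return A data frame with columns `t_s`, `x`, `y`, `z`.
#' @export
generate_club_trace <- function(scene, scenario, events, rng_seed = scenario$seed) {
  if (events$swing_onset_s >= events$contact_s) {
    stop("swing onset must precede contact")
  }
  if (events$contact_s > events$trial_end_s || events$swing_onset_s < 0) {
    stop("planted events lie outside the trial time span")
  }
  if (scenario$contact_speed_mps <= 0) stop("contact speed must be positive")
  set.seed(rng_seed)
  dt <- 1 / scenario$club_rate_hz
  t <- seq(0, events$trial_end_s, by = dt)
  bx <- scene$ball_position[1]
  x_addr <- bx - 0.05
  t_on <- events$swing_onset_s
  t_pk <- t_on + scenario$backswing_s
  t_c <- events$contact_s
  tau_c <- t_c - t_pk
  omega <- pi / (2 * tau_c)
  x_back <- bx - scenario$contact_speed_mps / omega   # peak backswing position
  if (x_back >= x_addr) stop("contact speed too low for the address offset")

  x <- numeric(length(t))
  x[] <- x_addr
  ph_back <- t >= t_on & t < t_pk
  x[ph_back] <- x_addr + (x_back - x_addr) *
    (1 - cos(pi * (t[ph_back] - t_on) / scenario$backswing_s)) / 2
  ph_down <- t >= t_pk & t <= t_pk + 2 * tau_c
  x[ph_down] <- bx + (x_back - bx) * cos(omega * (t[ph_down] - t_pk))
  ph_rest <- t > t_pk + 2 * tau_c
  x[ph_rest] <- bx + (bx - x_back)   # symmetric follow-through rest point

  y <- rep(scene$ball_position[2] + 0.02, length(t))
  z <- rep(scene$ball_position[3], length(t))
  if (scenario$club_noise_sd_m > 0) {
    x <- x + rnorm(length(t), 0, scenario$club_noise_sd_m)
    y <- y + rnorm(length(t), 0, scenario$club_noise_sd_m)
    z <- z + rnorm(length(t), 0, scenario$club_noise_sd_m)
  }
  data.frame(t_s = t, x = x, y = y, z = z)
}

#' Generate a full synthetic trial-level dataset
#'
#' Draws per-participant random intercepts and slopes, trial residuals and
#' planted quiet-eye durations under the [effect_model()], for a
#' within-participant design in which every participant completes
#' `n_trials` trials in each scenario. The first scenario is the reference
#' condition (indicator 0). Landing points are placed at a uniformly random
#' bearing at the drawn radial error.
#'
#' @param n_participants Number of participants (at least 2).
#' @param scenarios List of [scenario_config()] objects; the first is the
#'   reference condition.
#' @param effects An [effect_model()].
#' @param rng_seed Integer seed.
#' @return A list with `trials` (trial table: `participant_id`, `condition`,
#'   `trial_index`, `cond01`, `qe_planted_ms`, `radial_error_cm`,
#'   `land_x_cm`, `land_z_cm`) and `truth` (realized `participants` effects
#'   and the `effects` model).
#' @export
generate_dataset <- function(n_participants, scenarios, effects,
                             rng_seed = 1L) {
  if (n_participants < 2L) stop("need at least 2 participants")
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  set.seed(rng_seed)
  conds <- vapply(scenarios, function(s) s$condition, character(1))
  if (anyDuplicated(conds)) stop("scenario conditions must be distinct")
  u0 <- rnorm(n_participants, 0, effects$sd_intercept)
  u1 <- rnorm(n_participants, 0, effects$sd_slope)
  qe_means <- rep_len(effects$qe_mean_ms, length(scenarios))
  rows <- list()
  for (p in seq_len(n_participants)) {
    for (s in seq_along(scenarios)) {
      nt <- scenarios[[s]]$n_trials
      cond01 <- as.numeric(s > 1L)
      e <- rnorm(nt, 0, effects$residual_sd)
      y <- effects$intercept + u0[p] + (effects$condition_beta + u1[p]) * cond01 + e
      y <- pmax(y, 0)
      qe <- pmax(100, rnorm(nt, qe_means[s], effects$qe_sd_ms))
      bearing <- stats::runif(nt, 0, 2 * pi)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = sprintf("P%03d", p),
        condition = conds[s],
        trial_index = seq_len(nt),
        cond01 = cond01,
        qe_planted_ms = qe,
        radial_error_cm = y,
        land_x_cm = y * cos(bearing),
        land_z_cm = y * sin(bearing))
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  truth <- list(participants = data.frame(participant_id = sprintf("P%03d", seq_len(n_participants)),
                                          u_intercept = u0, u_slope = u1),
                effects = effects)
  list(trials = trials, truth = truth)
}

#' Generate gaze and club traces for one planned trial
#'
#' Convenience wrapper: plans the ground-truth layout for a planted
#' quiet-eye duration and generates matching gaze and club traces.
#'
#' @inheritParams generate_gaze_trace
#' @param qe_total_ms Planted quiet-eye duration (ms).
#' @param qe_early_frac Fraction of the quiet eye before swing onset.
#' @param swing_onset_s Backswing initiation time (s).
#' @return A list with `truth`, `gaze`, `club`.
#' @export
generate_trial_traces <- function(scene, scenario, qe_total_ms = 460,
                                  qe_early_frac = 0.6, swing_onset_s = 2.4,
                                  rng_seed = scenario$seed) {
  truth <- plan_trial_truth(scenario, qe_total_ms = qe_total_ms,
                            qe_early_frac = qe_early_frac,
                            swing_onset_s = swing_onset_s)
  gaze <- generate_gaze_trace(scene, scenario, truth, rng_seed = rng_seed)
  club <- generate_club_trace(scene, scenario, truth, rng_seed = rng_seed + 1L)
  list(truth = truth, gaze = gaze, club = club)
}
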