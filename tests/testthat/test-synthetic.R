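scene <- scene_geometry()

test_that("noise-free gaze on a static ball has exactly zero visual angle", {
  scen <- scenario_config("control", jitter_sd_deg = 0)
  truth <- plan_trial_truth(scen, qe_total_ms = 800, hole_look = FALSE)
  gz <- generate_gaze_trace(scene, scen, truth, rng_seed = 1)
  track <- world_gaze(gz, scene)
  qe_idx <- gz$t_s >= truth$qe_onset_s & gz$t_s <= truth$qe_offset_s
  expect_true(all(track$angle_to_ball_deg[qe_idx] < 1e-7))
})

test_that("the drifting dot moves gaze at the configured angular rate", {
  scen <- scenario_config("noisy_dot", jitter_sd_deg = 0, drift_deg_per_s = 1.5,
                          head_sway_m = 0)
  truth <- plan_trial_truth(scen, qe_total_ms = 1500, qe_early_frac = 0.8,
                            swing_onset_s = 3.2)
  gz <- generate_gaze_trace(scene, scen, truth, rng_seed = 1)
  q <- as.matrix(gz[, c("quat_w", "quat_x", "quat_y", "quat_z")])
  g <- as.matrix(gz[, c("gaze_x", "gaze_y", "gaze_z")])
  w <- quieteye:::quat_rotate(q, g)
  i0 <- which.min(abs(gz$t_s - truth$qe_onset_s))
  i1 <- which.min(abs(gz$t_s - (truth$qe_onset_s + 1)))
  ang <- quieteye:::angle_between_deg(w[i0, , drop = FALSE], w[i1, , drop = FALSE])
  expect_equal(ang, 1.5, tolerance = 1.5 / 120 + 1e-6)
})

test_that("angular jitter has the configured RMS amplitude", {
  scen <- scenario_config("control", jitter_sd_deg = 0.2)
  # one long fixation, about 10 000 samples
  truth <- plan_trial_truth(scen, qe_total_ms = 90000, qe_early_frac = 1,
                            swing_onset_s = 87)
  truth$fixations <- truth$fixations[truth$fixations$target == "ball" &
                                       truth$fixations$offset_az == 0 &
                                       truth$fixations$offset_el == 0, ]
  gz <- generate_gaze_trace(scene, scen, truth, rng_seed = 9)
  track <- world_gaze(gz, scene)
  idx <- gz$t_s >= truth$qe_onset_s & gz$t_s <= truth$qe_offset_s
  rms <- sqrt(mean(track$angle_to_ball_deg[idx]^2))
  expect_equal(rms, 0.2, tolerance = 0.05 * 0.2)
})

test_that("events outside the trial span are rejected", {
  scen <- scenario_config("control")
  truth <- plan_trial_truth(scen, qe_total_ms = 500)
  bad <- truth
  bad$fixations$end_s[nrow(bad$fixations)] <- bad$trial_end_s + 1
  expect_error(generate_gaze_trace(scene, scen, bad, 1), "outside the trial")
  bad2 <- truth
  bad2$swing_onset_s <- truth$contact_s + 1
  expect_error(generate_club_trace(scene, scen, bad2, 1), "precede contact|outside")
})

test_that("the club rests at address before swing onset and hits at speed", {
  scen <- scenario_config("control", club_noise_sd_m = 0)
  truth <- plan_trial_truth(scen, qe_total_ms = 500)
  club <- generate_club_trace(scene, scen, truth, rng_seed = 2)
  pre <- club$t_s < truth$swing_onset_s
  expect_true(all(club$x[pre] == club$x[1]))
  expect_true(all(abs(diff(club$x[pre])) == 0))
  # finite-difference velocity at the contact sample
  v <- finite_difference(sampled_series(club$t_s, club$x, scen$club_rate_hz), 1)
  i_c <- which.min(abs(club$t_s - truth$contact_s))
  expect_equal(v$values[i_c, 1], scen$contact_speed_mps,
               tolerance = 0.01 * scen$contact_speed_mps)
})

test_that("degenerate effect models yield constant radial errors", {
  eff <- effect_model(intercept = 90, condition_beta = 0, sd_intercept = 0,
                      sd_slope = 0, residual_sd = 0)
  scens <- list(scenario_config("control", n_trials = 5),
                scenario_config("occluded", n_trials = 5))
  ds <- generate_dataset(4, scens, eff, rng_seed = 1)
  expect_true(all(ds$trials$radial_error_cm == 90))
  expect_equal(radial_error(ds$trials$land_x_cm, ds$trials$land_z_cm),
               ds$trials$radial_error_cm, tolerance = 1e-9)
})

test_that("sample variance decomposition matches the specified components", {
  eff <- effect_model(intercept = 90, condition_beta = 0, sd_intercept = 30,
                      sd_slope = 0, residual_sd = 35)
  ds <- generate_dataset(45, list(scenario_config("control", n_trials = 20)),
                        eff, rng_seed = 4)
  m <- stats::aggregate(radial_error_cm ~ participant_id, ds$trials, mean)
  between <- stats::var(m$radial_error_cm) - 35^2 / 20
  within <- mean(stats::aggregate(radial_error_cm ~ participant_id, ds$trials,
                                  stats::var)$radial_error_cm)
  expect_equal(between, 30^2, tolerance = 0.15 * 30^2)
  expect_equal(within, 35^2, tolerance = 0.15 * 35^2)
})

test_that("identical seeds reproduce identical outputs", {
  eff <- effect_model()
  scens <- list(scenario_config("control", n_trials = 3),
                scenario_config("occluded", n_trials = 3))
  d1 <- generate_dataset(3, scens, eff, rng_seed = 7)
  d2 <- generate_dataset(3, scens, eff, rng_seed = 7)
  expect_identical(d1, d2)
  s1 <- simulate_study(2, scens, eff, rng_seed = 5)
  s2 <- simulate_study(2, scens, eff, rng_seed = 5)
  expect_identical(s1$gaze, s2$gaze)
  expect_identical(s1$club, s2$club)
})

test_that("occlusion toggles only the visibility channel", {
  t1 <- generate_trial_traces(scene, scenario_config("control"), 500, 0.6, 2.4,
                              rng_seed = 7)
  t2 <- generate_trial_traces(scene, scenario_config("occluded"), 500, 0.6, 2.4,
                              rng_seed = 7)
  keep <- setdiff(names(t1$gaze), "visible")
  expect_identical(t1$gaze[keep], t2$gaze[keep])
  expect_identical(t1$club, t2$club)
  expect_false(identical(t1$gaze$visible, t2$gaze$visible))
})

test_that("the planted final fixation stays within 3 degrees of the ball", {
  for (k in 1:10) {
    scen <- scenario_config("control", jitter_sd_deg = 0)
    tr <- generate_trial_traces(scene, scen, qe_total_ms = 600,
                                qe_early_frac = 0.5, swing_onset_s = 2.4,
                                rng_seed = k)
    track <- world_gaze(tr$gaze, scene)
    idx <- tr$gaze$t_s >= tr$truth$qe_onset_s & tr$gaze$t_s <= tr$truth$qe_offset_s
    expect_true(tr$truth$qe_onset_s < tr$truth$swing_onset_s)
    expect_true(tr$truth$qe_offset_s > tr$truth$swing_onset_s)
    expect_true(all(track$angle_to_ball_deg[idx] < 3))
  }
})

test_that("planted fixations are non-overlapping and inside the trial", {
  set.seed(31)
  for (k in 1:20) {
    scen <- scenario_config("control")
    truth <- plan_trial_truth(scen, qe_total_ms = max(100, rnorm(1, 460, 280)),
                              qe_early_frac = runif(1, 0.4, 0.8),
                              swing_onset_s = runif(1, 2.2, 2.6))
    fx <- truth$fixations
    expect_true(all(fx$start_s >= 0 & fx$end_s <= truth$trial_end_s))
    expect_true(all(fx$end_s > fx$start_s))
    if (nrow(fx) > 1) expect_true(all(fx$start_s[-1] >= fx$end_s[-nrow(fx)]))
    expect_true(truth$swing_onset_s < truth$contact_s)
  }
})
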