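test_that("a single ball fixation spanning the swing is the quiet eye", {
  fx <- rbind(fx_row(0.2, 1.0, angle = 8),       # off-target preparation
              fx_row(1.9, 3.4, angle = 0.4))     # ball fixation through contact
  ev <- events_ok(2.4, 3.2)
  qe <- extract_quiet_eye(fx, ev, trial_end_s = 4.2)
  expect_true(qe$present)
  expect_equal(qe$onset_s, 1.9)
  expect_equal(qe$offset_s, 3.4)
  expect_equal(qe$total_ms, 1500)
})

test_that("absent ball fixations are scored as zero", {
  fx <- rbind(fx_row(0.2, 1.0, angle = 8),
              fx_row(1.2, 2.2, angle = 4.5))     # never within 3 degrees
  qe <- extract_quiet_eye(fx, events_ok(2.4, 3.2), trial_end_s = 4.2)
  expect_false(qe$present)
  expect_equal(qe$total_ms, 0)
  qe <- split_phases(qe, events_ok(2.4, 3.2), 0, 4.2)
  expect_equal(qe$early_ms + qe$online_ms + qe$dwell_ms, 0)
})

test_that("sub-tolerance excursions merge; longer ones terminate the quiet eye", {
  # 80 ms, 5-degree excursion: both on-target segments form one quiet eye
  fx80 <- rbind(fx_row(1.5, 2.30, angle = 0.5),
                fx_row(2.38, 3.0, angle = 0.5))
  qe <- extract_quiet_eye(fx80, events_ok(2.4, 3.2), trial_end_s = 3.0)
  expect_true(qe$present)
  expect_equal(qe$onset_s, 1.5)
  expect_equal(qe$offset_s, 3.0)
  # 120 ms excursion: the quiet eye ends at the first segment's end
  fx120 <- rbind(fx_row(1.5, 2.30, angle = 0.5),
                 fx_row(2.42, 3.0, angle = 0.5))
  qe2 <- extract_quiet_eye(fx120, events_ok(2.35, 3.2), trial_end_s = 4.0)
  expect_true(qe2$present)
  expect_equal(qe2$offset_s, 2.30)
  expect_equal(qe2$total_ms, 800)
})

test_that("an interrupted pre-onset fixation spans both segments", {
  # both on-target segments start before swing onset; the quiet eye is the
  # merged chain, not just the later segment
  fx <- rbind(fx_row(1.0, 1.8, angle = 0.5),
              fx_row(1.86, 2.3, angle = 0.5))
  qe <- extract_quiet_eye(fx, events_ok(2.4, 3.2), trial_end_s = 4.2)
  expect_equal(qe$onset_s, 1.0)
  expect_equal(qe$offset_s, 2.3)  # the long off-target tail ends the quiet eye
  expect_equal(qe$total_ms, 1300)
})

test_that("phase decomposition follows interval arithmetic", {
  # quiet eye from -0.4 s to +0.2 s relative to onset at 2.4, contact at 3.2
  fx <- fx_row(2.0, 2.6, angle = 0.5)
  ev <- events_ok(2.4, 3.2)
  qe <- split_phases(extract_quiet_eye(fx, ev, trial_end_s = 4.2), ev, 0, 4.2)
  expect_equal(qe$early_ms, 400)
  expect_equal(qe$online_ms, 200)
  expect_equal(qe$dwell_ms, 0)
  # quiet eye ending exactly at contact has zero dwell
  fx2 <- fx_row(2.0, 3.2, angle = 0.5)
  qe2 <- split_phases(extract_quiet_eye(fx2, ev, trial_end_s = 4.4), ev, 0, 4.4)
  expect_equal(qe2$dwell_ms, 0)
  expect_equal(qe2$online_ms, 800)
})

test_that("phases sum to the total exactly on random layouts", {
  set.seed(17)
  for (k in 1:200) {
    onset <- runif(1, 1, 3)
    contact <- onset + runif(1, 0.3, 1.2)
    t_end <- contact + runif(1, 0.5, 1.5)
    qs <- runif(1, 0.2, onset)
    qe_end <- qs + runif(1, 0.15, t_end - qs)
    ev <- events_ok(onset, contact)
    qe <- split_phases(extract_quiet_eye(fx_row(qs, qe_end, angle = 0.3), ev,
                                         trial_end_s = t_end), ev, 0, t_end)
    expect_identical(qe$early_ms + qe$online_ms + qe$dwell_ms, qe$total_ms)
  }
})

test_that("extending the candidate fixation never shortens the quiet eye", {
  ev <- events_ok(2.4, 3.2)
  ends <- seq(2.5, 4.0, by = 0.1)
  totals <- vapply(ends, function(e) {
    extract_quiet_eye(fx_row(2.0, e, angle = 0.5), ev, trial_end_s = 4.2)$total_ms
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("missing swing events make the quiet eye unusable", {
  missing <- structure(list(status = "missing", swing_onset_s = NA_real_,
                            contact_s = NA_real_), class = "trial_events")
  qe <- extract_quiet_eye(fx_row(1, 2), missing, trial_end_s = 4)
  expect_identical(qe$status, "missing")
  expect_equal(qe$total_ms, 0)
})

test_that("planted quiet-eye durations are recovered on synthetic trials", {
  scene <- scene_geometry()
  errs <- numeric(0)
  for (k in 1:20) {
    scen <- scenario_config("control", jitter_sd_deg = 0)
    tr <- generate_trial_traces(scene, scen, qe_total_ms = 300 + 40 * k,
                                qe_early_frac = 0.5, swing_onset_s = 2.4,
                                rng_seed = 500 + k)
    res <- analyze_trial(tr$gaze, tr$club, scene, scen)
    expect_identical(res$events$status, "ok")
    expect_true(res$qe$present)
    planted <- (tr$truth$qe_offset_s - tr$truth$qe_onset_s) * 1000
    errs <- c(errs, res$qe$total_ms - planted)
  }
  expect_lte(max(abs(errs)), 2 * 1000 / 120)
})
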