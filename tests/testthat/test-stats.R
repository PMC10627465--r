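test_that("winsorization replaces only 3-SD outliers and preserves size", {
  v <- c(10, 11, 12, 13, 14, 12, 11, 10, 13, 12)
  w <- winsorize_outliers(v)
  expect_identical(w$values, v)
  expect_identical(w$n_replaced, 0L)

  v2 <- c(rep(0, 50), 100)
  w2 <- winsorize_outliers(v2)
  expect_identical(w2$n_replaced, 1L)
  expect_equal(w2$values[51], 1.01 * max(v2[1:50]) + 0.01 * 0)  # 1% beyond 0 is 0
  # idempotence on this vector: the second pass replaces nothing
  w3 <- winsorize_outliers(w2$values)
  expect_identical(w3$n_replaced, 0L)
})

test_that("winsorization never widens the sample range", {
  set.seed(21)
  for (k in 1:30) {
    v <- stats::rt(60, df = 3) * 10 + 5
    w <- winsorize_outliers(v)
    expect_identical(length(w$values), length(v))
    expect_gte(min(w$values), min(v))
    expect_lte(max(w$values), max(v))
  }
})

test_that("winsorization handles signs, constants and missing values", {
  vneg <- c(rep(-5, 40), -200)
  w <- winsorize_outliers(vneg)
  expect_equal(w$values[41], -5 - 0.01 * 5)  # 1% beyond the retained minimum
  expect_identical(winsorize_outliers(rep(3, 10))$n_replaced, 0L)
  vna <- c(rep(1, 30), NA, 50)
  wna <- winsorize_outliers(vna)
  expect_true(is.na(wna$values[31]))
})

make_table <- function(y, cond, id, trial = NULL) {
  data.frame(participant_id = id, cond01 = cond,
             trial_index = if (is.null(trial)) seq_along(y) else trial,
             y = y)
}

test_that("a deterministic outcome is fitted exactly", {
  id <- rep(sprintf("P%02d", 1:6), each = 10)
  cond <- rep(rep(0:1, each = 5), 6)
  tab <- make_table(2 + 5 * cond, cond, id, trial = rep(1:10, 6))
  f <- fit_condition_lmm(tab, "y")
  expect_equal(f$beta, 5, tolerance = 1e-6)
  expect_gt(f$r2_conditional, 0.999)
})

test_that("with independent errors the mixed model agrees with least squares", {
  set.seed(5)
  id <- rep(sprintf("P%02d", 1:12), each = 16)
  cond <- rep(rep(0:1, each = 8), 12)
  y <- 10 + 3 * cond + stats::rnorm(length(cond), 0, 4)
  tab <- make_table(y, cond, id, trial = rep(1:16, 12))
  f <- fit_condition_lmm(tab, "y", random_structure = "intercepts")
  ols <- stats::coef(stats::lm(y ~ cond))[["cond"]]
  expect_equal(f$beta, ols, tolerance = 1e-6)
  expect_lte(f$r2_marginal, f$r2_conditional)
})

test_that("the standardized beta is invariant to affine outcome rescaling", {
  set.seed(6)
  id <- rep(sprintf("P%02d", 1:10), each = 20)
  cond <- rep(rep(0:1, each = 10), 10)
  u <- rep(stats::rnorm(10, 0, 5), each = 20)
  y <- 50 + 8 * cond + u + stats::rnorm(200, 0, 10)
  tab <- make_table(y, cond, id, trial = rep(1:20, 10))
  f1 <- fit_condition_lmm(tab, "y", random_structure = "intercepts")
  tab2 <- tab
  tab2$y <- 100 * tab2$y - 40
  f2 <- fit_condition_lmm(tab2, "y", random_structure = "intercepts")
  expect_equal(f1$std_beta, f2$std_beta, tolerance = 1e-6)
  expect_equal(f2$beta, 100 * f1$beta, tolerance = 1e-6)
})

test_that("zero quiet-eye trials and missing-event rows are excluded", {
  id <- rep(sprintf("P%02d", 1:6), each = 10)
  cond <- rep(rep(0:1, each = 5), 6)
  tab <- data.frame(participant_id = id, cond01 = cond,
                    trial_index = rep(1:10, 6),
                    qe_total_ms = c(rep(0, 6), stats::rnorm(54, 400, 50)),
                    events_status = c(rep("missing", 3), rep("ok", 57)))
  f <- fit_condition_lmm(tab, "qe_total_ms", random_structure = "intercepts")
  # 3 missing rows; of the remaining 57, 3 are zero-QE
  expect_identical(f$n_obs, 54L)
})

test_that("marginal R2 never exceeds conditional R2 across random fits", {
  set.seed(9)
  for (k in 1:5) {
    eff <- effect_model(intercept = 460, condition_beta = 40 * k,
                        sd_intercept = 80, sd_slope = 30, residual_sd = 140)
    ds <- generate_dataset(12, list(scenario_config("control", n_trials = 8),
                                    scenario_config("occluded", n_trials = 8)),
                          eff, rng_seed = k)
    f <- fit_condition_lmm(ds$trials, "radial_error_cm", random_structure = "slopes")
    expect_lte(f$r2_marginal, f$r2_conditional + 1e-12)
    expect_gte(f$r2_marginal, 0)
    expect_lte(f$r2_conditional, 1)
    expect_true(f$ci_low <= f$beta && f$beta <= f$ci_high)
  }
})

test_that("parameter recovery is unbiased over replicates", {
  eff <- effect_model(intercept = 460, condition_beta = 75, sd_intercept = 100,
                      sd_slope = 50, residual_sd = 150)
  scens <- list(scenario_config("control", n_trials = 10),
                scenario_config("occluded", n_trials = 10))
  betas <- numeric(20)
  for (r in 1:20) {
    ds <- generate_dataset(20, scens, eff, rng_seed = 300 + r)
    betas[r] <- fit_condition_lmm(ds$trials, "radial_error_cm",
                                  random_structure = "slopes")$beta
  }
  expect_equal(mean(betas), 75, tolerance = 15)
})

test_that("an overwhelming effect is detected with near-certain power", {
  eff <- effect_model(intercept = 460, condition_beta = 0, sd_intercept = 30,
                      sd_slope = 0, residual_sd = 30)
  p <- mc_power(5 * 30, 40, 10, eff, n_sims = 100, seed = 2)
  expect_gt(p$power, 0.99)
  expect_equal(p$mc_se, sqrt(p$power * (1 - p$power) / 100))
})
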