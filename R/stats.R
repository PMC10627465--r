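# Trial-level statistics: Winsorized outlier replacement, mixed-effects
# condition contrasts with standardized effect sizes and marginal /
# conditional R-squared, and Monte-Carlo power simulation.

step_beyond <- function(x, upper) {
  # a value 1% beyond x, away from the centre of the data
  if (upper) x + 0.01 * abs(x) else x - 0.01 * abs(x)
}

#' Winsorize outliers beyond 3 standard deviations
#'
#' Values more than `z` standard deviations from the mean (mean and SD
#' computed on the input) are replaced by a value 1% beyond the next most
#' extreme non-outlying value on the same side, preserving sample size.
#'
#' @param values Numeric vector (at least 3 values). `NA`s are passed
#'   through untouched.
#' @param z Outlier threshold in SD units.
#' @return A list with `values` (same length) and `n_replaced`.
#' @export
winsorize_outliers <- function(values, z = 3) {
  ok <- !is.na(values)
  if (sum(ok) < 3L) stop("need at least 3 non-missing values")
  v <- values[ok]
  m <- mean(v)
  s <- stats::sd(v)
  if (s == 0) return(list(values = values, n_replaced = 0L))
  zs <- (v - m) / s
  hi <- zs > z
  lo <- zs < -z
  out <- v
  retained <- v[!hi & !lo]
  if (any(hi) && length(retained)) out[hi] <- step_beyond(max(retained), upper = TRUE)
  if (any(lo) && length(retained)) out[lo] <- step_beyond(min(retained), upper = FALSE)
  values[ok] <- out
  list(values = values, n_replaced = sum(hi) + sum(lo))
}

# Nakagawa-style variance decomposition for the fitted merMod: fixed-effect
# variance share (marginal R2) and fixed-plus-random share (conditional R2).
r2_mixed <- function(fit) {
  fe <- as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit))
  var_f <- stats::var(fe)
  vc <- lme4::VarCorr(fit)
  X <- lme4::getME(fit, "X")
  var_r <- 0
  for (g in names(vc)) {
    G <- as.matrix(vc[[g]])
    terms <- rownames(G)
    Zg <- X[, terms, drop = FALSE]
    # mean over observations of z_i' G z_i
    var_r <- var_r + mean(rowSums((Zg %*% G) * Zg))
  }
  var_e <- attr(vc, "sc")^2
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

structure_formula <- function(structure) {
  switch(structure,
         maximal = "(1 + cond01 | participant_id) + (1 | trial_index)",
         slopes = "(1 + cond01 | participant_id)",
         intercepts = "(1 | participant_id)",
         stop("unknown random structure: ", structure))
}

#' Mixed-effects condition contrast
#'
#' Fits `outcome ~ condition` by REML with the requested random-effect
#' structure (participant intercepts and slopes, optionally a trial-index
#' intercept), the condition coded 0/1. Rows whose swing events are missing
#' are excluded; when the outcome is a quiet-eye measure, zero quiet-eye
#' trials are treated as missing cases. Singular fits trigger automatic
#' simplification (trial intercept dropped, then slopes), recorded in the
#' returned `random_structure`; with no usable random structure an ordinary
#' least-squares fit is returned (`random_structure = "none"`).
#'
#' The p-value and confidence interval for the condition term use the
#' Satterthwaite denominator degrees of freedom. The standardized beta is
#' `beta * SD(predictor) / SD(outcome)` over the analyzed rows, and the
#' marginal / conditional R-squared follow the variance-decomposition
#' formulation for mixed models.
#'
#' @param table Trial table with columns `participant_id`, `condition` (or
#'   `cond01`), `trial_index`, the outcome column, and optionally
#'   `events_status`, `qe_present`.
#' @param outcome Name of the outcome column.
#' @param random_structure `"maximal"`, `"slopes"` or `"intercepts"`.
#' @param level Confidence level for the interval.
#' @return An `lmm_fit` list: `beta`, `ci_low`, `ci_high`, `p_value`,
#'   `std_beta`, `r2_marginal`, `r2_conditional`, `n_obs`, `n_groups`,
#'   `random_structure`, `outcome`.
#' @export
fit_condition_lmm <- function(table, outcome, random_structure = "maximal",
                              level = 0.95) {
  df <- as.data.frame(table)
  if (!"cond01" %in% names(df)) {
    if (!"condition" %in% names(df)) stop("need a condition or cond01 column")
    lev <- unique(df$condition)
    if (length(lev) != 2L) stop("need exactly 2 conditions")
    df$cond01 <- as.numeric(df$condition == lev[2])
  }
  if ("events_status" %in% names(df)) df <- df[df$events_status == "ok", ]
  is_qe <- grepl("^qe_", outcome)
  y <- df[[outcome]]
  if (is_qe) y[!is.na(y) & y == 0] <- NA  # zero quiet eye treated as missing
  df$.y <- y
  df <- df[stats::complete.cases(df[, c(".y", "cond01", "participant_id")]), ]
  if (length(unique(df$participant_id)) < 2L) stop("need at least 2 participants")
  if (length(unique(df$cond01)) < 2L) stop("need both conditions present")

  chain <- switch(random_structure,
                  maximal = c("maximal", "slopes", "intercepts"),
                  slopes = c("slopes", "intercepts"),
                  intercepts = "intercepts")
  fit <- NULL
  used <- "none"
  for (st in chain) {
    if (st == "maximal" && !"trial_index" %in% names(df)) next
    f <- stats::as.formula(paste(".y ~ cond01 +", structure_formula(st)))
    cand <- tryCatch(
      suppressWarnings(suppressMessages(
        lmerTest::lmer(f, data = df, REML = TRUE,
                       control = lme4::lmerControl(check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))))),
      error = function(e) NULL)
    if (is.null(cand)) next
    if (lme4::isSingular(cand, tol = 1e-4) && st != utils::tail(chain, 1)) next
    fit <- cand
    used <- st
    break
  }

  sd_x <- stats::sd(df$cond01)
  sd_y <- stats::sd(df$.y)
  if (!is.null(fit)) {
    co <- stats::coef(summary(fit))["cond01", ]
    beta <- co[["Estimate"]]
    se <- co[["Std. Error"]]
    ddf <- co[["df"]]
    p <- co[["Pr(>|t|)"]]
    tcrit <- stats::qt(1 - (1 - level) / 2, ddf)
    r2 <- r2_mixed(fit)
  } else {
    ols <- stats::lm(.y ~ cond01, data = df)
    co <- stats::coef(summary(ols))["cond01", ]
    beta <- co[["Estimate"]]
    se <- co[["Std. Error"]]
    ddf <- ols$df.residual
    p <- co[["Pr(>|t|)"]]
    tcrit <- stats::qt(1 - (1 - level) / 2, ddf)
    r2v <- summary(ols)$r.squared
    r2 <- c(marginal = r2v, conditional = r2v)
  }
  structure(list(beta = beta, ci_low = beta - tcrit * se,
                 ci_high = beta + tcrit * se, se = se, df = ddf, p_value = p,
                 std_beta = beta * sd_x / sd_y,
                 r2_marginal = unname(r2["marginal"]),
                 r2_conditional = unname(r2["conditional"]),
                 n_obs = nrow(df),
                 n_groups = length(unique(df$participant_id)),
                 random_structure = used, outcome = outcome),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s ~ condition: beta = %.3f [%.3f, %.3f], p = %.4g, std beta = %.3f\n",
              x$outcome, x$beta, x$ci_low, x$ci_high, x$p_value, x$std_beta))
  cat(sprintf("  R2 marginal %.3f / conditional %.3f; n = %d obs, %d participants; random: %s\n",
              x$r2_marginal, x$r2_conditional, x$n_obs, x$n_groups, x$random_structure))
  invisible(x)
}

#' Monte-Carlo power for the condition contrast
#'
#' Repeatedly simulates trial-level datasets under the effect model via
#' [generate_dataset()], fits the condition contrast with
#' [fit_condition_lmm()], and estimates power as the proportion of
#' simulations whose condition term is significant at `alpha`.
#'
#' @param effect Fixed condition effect (outcome units) to simulate.
#' @param n_participants,n_trials Design size (trials per condition per
#'   participant).
#' @param variance_components An [effect_model()] supplying the variance
#'   components (its `condition_beta` is overridden by `effect`).
#' @param alpha Significance level.
#' @param n_sims Number of simulated datasets (at least 100).
#' @param seed Integer seed.
#' @param random_structure Random structure used for the fits.
#' @return A `power_estimate` list: `power`, `mc_se`, and the simulation
#'   settings.
#' @export
mc_power <- function(effect, n_participants, n_trials,
                     variance_components = effect_model(), alpha = 0.05,
                     n_sims = 1000L, seed = 1L,
                     random_structure = "slopes") {
  if (n_sims < 100L) stop("n_sims must be at least 100")
  eff <- variance_components
  eff$condition_beta <- effect
  scens <- list(scenario_config("control", n_trials = n_trials),
                scenario_config("occluded", n_trials = n_trials))
  sig <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    ds <- generate_dataset(n_participants, scens, eff,
                           rng_seed = (seed + i - 1L) %% .Machine$integer.max)
    fit <- fit_condition_lmm(ds$trials, "radial_error_cm",
                             random_structure = random_structure)
    sig[i] <- fit$p_value < alpha
  }
  power <- mean(sig)
  structure(list(n_participants = n_participants, n_trials = n_trials,
                 effect = effect, power = power,
                 mc_se = sqrt(power * (1 - power) / n_sims),
                 n_sims = n_sims, alpha = alpha),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("<power_estimate> n = %d x %d trials, effect %.3g: power %.3f (MC SE %.3f, %d sims, alpha %.2g)\n",
              x$n_participants, x$n_trials, x$effect, x$power, x$mc_se,
              x$n_sims, x$alpha))
  invisible(x)
}
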