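# Between-subject swelling variation: random intercepts and the
# highest-of-k ("high sweller") edema load.

#' Expected maximum of k standard normal draws
#'
#' \eqn{E[\max(Z_1,\dots,Z_k)]} for iid standard normals, by numerical
#' integration of the order-statistic density
#' \eqn{k\,\phi(x)\Phi(x)^{k-1}}. For `k = 10` the value is about 1.5388.
#'
#' @param k Number of draws (>= 1).
#' @return A single number (0 for `k = 1`).
#' @export
expected_max_normal <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be a positive integer", call. = FALSE)
  if (k == 1) return(0)
  stats::integrate(function(x) x * k * stats::dnorm(x) * stats::pnorm(x)^(k - 1),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

#' Expected high-sweller offset
#'
#' The expected swelling offset (%) of the highest sweller among `k`
#' random individuals whose subject effects are iid N(0, `sigma_u`^2):
#' `sigma_u * E[max of k standard normals]`.
#'
#' @param sigma_u Between-subject SD of the swelling offset (%).
#' @param k Number of individuals (default 10).
#' @return Offset (%).
#' @export
expected_max_offset <- function(sigma_u, k = 10) {
  if (!is.numeric(sigma_u) || length(sigma_u) != 1L || sigma_u < 0)
    stop("`sigma_u` must be a single non-negative number", call. = FALSE)
  sigma_u * expected_max_normal(k)
}

#' Sampled high-sweller offsets
#'
#' Monte-Carlo counterpart of [expected_max_offset()] for sensitivity
#' analysis: `n` draws of the maximum of `k` iid N(0, `sigma_u`^2)
#' effects. Uses the current RNG state; set a seed for reproducibility.
#'
#' @inheritParams expected_max_offset
#' @param n Number of replicate maxima to draw.
#' @return Numeric vector of length `n`.
#' @export
sample_max_offset <- function(sigma_u, k = 10, n = 1) {
  sigma_u * apply(matrix(stats::rnorm(n * k), nrow = n), 1, max)
}

#' Calibrate the between-subject SD from a published high-sweller cell
#'
#' No between-subject SD is published; it is recovered from the structure
#' of the high-sweller table, whose cells differ from the average-sweller
#' table by a constant per decade. That structure implies the high
#' sweller's trajectory is the average trajectory plus a constant offset
#' over the full 24 h, so the anchor cell (no lens, 10 years, relative
#' load `anchor`) gives `offset = (anchor - 1) * no_lens_daily_load / 24`
#' and `sigma_u = offset / E[max of k standard normals]`.
#'
#' @param anchor Published high-sweller relative load for 10 years of no
#'   lens wear (default 2.6).
#' @param k Number of individuals the maximum is taken over.
#' @inheritParams scenario_load
#' @return `sigma_u` (%), a single number.
#' @export
calibrate_sigma_u <- function(anchor = 2.6, k = 10,
                              po = edema_params("table1_2021"),
                              p = edema_params(), dt = 1 / 60) {
  daily <- scenario_load("no_lens", NULL, po, p, dt)
  offset <- (anchor - 1) * daily / 24
  offset / expected_max_normal(k)
}

#' High-sweller relative edema load
#'
#' Relative edema load of the highest sweller among `k` random wearers of
#' the same lens with the same compliance: the average-sweller 24-h
#' trajectory shifted up by the constant offset
#' [expected_max_offset()]`(sigma_u, k)`, integrated, scaled to `years`,
#' and divided by the average-sweller no-lens 10-year load.
#'
#' @inheritParams lifetime_load
#' @param sigma_u Between-subject SD (%), or `"calibrated"` to use
#'   [calibrate_sigma_u()] with its default anchor.
#' @param k Number of individuals the maximum is taken over.
#' @return Relative load (dimensionless).
#' @export
high_sweller_relative_load <- function(lens, pattern = compliance_pattern(),
                                       years, sigma_u = "calibrated",
                                       k = 10,
                                       po = edema_params("table1_2021"),
                                       p = edema_params(), dt = 1 / 60) {
  if (identical(sigma_u, "calibrated"))
    sigma_u <- calibrate_sigma_u(k = k, po = po, p = p, dt = dt)
  offset <- expected_max_offset(sigma_u, k)
  daily <- mixed_daily_load(lens, pattern, po, p, dt) + 24 * offset
  ref <- reference_load("no_lens_10y", po, p, dt)
  daily * DAYS_PER_YEAR * years / ref
}

#' High-sweller relative load table
#'
#' The full high-sweller grid: [relative_load_table()] with the constant
#' high-sweller offset added to every trajectory, referenced to the
#' average-sweller 10-year no-lens load.
#'
#' @inheritParams relative_load_table
#' @inheritParams high_sweller_relative_load
#' @export
high_sweller_table <- function(lenses = c(10, 27, 100, 157),
                               patterns = list(
                                 compliance_pattern(0, 0),
                                 compliance_pattern(1, 1),
                                 compliance_pattern(8, 4)),
                               years_list = c(10, 20, 30, 40),
                               sigma_u = "calibrated", k = 10,
                               po = edema_params("table1_2021"),
                               p = edema_params(), dt = 1 / 60) {
  if (identical(sigma_u, "calibrated"))
    sigma_u <- calibrate_sigma_u(k = k, po = po, p = p, dt = dt)
  relative_load_table(lenses, patterns, years_list,
                      reference = "no_lens_10y",
                      offset = expected_max_offset(sigma_u, k),
                      po = po, p = p, dt = dt)
}

#' Fit the subject random-effect model to NLS residuals
#'
#' Random-intercept model `residual ~ 1 + (1 | subject)` fitted by REML
#' (via \pkg{lme4}) to the individual-level residuals of the swelling
#' model, giving the between-subject SD `sigma_u` and residual SD
#' `sigma_e` of the swelling offset.
#'
#' @param residuals Data frame with columns `subject` and `resid`.
#' @return A list with `sigma_u`, `sigma_e` (both %) and the fitted
#'   `merMod` object (`NULL` in the degenerate all-zero case).
#' @export
fit_subject_effects <- function(residuals) {
  if (!all(c("subject", "resid") %in% names(residuals)))
    stop("`residuals` needs columns `subject` and `resid`", call. = FALSE)
  tab <- table(residuals$subject)
  if (sum(tab >= 2) < 2)
    stop("need at least 2 subjects with at least 2 observations each; ",
         "a single observation per subject cannot separate sigma_u from ",
         "sigma_e", call. = FALSE)
  if (all(residuals$resid == 0))
    return(list(sigma_u = 0, sigma_e = 0, model = NULL))
  fit <- suppressMessages(
    lme4::lmer(resid ~ 1 + (1 | subject), data = residuals, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(sigma_u = vc$sdcor[vc$grp == "subject"],
       sigma_e = vc$sdcor[vc$grp == "Residual"],
       model = fit)
}
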