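# Edema load: AUC of swelling trajectories, day-type mixing, decadal
# extrapolation and the relative-load tables.

DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 365.25 / 12

#' Daily edema load of a trajectory
#'
#' Trapezoid integral of swelling (%) over the trajectory's time grid,
#' in %-hours. A constant 1% over 24 h gives 24 %-h.
#'
#' @param traj An `edema_trajectory` (or any data frame with `time` and
#'   `swelling` columns).
#' @return Edema load (%\eqn{\cdot}h).
#' @export
daily_load <- function(traj) {
  t <- traj$time
  s <- traj$swelling
  if (length(t) < 2L) stop("trajectory needs at least two points",
                           call. = FALSE)
  sum(diff(t) * (s[-1] + s[-length(s)]) / 2)
}

#' Compliance pattern for a daily-wear modality
#'
#' How often, per month, a daily-lens wearer naps in their lenses or
#' sleeps a full night in them. The published tables use
#' (0 naps, 0 sleeps), (1, 1) and (8, 4).
#'
#' @param naps_per_month Nap days per month (>= 0).
#' @param sleeps_per_month Sleep-in-lens nights per month (>= 0).
#' @param wear_hours Daily open-eye wear (h).
#' @return An object of class `compliance_pattern`.
#' @export
compliance_pattern <- function(naps_per_month = 0, sleeps_per_month = 0,
                               wear_hours = 14) {
  if (naps_per_month < 0 || sleeps_per_month < 0)
    stop("nap/sleep counts must be non-negative", call. = FALSE)
  if (naps_per_month + sleeps_per_month > DAYS_PER_MONTH)
    stop("naps + sleeps per month exceed the month length", call. = FALSE)
  structure(list(naps_per_month = naps_per_month,
                 sleeps_per_month = sleeps_per_month,
                 wear_hours = wear_hours),
            class = "compliance_pattern")
}

#' Daily edema load of one day type
#'
#' Simulates one canonical day of the given scenario and integrates it.
#'
#' @param scenario Scenario name, see [build_schedule()].
#' @param lens A [lens_config()]; ignored for `"no_lens"`.
#' @param po,p Parameter sets (default: packaged published values).
#' @param dt Trajectory grid step (h).
#' @param wear_hours Open-eye wear duration (h).
#' @return Edema load (%\eqn{\cdot}h).
#' @export
scenario_load <- function(scenario, lens = NULL,
                          po = edema_params("table1_2021"),
                          p = edema_params(), dt = 1 / 60,
                          wear_hours = 14) {
  if (scenario == "no_lens" || is.null(lens)) lens <- no_lens(p)
  sched <- build_schedule(scenario, wear_hours = wear_hours)
  daily_load(simulate_day(sched, lens, po, p, dt = dt))
}

#' Mean daily edema load under a compliance pattern
#'
#' Deterministic day-type mixture: of the `365.25/12` days in a month,
#' `sleeps_per_month` are sleep-in-lens days, `naps_per_month` are nap
#' days, and the remainder are compliant daily-wear days. The mean daily
#' load is the weighted mean of the three day-type loads (loads are linear
#' in day-type frequencies, so no sampling is involved).
#'
#' @param lens A [lens_config()].
#' @param pattern A [compliance_pattern()].
#' @inheritParams scenario_load
#' @return Mean daily edema load (%\eqn{\cdot}h).
#' @export
mixed_daily_load <- function(lens, pattern = compliance_pattern(),
                             po = edema_params("table1_2021"),
                             p = edema_params(), dt = 1 / 60) {
  stopifnot(inherits(pattern, "compliance_pattern"))
  lens <- check_lens(lens, p)
  month <- DAYS_PER_MONTH
  n_nap <- pattern$naps_per_month
  n_slp <- pattern$sleeps_per_month
  if (n_nap + n_slp > month)
    stop("naps + sleeps per month exceed the month length", call. = FALSE)
  wh <- pattern$wear_hours
  bare <- lens$dkt_ipsi >= p$DN && lens$dkt_contra >= p$DN
  l_comp <- scenario_load(if (bare) "no_lens" else "daily_compliant",
                          lens, po, p, dt, wh)
  l_nap <- if (n_nap > 0 && !bare)
    scenario_load("daily_nap", lens, po, p, dt, wh) else l_comp
  l_slp <- if (n_slp > 0 && !bare)
    scenario_load("sleep_in_lens", lens, po, p, dt, wh) else l_comp
  (l_comp * (month - n_nap - n_slp) + l_nap * n_nap + l_slp * n_slp) / month
}

#' Lifetime edema load
#'
#' Mean daily load under the pattern, scaled by `365.25 * years`. Linear
#' in `years` by construction.
#'
#' @inheritParams mixed_daily_load
#' @param years Duration of wear (years, > 0).
#' @return Lifetime edema load (%\eqn{\cdot}h).
#' @export
lifetime_load <- function(lens, pattern = compliance_pattern(), years,
                          po = edema_params("table1_2021"),
                          p = edema_params(), dt = 1 / 60) {
  if (!is.numeric(years) || any(years <= 0))
    stop("`years` must be positive", call. = FALSE)
  mixed_daily_load(lens, pattern, po, p, dt) * DAYS_PER_YEAR * years
}

#' Reference edema loads
#'
#' The two reference exposures the relative tables are expressed against:
#' `"no_lens_10y"`, ten years of no lens wear, and `"ew_lowdk_5y"`, five
#' years of continuous (extended) wear of a low-Dk/t hydrogel
#' (`ew_dkt = 11`): the lens is worn overnight 13 of every 14 nights, and
#' on the one off-night it is removed for sleep but worn through the day.
#'
#' @param reference Reference name.
#' @inheritParams scenario_load
#' @param ew_dkt Dk/t of the extended-wear reference hydrogel.
#' @return Reference load (%\eqn{\cdot}h).
#' @export
reference_load <- function(reference = c("no_lens_10y", "ew_lowdk_5y"),
                           po = edema_params("table1_2021"),
                           p = edema_params(), dt = 1 / 60, ew_dkt = 11) {
  reference <- match.arg(reference)
  if (reference == "no_lens_10y") {
    scenario_load("no_lens", NULL, po, p, dt) * DAYS_PER_YEAR * 10
  } else {
    ew_daily_load(ew_dkt, po, p, dt) * DAYS_PER_YEAR * 5
  }
}

# mean daily load of the continuous-wear reference: 13 nights in lens +
# 1 compliant off-night per fortnight
ew_daily_load <- function(ew_dkt = 11, po = edema_params("table1_2021"),
                          p = edema_params(), dt = 1 / 60) {
  lens <- lens_config(ew_dkt)
  (13 * scenario_load("continuous_wear_day", lens, po, p, dt) +
      scenario_load("continuous_wear_offnight", lens, po, p, dt)) / 14
}

#' Relative edema load table
#'
#' Lifetime loads for a grid of lenses, compliance patterns and wear
#' durations, expressed relative to a reference exposure
#' ([reference_load()]). With the defaults this reproduces the published
#' decade-scale tables: lenses Dk/t 10, 27, 100, 157; patterns
#' (0 naps, 0 sleeps), (1, 1) and (8, 4) per month; 10-40 years.
#'
#' @param lenses Numeric vector of Dk/t values (same lens in both eyes),
#'   or a list of [lens_config()] objects.
#' @param patterns List of [compliance_pattern()] objects.
#' @param years_list Numeric vector of wear durations (years).
#' @param reference `"no_lens_10y"` or `"ew_lowdk_5y"`.
#' @param offset Constant additive swelling offset (%) applied over the
#'   full 24 h before integration (used for the high-sweller table; 0 for
#'   an average wearer).
#' @inheritParams scenario_load
#' @inheritParams reference_load
#' @return A data frame with columns `dkt_ipsi`, `dkt_contra`,
#'   `naps_per_month`, `sleeps_per_month`, `years`, `load` (%-h) and
#'   `relative_load`.
#' @export
#' @examples
#' \donttest{
#' tab <- relative_load_table(lenses = c(27, 157),
#'                            patterns = list(compliance_pattern(0, 0)),
#'                            years_list = c(10, 40))
#' tab[, c("dkt_ipsi", "years", "relative_load")]
#' }
relative_load_table <- function(lenses = c(10, 27, 100, 157),
                                patterns = list(
                                  compliance_pattern(0, 0),
                                  compliance_pattern(1, 1),
                                  compliance_pattern(8, 4)),
                                years_list = c(10, 20, 30, 40),
                                reference = c("no_lens_10y", "ew_lowdk_5y"),
                                offset = 0,
                                po = edema_params("table1_2021"),
                                p = edema_params(), dt = 1 / 60,
                                ew_dkt = 11) {
  reference <- match.arg(reference)
  if (is.numeric(lenses)) lenses <- lapply(lenses, lens_config)
  ref <- reference_load(reference, po, p, dt, ew_dkt)
  rows <- list()
  for (lens in lenses) {
    for (pat in patterns) {
      daily <- mixed_daily_load(lens, pat, po, p, dt) + 24 * offset
      for (yr in years_list) {
        load <- daily * DAYS_PER_YEAR * yr
        rows[[length(rows) + 1L]] <- data.frame(
          dkt_ipsi = lens$dkt_ipsi, dkt_contra = lens$dkt_contra,
          naps_per_month = pat$naps_per_month,
          sleeps_per_month = pat$sleeps_per_month,
          years = yr, load = load, relative_load = load / ref)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  attr(out, "reference_load") <- ref
  out
}

#' Equivalent years of low-Dk/t extended wear
#'
#' The number of years of continuous low-Dk/t hydrogel extended wear
#' (13 of 14 nights) that produces the same edema load as the given lens,
#' pattern and duration; rounded half-up to the nearest year.
#'
#' @inheritParams lifetime_load
#' @inheritParams reference_load
#' @return Whole years (single number).
#' @export
equivalent_ew_years <- function(lens, pattern = compliance_pattern(),
                                years,
                                po = edema_params("table1_2021"),
                                p = edema_params(), dt = 1 / 60,
                                ew_dkt = 11) {
  load <- lifetime_load(lens, pattern, years, po, p, dt)
  yrs <- load / (ew_daily_load(ew_dkt, po, p, dt) * DAYS_PER_YEAR)
  floor(yrs + 0.5)
}
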