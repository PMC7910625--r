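# Wear scenarios -> event timelines -> piecewise 24-h swelling trajectories.

.scenarios <- c("no_lens", "daily_compliant", "daily_nap", "sleep_in_lens",
                "continuous_wear_day", "continuous_wear_offnight")

#' Build a canonical 24-hour wear schedule
#'
#' Turns a named wear scenario into an ordered event timeline on a 24-h
#' clock that starts at sleep onset. The canonical day: 8 h of sleep, lens
#' insertion 1 h after waking, 14 h of wear with removal 1 h before the
#' next sleep onset. A nap day adds a 1-h closed-eye interval, by default
#' starting 6 h after waking, with the lens in situ. A sleep-in-lens day
#' keeps the lens in through the night, with removal 15 h after waking.
#' `continuous_wear_day` is an alias for `sleep_in_lens`;
#' `continuous_wear_offnight` (the one lens-free night in 14 of a
#' continuous-wear fortnight) is an alias for `daily_compliant`.
#'
#' @param scenario One of `"no_lens"`, `"daily_compliant"`, `"daily_nap"`,
#'   `"sleep_in_lens"`, `"continuous_wear_day"`,
#'   `"continuous_wear_offnight"`.
#' @param wear_hours Open-eye lens wear duration (h), in (0, 16].
#' @param sleep_hours Overnight sleep duration (h).
#' @param nap_offset Nap start, hours after waking.
#' @param nap_hours Nap duration (h).
#' @return A `wear_schedule`: a data frame of events `(time, kind)` with
#'   scenario metadata attached.
#' @export
#' @examples
#' build_schedule("daily_compliant")
build_schedule <- function(scenario, wear_hours = 14, sleep_hours = 8,
                           nap_offset = 6, nap_hours = 1) {
  if (length(scenario) != 1L || !scenario %in% .scenarios)
    stop("unknown scenario: ", paste(scenario, collapse = ", "),
         " (expected one of ", paste(.scenarios, collapse = ", "), ")",
         call. = FALSE)
  if (!is.finite(wear_hours) || wear_hours <= 0 || wear_hours > 16)
    stop("`wear_hours` must lie in (0, 16]", call. = FALSE)
  if (!is.finite(sleep_hours) || sleep_hours <= 0 || sleep_hours >= 24)
    stop("`sleep_hours` must lie in (0, 24)", call. = FALSE)

  canon <- switch(scenario,
                  continuous_wear_day = "sleep_in_lens",
                  continuous_wear_offnight = "daily_compliant",
                  scenario)
  wake <- sleep_hours
  ev <- data.frame(time = c(0, wake),
                   kind = c("sleep_start", "wake"),
                   stringsAsFactors = FALSE)
  lens_overnight <- FALSE
  if (canon %in% c("daily_compliant", "daily_nap")) {
    ti <- wake + 1
    tr <- min(ti + wear_hours, 24)
    ev <- rbind(ev, data.frame(time = c(ti, tr),
                               kind = c("lens_insert", "lens_remove")))
  }
  if (canon == "daily_nap") {
    tn <- wake + nap_offset
    te <- tn + nap_hours
    if (te >= 24 - 1e-9)
      stop("nap does not fit in the open-eye period", call. = FALSE)
    ev <- rbind(ev, data.frame(time = c(tn, te),
                               kind = c("nap_start", "nap_end")))
  }
  if (canon == "sleep_in_lens") {
    lens_overnight <- TRUE
    ev <- rbind(ev, data.frame(time = min(wake + 15, 24),
                               kind = "lens_remove"))
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("wear_schedule", "data.frame"),
            scenario = scenario, canonical = canon,
            lens_overnight = lens_overnight,
            sleep_hours = sleep_hours, wear_hours = wear_hours)
}

event_time <- function(sched, kind) {
  t <- sched$time[sched$kind == kind]
  if (length(t)) t[1] else NA_real_
}

#' Simulate the 24-hour swelling trajectory for a schedule
#'
#' Assembles the piecewise swelling time course implied by a
#' [build_schedule()] timeline and a lens configuration:
#' \itemize{
#'   \item closed-eye intervals (sleep, naps) follow the logarithmic
#'     closed-eye shape of [overnight_curve()], anchored between the level
#'     at eye closure and the model's eye-opening level for the lens worn
#'     during closure ([eye_opening_swelling()] for sleep,
#'     [deswell_after_nap()] at `t = 0` for naps);
#'   \item after waking, swelling follows [deswell_after_sleep()] for the
#'     overnight lens configuration (the bare eye for daily-wear days);
#'   \item after lens insertion, [daytime_swelling()] is added on top of
#'     the deswelling tail (the sum keeps the curve continuous at
#'     insertion); after removal the accumulated daytime component
#'     deswells at the bare-eye (Dk/t = DN) deswelling rate;
#'   \item after a nap, the curve follows [deswell_after_nap()], floored
#'     pointwise at the background (no-nap) curve.
#' }
#' The day starts from zero swelling at sleep onset, matching the
#' closed-eye curve's own origin (it is identically zero at eye closure);
#' `start_level = "steady"` instead anchors the night at the level the
#' same day reaches at its end (exact, because the open-eye portion of
#' the day does not depend on the starting level), and a number carries
#' state across chained windows.
#'
#' A nap with no lens in situ is skipped with a warning: open-eye/no-lens
#' closed-eye swelling excess is outside the model's scope, which also
#' keeps a `Dk/t = DN` "lens" identical to no lens wear in every scenario.
#'
#' @param sched A `wear_schedule`.
#' @param lens A [lens_config()].
#' @param po An [overnight_params()] set.
#' @param p A [deswell_params()] set.
#' @param dt Grid step (h), at most 1 minute.
#' @param start_level Swelling (%) at sleep onset: a number, or
#'   `"steady"` for the steady-state (end-of-day) level.
#' @return An `edema_trajectory`: data frame `(time, swelling, segment)`
#'   on a grid spanning exactly 24 h.
#' @export
#' @examples
#' p <- edema_params(); po <- edema_params("table1_2021")
#' tr <- simulate_day(build_schedule("no_lens"), no_lens(p), po, p)
#' max(tr$swelling)  # ~3.3 at waking
simulate_day <- function(sched, lens, po, p, dt = 1 / 60,
                         start_level = 0) {
  stopifnot(inherits(sched, "wear_schedule"))
  lens <- check_lens(lens, p)
  if (!is.finite(dt) || dt <= 0 || dt > 1 / 60 + 1e-12)
    stop("`dt` must be positive and at most 1/60 h", call. = FALSE)

  wake <- event_time(sched, "wake")
  ti <- event_time(sched, "lens_insert")
  tr <- event_time(sched, "lens_remove")
  tn <- event_time(sched, "nap_start")
  te <- event_time(sched, "nap_end")
  lens_night <- if (isTRUE(attr(sched, "lens_overnight"))) lens else
    no_lens(p)
  bare <- lens$dkt_ipsi >= p$DN && lens$dkt_contra >= p$DN

  n <- max(2L, ceiling(24 / dt))
  tgrid <- seq(0, 24, length.out = n + 1L)
  open <- tgrid >= wake

  # background open-eye curve: post-sleep deswelling tail, plus the
  # daytime term once a lens is inserted; after removal the accumulated
  # daytime component deswells at the bare-eye rate (the Dk/t = DN decay
  # rate of the post-sleep curve)
  r_bare <- p$kdeswell + p$DN * (p$k2 + p$kc2)
  bg_fun <- function(t) {
    tend <- if (is.na(tr)) 24 else tr
    if (isTRUE(attr(sched, "lens_overnight"))) {
      # lens in situ since the previous night: the whole post-sleep curve
      # is evaluated with the lens until removal, then decays at the
      # bare-eye rate
      s <- deswell_after_sleep(pmax(pmin(t, tend) - wake, 0), lens_night, p)
      s <- s * exp(-r_bare * pmax(t - tend, 0))
    } else {
      s <- deswell_after_sleep(pmax(t - wake, 0), lens_night, p)
      if (!is.na(ti)) {
        tl <- pmin(t, tend)
        add <- ifelse(t >= ti, daytime_swelling(pmax(tl - ti, 0), lens, p),
                      0)
        s <- s + add * exp(-r_bare * pmax(t - tend, 0))
      }
    }
    s
  }

  sw <- numeric(length(tgrid))
  seg <- character(length(tgrid))
  sw[open] <- bg_fun(tgrid[open])
  seg[open] <- ifelse(!is.na(ti) & tgrid[open] >= ti, "daytime",
                      "post-wake-deswell")

  nap_active <- FALSE
  if (!is.na(tn)) {
    lens_in_at_nap <- (!is.na(ti) && tn >= ti && te <= (if (is.na(tr)) 24 else tr)) ||
      isTRUE(attr(sched, "lens_overnight"))
    if (!lens_in_at_nap || bare) {
      warning("nap with no lens in situ: closed-eye no-lens swelling is ",
              "not modelled; nap ignored", call. = FALSE)
    } else {
      nap_active <- TRUE
      lvl_pre <- bg_fun(tn)
      lvl_end <- deswell_after_nap(0, lens, p)
      in_nap <- tgrid >= tn & tgrid <= te
      sw[in_nap] <- lvl_pre +
        (lvl_end - lvl_pre) * log(po$Bh * (tgrid[in_nap] - tn) + 1) /
        log(po$Bh * (te - tn) + 1)
      seg[in_nap] <- "nap"
      post <- tgrid > te
      sw[post] <- deswell_after_nap(tgrid[post] - te, lens, p,
                                    floor = sw[post])
      seg[post] <- "post-nap-deswell"
    }
  }

  # the open-eye portion is independent of the sleep-onset level, so the
  # steady-state starting level is just the level at the end of this day
  s_start <- if (identical(start_level, "steady")) sw[length(sw)] else
    start_level
  if (s_start < 0) stop("`start_level` must be non-negative", call. = FALSE)
  s_open <- eye_opening_swelling(lens_night, p)
  night <- tgrid <= wake
  sw[night] <- s_start + (s_open - s_start) *
    log(po$Bh * tgrid[night] + 1) / log(po$Bh * wake + 1)
  seg[night] <- "overnight"
  sw <- pmax(sw, 0)

  structure(data.frame(time = tgrid, swelling = sw, segment = seg,
                       stringsAsFactors = FALSE),
            class = c("edema_trajectory", "data.frame"),
            scenario = attr(sched, "scenario"), lens = lens, dt = dt,
            nap_active = nap_active, start_level = s_start)
}

#' Simulate a chain of days with carried-over state
#'
#' Simulates consecutive 24-h windows, carrying the end-of-day swelling of
#' each window into the overnight anchor of the next. Used for multi-day
#' patterns such as continuous wear.
#'
#' @param scenarios Character vector of scenario names, one per day
#'   (recycled singletons allowed via `rep()` by the caller).
#' @inheritParams simulate_day
#' @param start_level Swelling at the first sleep onset (default 0).
#' @return An `edema_trajectory` data frame spanning `24 * length(scenarios)`
#'   hours, with a `day` column.
#' @export
simulate_days <- function(scenarios, lens, po, p, dt = 1 / 60,
                          start_level = 0, ...) {
  out <- vector("list", length(scenarios))
  lvl <- start_level
  for (d in seq_along(scenarios)) {
    sched <- build_schedule(scenarios[d], ...)
    tr <- simulate_day(sched, lens, po, p, dt = dt, start_level = lvl)
    lvl <- tr$swelling[nrow(tr)]
    tr$day <- d
    tr$time <- tr$time + 24 * (d - 1)
    out[[d]] <- as.data.frame(tr)
  }
  res <- do.call(rbind, out)
  structure(res, class = c("edema_trajectory", "data.frame"),
            scenario = scenarios, lens = lens, dt = dt)
}

#' @export
print.wear_schedule <- function(x, ...) {
  cat("Wear schedule (", attr(x, "scenario"), "), clock starts at sleep onset:\n",
      sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
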