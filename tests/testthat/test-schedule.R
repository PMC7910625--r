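test_that("canonical schedules carry the expected events", {
  s <- build_schedule("daily_compliant")
  expect_equal(s$time[s$kind == "wake"], 8)
  expect_equal(s$time[s$kind == "lens_insert"], 9)
  expect_equal(s$time[s$kind == "lens_remove"], 23)
  expect_true(all(diff(s$time) >= 0))

  expect_false(any(build_schedule("no_lens")$kind %in%
                     c("lens_insert", "lens_remove")))

  s_nap <- build_schedule("daily_nap")
  expect_equal(s_nap$time[s_nap$kind == "nap_start"], 14)
  expect_equal(s_nap$time[s_nap$kind == "nap_end"], 15)

  s_ew <- build_schedule("sleep_in_lens")
  expect_true(attr(s_ew, "lens_overnight"))
  expect_equal(s_ew$time[s_ew$kind == "lens_remove"], 23)

  expect_error(build_schedule("weekend"), "unknown scenario")
  expect_error(build_schedule("daily_compliant", wear_hours = 17), "0, 16")
})

test_that("no-lens day peaks at the published eye-opening level", {
  tr <- simulate_day(build_schedule("no_lens"), no_lens(p_ref), po_ref,
                     p_ref)
  expect_equal(range(tr$time), c(0, 24))
  expect_true(all(tr$swelling >= 0))
  expect_equal(max(tr$swelling), 3.3, tolerance = 0.05 / 3.3)
  expect_equal(tr$time[which.max(tr$swelling)], 8)
  expect_equal(daily_load(tr), 23.12, tolerance = 1e-3)
})

test_that("overnight-wear day peaks at the lens eye-opening level", {
  tr <- simulate_day(build_schedule("sleep_in_lens"), lens_config(11),
                     po_ref, p_ref)
  expect_equal(max(tr$swelling),
               eye_opening_swelling(lens_config(11), p_ref),
               tolerance = 1e-9)
  expect_equal(tr$time[which.max(tr$swelling)], 8)
})

test_that("trajectories are continuous across segment boundaries", {
  for (scen in c("no_lens", "daily_compliant", "daily_nap",
                 "sleep_in_lens")) {
    lens <- if (scen == "no_lens") no_lens(p_ref) else lens_config(11)
    tr <- simulate_day(build_schedule(scen), lens, po_ref, p_ref)
    # steepest model slope is ~0.6 %/min early in the night
    expect_lt(max(abs(diff(tr$swelling))), 0.8)
    expect_setequal(unique(tr$segment[tr$time < 8]), "overnight")
  }
})

test_that("sleeping in lenses dominates compliant wear pointwise", {
  for (dkt in c(27, 100)) {
    lens <- lens_config(dkt)
    tr_ew <- simulate_day(build_schedule("sleep_in_lens"), lens, po_ref,
                          p_ref)
    tr_dd <- simulate_day(build_schedule("daily_compliant"), lens,
                          po_ref, p_ref)
    expect_true(all(tr_ew$swelling - tr_dd$swelling >= -1e-9))
  }
})

test_that("a Dk/t = DN lens collapses every scenario to no lens wear", {
  ref <- simulate_day(build_schedule("no_lens"), no_lens(p_ref), po_ref,
                      p_ref)
  for (scen in c("daily_compliant", "sleep_in_lens",
                 "continuous_wear_offnight")) {
    tr <- simulate_day(build_schedule(scen), no_lens(p_ref), po_ref,
                       p_ref)
    expect_equal(tr$swelling, ref$swelling, tolerance = 1e-12)
  }
  expect_warning(
    tr_nap <- simulate_day(build_schedule("daily_nap"), no_lens(p_ref),
                           po_ref, p_ref),
    "nap ignored")
  expect_equal(tr_nap$swelling, ref$swelling, tolerance = 1e-12)
})

test_that("trajectory AUC is stable under grid refinement", {
  for (scen in c("daily_nap", "sleep_in_lens")) {
    sched <- build_schedule(scen)
    a1 <- daily_load(simulate_day(sched, lens_config(27), po_ref, p_ref,
                                  dt = 1 / 60))
    a2 <- daily_load(simulate_day(sched, lens_config(27), po_ref, p_ref,
                                  dt = 1 / 240))
    expect_lt(abs(a1 - a2) / a2, 0.001)
  }
  expect_error(simulate_day(build_schedule("no_lens"), no_lens(p_ref),
                            po_ref, p_ref, dt = 0.1), "1/60")
})

test_that("a high-Dk/t lens adds almost nothing by end of day", {
  tr157 <- simulate_day(build_schedule("daily_compliant"),
                        lens_config(157), po_ref, p_ref)
  tr0 <- simulate_day(build_schedule("no_lens"), no_lens(p_ref), po_ref,
                      p_ref)
  n <- nrow(tr157)
  expect_lt(tr157$swelling[n] - tr0$swelling[n], 0.1)
})

test_that("nap days rise to the post-nap level and stay above background", {
  lens <- lens_config(27)
  tr_nap <- simulate_day(build_schedule("daily_nap"), lens, po_ref, p_ref)
  tr_bg <- simulate_day(build_schedule("daily_compliant"), lens, po_ref,
                        p_ref)
  at <- function(tr, t) tr$swelling[which.min(abs(tr$time - t))]
  expect_equal(at(tr_nap, 15), deswell_after_nap(0, lens, p_ref),
               tolerance = 1e-9)
  post <- tr_nap$time > 15
  expect_true(all(tr_nap$swelling[post] - tr_bg$swelling[post] >= -1e-9))
  expect_gt(daily_load(tr_nap), daily_load(tr_bg))
})

test_that("chained days carry end-of-day state into the next night", {
  tr <- simulate_days(rep("continuous_wear_day", 3), lens_config(27),
                      po_ref, p_ref)
  expect_equal(range(tr$time), c(0, 72))
  end_d1 <- tr$swelling[max(which(tr$day == 1))]
  start_d2 <- tr$swelling[min(which(tr$day == 2))]
  expect_equal(start_d2, end_d1, tolerance = 1e-9)
  # mornings repeat once past the first day
  at <- function(t) tr$swelling[which.min(abs(tr$time - t))]
  expect_equal(at(32), at(56), tolerance = 1e-6)
})
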