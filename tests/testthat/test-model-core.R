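test_that("eye-opening swelling reproduces the published anchor triple", {
  p <- p_ref
  expect_equal(eye_opening_swelling(lens_config(11, p$DN), p), 10.8,
               tolerance = 0.05 / 10.8)
  expect_equal(eye_opening_swelling(lens_config(p$DN, 11), p), 3.9,
               tolerance = 0.05 / 3.9)
  expect_equal(eye_opening_swelling(no_lens(p), p), 3.3,
               tolerance = 0.05 / 3.3)
})

test_that("the residual exponent calibration solves the anchor exactly", {
  expect_gt(p_ref$b, 0.5)
  expect_lt(p_ref$b, 0.8)
  expect_equal(eye_opening_swelling(lens_config(11, p_ref$DN), p_ref),
               10.8, tolerance = 1e-9)
  # a different anchor moves the root accordingly
  b2 <- calibrate_b(p_ref, anchor = 10.5)
  p2 <- p_ref; p2$b <- b2
  expect_equal(eye_opening_swelling(lens_config(11, p2$DN), p2), 10.5,
               tolerance = 1e-9)
  expect_error(calibrate_b(p_ref, anchor = 30), "unattainable")
})

test_that("deswelling curves agree with hand-written closed forms", {
  p <- p_ref
  for (case in list(c(11, 177, 0), c(11, 177, 1), c(27, 27, 3.5),
                    c(157, 11, 12))) {
    di <- case[1]; dc <- case[2]; t <- case[3]
    oracle <- (p$Bnap + p$Bdiff) *
      exp(-(di * (p$kD + p$k2 * t) + dc * (p$kcD + p$kc2 * t) +
              p$kdeswell * t)) +
      (p$L0 + p$Ldiff) * (di^(-p$b) - p$DN^(-p$b))
    expect_equal(deswell_after_sleep(t, lens_config(di, dc), p),
                 oracle, tolerance = 1e-12)
    # the nap curve differs only through the Bnap-for-(Bnap+Bdiff) scale
    expect_equal(deswell_after_nap(t, lens_config(di, dc), p),
                 max(0, oracle - p$Bdiff *
                       exp(-(di * (p$kD + p$k2 * t) +
                               dc * (p$kcD + p$kc2 * t) +
                               p$kdeswell * t))),
                 tolerance = 1e-12)
  }
  expect_equal(eye_opening_swelling(lens_config(11), p_ref),
               eye_open_oracle(11, 11, p_ref))
  # t = 0 consistency between the sleep curve and eye opening
  for (lens in list(lens_config(27), lens_config(100, 11)))
    expect_identical(deswell_after_sleep(0, lens, p_ref),
                     eye_opening_swelling(lens, p_ref))
})

test_that("deswelling is monotone non-increasing in time and Dk/t", {
  tt <- seq(0, 16, by = 0.25)
  for (dkt in c(11, 27, 100, 157)) {
    s <- deswell_after_sleep(tt, lens_config(dkt), p_ref)
    expect_true(all(diff(s) <= 1e-12))
    s_nap <- deswell_after_nap(tt, lens_config(dkt), p_ref)
    expect_true(all(diff(s_nap) <= 1e-12))
  }
  dkts <- c(11, 27, 61, 100, 157, 177)
  for (t in c(0, 1, 4, 12)) {
    s_ipsi <- sapply(dkts, function(d)
      deswell_after_sleep(t, lens_config(d, 100), p_ref))
    s_contra <- sapply(dkts, function(d)
      deswell_after_sleep(t, lens_config(100, d), p_ref))
    expect_true(all(diff(s_ipsi) <= 1e-12))
    expect_true(all(diff(s_contra) <= 1e-12))
  }
  # long-time limit is the residual term
  res <- (p_ref$L0 + p_ref$Ldiff) * (27^(-p_ref$b) - p_ref$DN^(-p_ref$b))
  expect_equal(deswell_after_sleep(80, lens_config(27), p_ref), res,
               tolerance = 1e-9)
  expect_equal(deswell_after_sleep(80, no_lens(p_ref), p_ref), 0,
               tolerance = 1e-12)
})

test_that("daytime swelling: zero at insertion, increasing, DN-degenerate", {
  p <- p_ref
  expect_identical(daytime_swelling(0, lens_config(27), p), 0)
  expect_identical(daytime_swelling(c(1, 7, 14), no_lens(p), p),
                   c(0, 0, 0))
  s <- daytime_swelling(seq(0, 14, 0.5), lens_config(27), p)
  expect_true(all(diff(s) >= 0))
  # closed form at 14 h of wear
  expect_equal(daytime_swelling(14, lens_config(27), p),
               p$L0 * (27^(-p$b) - p$DN^(-p$b)) * log(p$kday * 14 + 1),
               tolerance = 1e-12)
  # daytime coefficient is the post-sleep residual scaled by L0/(L0+Ldiff)
  res_sleep <- deswell_after_sleep(1e6, lens_config(27), p)
  expect_equal(daytime_swelling(14, lens_config(27), p) /
                 log(p$kday * 14 + 1),
               res_sleep * p$L0 / (p$L0 + p$Ldiff), tolerance = 1e-6)
})

test_that("closed-eye curve endpoints and AUC match quadrature", {
  po <- po_ref
  expect_equal(overnight_curve(0, 5, po), 0)
  expect_equal(overnight_curve(8, 5, po), 5)
  for (sleep_h in c(1, 8)) {
    num <- integrate(function(t) overnight_curve(t, 1, po, sleep_h),
                     0, sleep_h, rel.tol = 1e-12)$value
    expect_equal(overnight_auc(1, po, sleep_h), num, tolerance = 1e-9)
  }
  # frozen value: an 8-h night contributes 6.37 %*h per % at eye opening
  expect_equal(overnight_auc(1, po, 8), 6.3709, tolerance = 1e-4)
})

test_that("oxygen equivalence inverts the closed-eye curve", {
  p <- p_ref; po <- po_ref
  s0 <- eye_opening_swelling(no_lens(p), p)
  ox <- equivalent_oxygen(no_lens(p), po, p)
  expect_equal(ox, po$A * log(po$Bh * 8 + 1) / s0, tolerance = 1e-12)
  expect_equal(ox, 1.819, tolerance = 1e-3)
  # reciprocal in swelling, hence lower oxygen for a tighter lens
  expect_lt(equivalent_oxygen(lens_config(11, p$DN), po, p), ox)
  expect_equal(equivalent_oxygen(lens_config(11, p$DN), po, p) /
                 ox, s0 / 10.8, tolerance = 1e-9)
})

test_that("thickness-to-swelling conversion and input validation", {
  expect_equal(thickness_to_swelling(550, 550), 0)
  expect_equal(thickness_to_swelling(605, 550), 10)
  expect_equal(thickness_to_swelling(561, 550), 2)
  expect_error(thickness_to_swelling(550, 0), "baseline")
  expect_error(deswell_after_sleep(-1, lens_config(27), p_ref), "non-negative")
  expect_error(daytime_swelling(-0.1, lens_config(27), p_ref), "non-negative")
  expect_error(lens_config(-5), "positive")
  expect_error(deswell_after_sleep(1, lens_config(200), p_ref), "DN")
  expect_error(overnight_curve(1, 5, po_ref, sleep_h = 0), "positive")
  expect_error(overnight_params(A = -1), "positive")
  expect_error(deswell_params(kdeswell = 0), "positive")
})

test_that("parameter sets round-trip through flat key-value files", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_params(p_ref, f)
  p2 <- read_params(f)
  expect_equal(unclass(p2), unclass(p_ref), tolerance = 1e-14)
  write_params(po_ref, f)
  expect_equal(unclass(read_params(f)), unclass(po_ref))
})
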