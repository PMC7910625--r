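noise_free_corpus <- function(seed = 7) {
  gen_overnight_corpus(p_ref, corpus_spec(sigma_u = 0, sigma_e = 0,
                                          seed = seed))
}

test_that("closed-eye parameters are recovered exactly without noise", {
  rec <- gen_goggle_study(po_ref, sigma_u = 0, sigma_e = 0)
  fit <- fit_overnight(rec)
  expect_equal(fit$params$A, po_ref$A, tolerance = 1e-6)
  expect_equal(fit$params$Bh, po_ref$Bh, tolerance = 1e-6)
  expect_true(all(is.finite(fit$se)))
})

test_that("closed-eye fit recovers truth on a noisy goggle corpus", {
  rec <- gen_goggle_study(po_ref, sigma_u = 0.3, sigma_e = 0.4,
                          seed = 11)
  fit <- fit_overnight(rec)
  # same order of magnitude as the published uncertainty (SE ~ 0.5 on A)
  expect_equal(fit$params$A, po_ref$A, tolerance = 0.5)
  expect_gt(fit$se[["A"]], 0.005)
  expect_lt(fit$se[["A"]], 5)
})

test_that("closed-eye fit refuses non-identifiable designs", {
  rec <- gen_goggle_study(po_ref, sigma_u = 0, sigma_e = 0)
  expect_error(fit_overnight(rec[rec$t == 2, ]), "3 time points")
  expect_error(fit_overnight(rec[rec$oxygen == 5, ]), "oxygen levels")
})

test_that("all twelve coefficients are recovered from a noise-free corpus", {
  rec <- noise_free_corpus()
  fit <- fit_deswell(rec, n_starts = 2, se_type = "asymptotic")
  nm <- c("Bnap", "Bdiff", "kdeswell", "kD", "kcD", "k2", "kc2", "DN",
          "L0", "Ldiff", "kday", "b")
  est <- unlist(fit$params[nm])
  tru <- unlist(p_ref[nm])
  expect_equal(est, tru, tolerance = 1e-4)
})

test_that("deswell fit refuses non-identifiable corpora", {
  rec <- noise_free_corpus()
  expect_error(fit_deswell(rec[rec$phase != "post_nap", ]),
               "post_nap")
  one_dkt <- rec[rec$dkt_ipsi == 27 & rec$dkt_contra == 27, ]
  expect_error(fit_deswell(one_dkt), "kD")
})

test_that("weighting is inert when every record is individual-level", {
  rec <- noise_free_corpus()
  rec <- rec[rec$n == 1, ]
  rec$swelling <- rec$swelling + rnorm(nrow(rec), 0, 0.2)  # same data both fits
  f_w <- fit_deswell(rec, weight_mode = "inverse_n", n_starts = 1,
                     se_type = "asymptotic")
  f_u <- fit_deswell(rec, weight_mode = "unweighted", n_starts = 1,
                     se_type = "asymptotic")
  expect_equal(unlist(f_w$params), unlist(f_u$params), tolerance = 1e-8)
})

test_that("estimates ignore record order and respect weight arithmetic", {
  rec <- gen_overnight_corpus(p_ref, corpus_spec(n_lens_points = 300,
                                                 n_nolens_points = 280,
                                                 sigma_u = 0.5,
                                                 sigma_e = 0.3,
                                                 seed = 77))
  base <- fit_deswell(rec, n_starts = 1, se_type = "asymptotic")
  shuf <- fit_deswell(rec[rev(seq_len(nrow(rec))), ], n_starts = 1,
                      se_type = "asymptotic")
  # kday sits on a near-flat ridge; order permutations move it by ~1e-4
  expect_equal(unlist(base$params), unlist(shuf$params),
               tolerance = 1e-3)
  # listing a record twice equals halving its n (doubling its 1/n weight)
  i <- which(rec$study_mean)[1]
  dup <- rbind(rec, rec[i, ])
  dup$n[c(i, nrow(dup))] <- rec$n[i] * 2
  f_dup <- fit_deswell(dup, n_starts = 1, se_type = "asymptotic")
  expect_equal(unlist(f_dup$params), unlist(base$params),
               tolerance = 1e-3)
})

test_that("the objective profile in b is unimodal near the calibration", {
  rec <- noise_free_corpus()
  w <- 1 / rec$n
  nm <- setdiff(c("Bnap", "Bdiff", "kdeswell", "kD", "kcD", "k2", "kc2",
                  "DN", "L0", "Ldiff", "kday", "b"), "b")
  grid <- seq(0.2, 1.6, by = 0.1)
  # profile objective: refit all other coefficients at each fixed b
  ssr <- sapply(grid, function(b) {
    rf <- function(par) {
      q <- as.list(par); q$b <- b
      sqrt(w) * (rec$swelling - predict_swelling(rec, q))
    }
    suppressWarnings(
      minpack.lm::nls.lm(unlist(p_ref[nm]), fn = rf,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300))$deviance)
  })
  drops <- diff(ssr) < 0
  # decreasing then increasing: exactly one sign change
  expect_equal(sum(diff(drops) != 0), 1)
  expect_equal(which.min(ssr), which.min(abs(grid - p_ref$b)))
})

test_that("residuals dispatch on phase and vanish for perfect data", {
  rec <- noise_free_corpus()
  out <- swelling_residuals(rec, p_ref)
  expect_equal(max(abs(out$resid)), 0, tolerance = 1e-12)
  # the same record under a different phase tag predicts differently
  r1 <- rec[rec$phase == "post_sleep" & rec$dkt_ipsi < p_ref$DN, ][1, ]
  r2 <- r1; r2$phase <- "post_nap"
  expect_equal(predict_swelling(r1, p_ref) - predict_swelling(r2, p_ref),
               p_ref$Bdiff * exp(-(r1$dkt_ipsi * (p_ref$kD + p_ref$k2 * r1$t) +
                                     r1$dkt_contra * (p_ref$kcD + p_ref$kc2 * r1$t) +
                                     p_ref$kdeswell * r1$t)),
               tolerance = 1e-12)
  # unbiased noise gives near-zero mean residual
  noisy <- gen_overnight_corpus(p_ref, corpus_spec(seed = 31))
  mres <- mean(swelling_residuals(noisy, p_ref)$resid)
  expect_lt(abs(mres), 0.15)
})
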