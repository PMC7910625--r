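# Weighted nonlinear least-squares estimation of the swelling model from
# a collated swelling dataset.

.phases <- c("post_sleep", "daytime", "post_nap", "closed_eye")

#' Predict swelling for collated records
#'
#' Evaluates the model for each record, dispatching on its `phase` tag:
#' `"post_sleep"` and `"post_nap"` use the deswelling curves, `"daytime"`
#' the post-insertion swelling curve, and `"closed_eye"` the goggle-study
#' closed-eye curve (which requires an `oxygen` column and overnight
#' parameters `po`). Predictions are the raw closed forms, without the
#' clamping applied by the trajectory simulator.
#'
#' @param records Data frame with columns `phase`, `t`, `dkt_ipsi`,
#'   `dkt_contra`, and (for closed-eye records) `oxygen`.
#' @param p A [deswell_params()] set.
#' @param po An [overnight_params()] set (only needed for closed-eye
#'   records).
#' @return Numeric vector of predicted swelling (%).
#' @export
predict_swelling <- function(records, p, po = NULL) {
  check_records(records)
  pred <- numeric(nrow(records))
  ph <- records$phase
  t <- records$t
  di <- records$dkt_ipsi
  dc <- records$dkt_contra
  expo <- di * (p$kD + p$k2 * t) + dc * (p$kcD + p$kc2 * t) +
    p$kdeswell * t
  res_full <- (p$L0 + p$Ldiff) * (di^(-p$b) - p$DN^(-p$b))
  i <- ph == "post_sleep"
  pred[i] <- (p$Bnap + p$Bdiff) * exp(-expo[i]) + res_full[i]
  i <- ph == "post_nap"
  pred[i] <- p$Bnap * exp(-expo[i]) + res_full[i]
  i <- ph == "daytime"
  pred[i] <- p$L0 * (di[i]^(-p$b) - p$DN^(-p$b)) * log(p$kday * t[i] + 1)
  i <- ph == "closed_eye"
  if (any(i)) {
    if (is.null(po))
      stop("closed-eye records need overnight parameters `po`",
           call. = FALSE)
    pred[i] <- po$A * log(po$Bh * t[i] + 1) / records$oxygen[i]
  }
  pred
}

check_records <- function(records, need = c("phase", "t")) {
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(records$phase), .phases)
  if (length(bad))
    stop("unknown phase tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(records)
}

record_weights <- function(records, weight_mode) {
  n <- if ("n" %in% names(records)) records$n else rep(1, nrow(records))
  switch(weight_mode,
         inverse_n = 1 / n,
         n = n,
         unweighted = rep(1, nrow(records)),
         stop("unknown weight_mode: ", weight_mode, call. = FALSE))
}

# save/restore the global RNG state around a seeded computation
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fit the closed-eye swelling curve to goggle-study data
#'
#' Nonlinear least squares (Levenberg-Marquardt) estimation of the
#' closed-eye parameters `A` and `Bh` from swelling time courses measured
#' under controlled oxygen mixtures: `swelling = A log(Bh t + 1)/oxygen`.
#'
#' @param records Data frame of closed-eye records: columns `t` (hours of
#'   closure), `oxygen` (oxygen availability), `swelling` (%), and
#'   optionally `n`.
#' @param start Named starting values for `A` and `Bh`.
#' @param weight_mode Per-record weighting: `"inverse_n"`, `"n"` or
#'   `"unweighted"`.
#' @return A list with `params` ([overnight_params()]), `se` (named
#'   asymptotic standard errors) and `convergence` metadata.
#' @export
fit_overnight <- function(records, start = c(A = 1, Bh = 5),
                          weight_mode = c("unweighted", "inverse_n", "n")) {
  weight_mode <- match.arg(weight_mode)
  need <- c("t", "oxygen", "swelling")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(unique(records$oxygen)) < 2)
    stop("need at least 2 oxygen levels", call. = FALSE)
  if (length(unique(records$t)) < 3)
    stop("need at least 3 time points: A and Bh are not identifiable ",
         "from fewer", call. = FALSE)
  sw <- sqrt(record_weights(records, weight_mode))
  resid_fn <- function(par) {
    sw * (records$swelling -
            par[["A"]] * log(par[["Bh"]] * records$t + 1) / records$oxygen)
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            lower = c(1e-8, 1e-8),
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-12, ptol = 1e-12, maxiter = 200))
  if (fit$info %in% c(0, 5))
    stop("overnight fit did not converge (residual norm ",
         format(sqrt(fit$deviance)), ")", call. = FALSE)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 2))
  list(params = overnight_params(A = fit$par[["A"]], Bh = fit$par[["Bh"]]),
       se = stats::setNames(as.numeric(se), names(fit$par)),
       convergence = list(info = fit$info, message = fit$message,
                          deviance = fit$deviance,
                          niter = fit$niter))
}

.deswell_par_names <- c("Bnap", "Bdiff", "kdeswell", "kD", "kcD", "k2",
                        "kc2", "DN", "L0", "Ldiff", "kday", "b")

#' Fit the open-eye swelling model to a collated corpus
#'
#' Joint weighted nonlinear least squares over the post-sleep, post-nap
#' and daytime curves, combined by per-record phase indicators. All
#' twelve coefficients (including the residual exponent `b`) are
#' estimated. Default weighting is the inverse of the record's sample
#' size `n`; weighting by `n` and unweighted fits are available for
#' sensitivity analysis. Optimisation is Levenberg-Marquardt with
#' multi-start from jittered initial values (fixed jitter seed), keeping
#' the best converged solution.
#'
#' Standard errors are computed by a cluster bootstrap by default,
#' resampling subjects (individual records of one subject stay together;
#' each study-mean record is its own cluster) and refitting each
#' replicate from the estimator's own starting values: repeated observations of one subject share a
#' random swelling offset, study-mean records have n-dependent variance,
#' and two coefficients (`kday`, and with it `L0`/`Ldiff`) sit on a
#' near-flat likelihood ridge, so model-based Wald standard errors are
#' anticonservative here. A sandwich (`"cluster_robust"`) and the plain
#' asymptotic NLS standard error are available as cheaper alternatives.
#'
#' @param records Collated swelling records: columns `phase`, `t`,
#'   `dkt_ipsi`, `dkt_contra`, `swelling`, and optionally `n`.
#' @param weight_mode `"inverse_n"` (default), `"n"` or `"unweighted"`.
#' @param start Named numeric vector of starting values (default: the
#'   packaged published coefficients).
#' @param n_starts Number of jittered starts.
#' @param seed Seed for the start jitter.
#' @param se_type `"cluster_bootstrap"` (default), `"cluster_robust"` or
#'   `"asymptotic"`.
#' @param n_boot Bootstrap replicates for `se_type = "cluster_bootstrap"`.
#' @return An object of class `deswell_fit`: list with `params`
#'   ([deswell_params()] including the fitted `b`), `se`, `convergence`
#'   and `weight_mode`.
#' @export
fit_deswell <- function(records,
                        weight_mode = c("inverse_n", "n", "unweighted"),
                        start = NULL, n_starts = 10, seed = 1,
                        se_type = c("cluster_bootstrap", "cluster_robust",
                                    "asymptotic"),
                        n_boot = 40) {
  weight_mode <- match.arg(weight_mode)
  se_type <- match.arg(se_type)
  check_records(records, need = c("phase", "t", "dkt_ipsi", "dkt_contra",
                                  "swelling"))
  open_ph <- intersect(c("post_sleep", "daytime", "post_nap"),
                       unique(records$phase))
  if (length(open_ph) < 3)
    stop("identifiability: records must cover the post-sleep, daytime ",
         "and post-nap phases; missing ",
         paste(setdiff(c("post_sleep", "daytime", "post_nap"), open_ph),
               collapse = ", "), call. = FALSE)
  records <- records[records$phase != "closed_eye", , drop = FALSE]
  if (length(unique(records$dkt_ipsi)) < 3)
    stop("identifiability: need at least 3 distinct Dk/t values; with a ",
         "single Dk/t the coefficients kD and k2 are unconstrained",
         call. = FALSE)

  if (is.null(start)) {
    p0 <- edema_params("table2_2021")
    start <- unlist(p0[.deswell_par_names])
  }
  start <- start[.deswell_par_names]
  sw <- sqrt(record_weights(records, weight_mode))
  resid_fn <- function(par) {
    p <- as.list(par)
    sw * (records$swelling - predict_swelling(records, p))
  }
  lower <- stats::setNames(rep(-Inf, 12), .deswell_par_names)
  lower[c("Bnap", "Bdiff", "kdeswell", "kD", "kcD", "DN", "L0", "Ldiff",
          "kday")] <- 1e-8
  lower["b"] <- 0.01

  starts <- with_seed(seed, {
    c(list(start),
      lapply(seq_len(max(0, n_starts - 1)), function(i)
        start * exp(stats::rnorm(length(start), 0, 0.05))))
  })
  best <- NULL
  fallback <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s0, fn = resid_fn, lower = lower,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$info %in% c(0, 5)) {
      # iteration limit: keep as a fallback solution only
      if (fit$info == 5 &&
          (is.null(fallback) || fit$deviance < fallback$deviance))
        fallback <- fit
      next
    }
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best) && !is.null(fallback)) {
    warning("deswell fit stopped at the iteration limit; estimates may ",
            "sit on a flat ridge", call. = FALSE)
    best <- fallback
  }
  if (is.null(best))
    stop("deswell fit did not converge from any start", call. = FALSE)
  cl <- if ("subject_id" %in% names(records))
    records$subject_id else rep(NA_character_, nrow(records))
  cl[is.na(cl)] <- paste0(".rec", which(is.na(cl)))
  se <- switch(se_type,
    cluster_robust = cluster_robust_se(unlist(best$par), resid_fn, cl),
    cluster_bootstrap = cluster_bootstrap_se(records, cl, start,
                                             weight_mode, lower, n_boot,
                                             seed),
    asymptotic = tryCatch(summary(best)$coefficients[, "Std. Error"],
                          error = function(e)
                            rep(NA_real_, length(best$par))))
  est <- as.list(best$par)
  structure(list(params = do.call(deswell_params, est),
                 se = stats::setNames(as.numeric(se), names(best$par)),
                 convergence = list(info = best$info,
                                    message = best$message,
                                    deviance = best$deviance,
                                    niter = best$niter,
                                    n_starts = length(starts)),
                 weight_mode = weight_mode),
            class = "deswell_fit")
}

#' @export
print.deswell_fit <- function(x, ...) {
  cat("Swelling model fit (weighted NLS, weights:", x$weight_mode, ")\n")
  est <- unlist(x$params[.deswell_par_names])
  print(data.frame(estimate = signif(est, 4),
                   se = signif(x$se[.deswell_par_names], 3)))
  cat("deviance:", format(x$convergence$deviance), "\n")
  invisible(x)
}

# cluster bootstrap SE: resample clusters with replacement, refit each
# replicate from the same starting values the estimator itself used (not
# from the full-data optimum, which would pull replicates toward it and
# understate the spread), take the per-coefficient SD across replicates
cluster_bootstrap_se <- function(records, cl, start, weight_mode,
                                 lower, n_boot, seed) {
  idx <- split(seq_len(nrow(records)), cl)
  ests <- with_seed(seed + 1L, {
    vapply(seq_len(n_boot), function(b) {
      take <- unlist(idx[sample(length(idx), replace = TRUE)],
                     use.names = FALSE)
      rb <- records[take, , drop = FALSE]
      swb <- sqrt(record_weights(rb, weight_mode))
      rfb <- function(par) {
        swb * (rb$swelling - predict_swelling(rb, as.list(par)))
      }
      fit <- tryCatch(
        minpack.lm::nls.lm(par = start, fn = rfb, lower = lower,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-10, ptol = 1e-10, maxiter = 300)),
        error = function(e) NULL)
      if (is.null(fit)) rep(NA_real_, length(start)) else
        unlist(fit$par)
    }, numeric(length(start)))
  })
  apply(ests, 1, stats::sd, na.rm = TRUE)
}

# sandwich variance for a least-squares fit: (J'J)^-1 (sum_c g_c g_c')
# (J'J)^-1 with per-cluster scores g_c = J_c' r_c, J the numeric Jacobian
# of the weighted residual vector at the optimum
cluster_robust_se <- function(par, resid_fn, cluster) {
  r0 <- resid_fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- max(1e-6, abs(par[j]) * 1e-6)
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (resid_fn(up) - resid_fn(dn)) / (2 * h)
  }
  A <- crossprod(J)
  scores <- rowsum(J * r0, cluster)
  B <- crossprod(as.matrix(scores))
  G <- nrow(scores)
  # equilibrate: coefficient scales span five orders of magnitude
  d <- 1 / sqrt(pmax(diag(A), .Machine$double.eps))
  As <- A * tcrossprod(d)
  Ainv_s <- solve(As, tol = .Machine$double.eps)
  Ainv <- Ainv_s * tcrossprod(d)
  V <- Ainv %*% B %*% Ainv * G / max(1, G - 1)
  stats::setNames(sqrt(pmax(diag(V), 0)), names(par))
}

#' Residuals of the swelling model
#'
#' Observed minus predicted swelling per record, with the prediction
#' dispatched on each record's phase tag. Individual-level records keep
#' their subject identifier so the result can feed
#' [fit_subject_effects()].
#'
#' @inheritParams predict_swelling
#' @return The `records` data frame with added columns `pred` and
#'   `resid`.
#' @export
swelling_residuals <- function(records, p, po = NULL) {
  records$pred <- predict_swelling(records, p, po)
  records$resid <- records$swelling - records$pred
  records
}
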