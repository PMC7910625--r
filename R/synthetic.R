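# Synthetic literature-corpus generator: datasets with the statistical
# structure the fit assumes (individual and study-mean records, subject
# random effects, Gaussian noise), so fitting and variance-component
# estimation are testable without any external data.

#' Specification of a synthetic swelling corpus
#'
#' Describes the shape of a synthetic collated-literature dataset. The
#' defaults mirror the collated corpus the published coefficients were
#' estimated from: 561 lens-wear points (overnight lens wear), 512 points
#' without overnight lens wear (bare-eye nights, post-insertion daytime
#' swelling, naps), 64% individual-level records and 36% study means.
#'
#' @param n_lens_points Records with overnight lens wear.
#' @param n_nolens_points Records without overnight lens wear.
#' @param individual_fraction Proportion of records that are
#'   individual-level (`n = 1`).
#' @param dkt_menu Lens Dk/t values sampled by the generator.
#' @param sigma_u Between-subject SD of the swelling offset (%).
#' @param sigma_e Residual (within-subject / measurement) SD (%).
#' @param seed Integer seed; every generator is a pure function of
#'   (parameters, spec, seed).
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_lens_points = 561, n_nolens_points = 512,
                        individual_fraction = 0.64,
                        dkt_menu = c(11, 20, 27, 46, 61, 87, 100, 127, 157),
                        sigma_u = 1.0, sigma_e = 0.5, seed = 20210222) {
  if (individual_fraction < 0 || individual_fraction > 1)
    stop("`individual_fraction` must lie in [0, 1]", call. = FALSE)
  if (n_lens_points < 0 || n_nolens_points < 0)
    stop("point counts must be non-negative", call. = FALSE)
  structure(list(n_lens_points = n_lens_points,
                 n_nolens_points = n_nolens_points,
                 individual_fraction = individual_fraction,
                 dkt_menu = dkt_menu, sigma_u = sigma_u,
                 sigma_e = sigma_e, seed = as.integer(seed)),
            class = "corpus_spec")
}

new_record <- function(study_id, subject_id, study_mean, n, phase, t,
                       dkt_ipsi, dkt_contra, oxygen, swelling,
                       instrument) {
  data.frame(study_id = study_id, subject_id = subject_id,
             study_mean = study_mean, n = n, phase = phase, t = t,
             dkt_ipsi = dkt_ipsi, dkt_contra = dkt_contra,
             oxygen = oxygen, swelling = swelling,
             instrument = instrument, stringsAsFactors = FALSE)
}

#' Generate a goggle oxygen-mixture study
#'
#' Closed-eye swelling time courses for `n_subjects` individuals measured
#' hourly over `max(times)` hours of eye closure under several controlled
#' oxygen mixtures, following the closed-eye curve
#' `A log(Bh t + 1)/oxygen` plus a subject offset and Gaussian noise.
#'
#' @param po An [overnight_params()] set.
#' @param oxygen_levels Oxygen availabilities of the gas mixtures.
#' @param n_subjects Number of participants (default 8).
#' @param times Measurement times (hours of closure).
#' @param sigma_u Between-subject SD (%).
#' @param sigma_e Measurement SD (%).
#' @param seed Integer seed.
#' @return A records data frame (phase `"closed_eye"`).
#' @export
gen_goggle_study <- function(po = edema_params("table1_2021"),
                             oxygen_levels = c(1, 2, 5, 10, 21),
                             n_subjects = 8, times = 0:8,
                             sigma_u = 0.3, sigma_e = 0.4,
                             seed = 20210222) {
  if (length(oxygen_levels) < 2)
    stop("need at least 2 oxygen levels", call. = FALSE)
  with_seed(seed, {
    u <- stats::rnorm(n_subjects, 0, sigma_u)
    grid <- expand.grid(subject = seq_len(n_subjects),
                        oxygen = oxygen_levels, t = times)
    truth <- po$A * log(po$Bh * grid$t + 1) / grid$oxygen
    sw <- truth + u[grid$subject] + stats::rnorm(nrow(grid), 0, sigma_e)
    new_record(study_id = "goggle",
               subject_id = sprintf("goggle_s%02d", grid$subject),
               study_mean = FALSE, n = 1, phase = "closed_eye",
               t = grid$t, dkt_ipsi = NA_real_, dkt_contra = NA_real_,
               oxygen = grid$oxygen, swelling = sw,
               instrument = "optical")
  })
}

# time-point menus mimicking common pachymetry designs
.t_post_sleep <- c(0, 1 / 3, 1, 2, 3, 5, 12)
.t_daytime <- 1:14
.t_post_nap <- c(0, 0.5, 1, 2, 3)

#' Generate a collated overnight/daytime swelling corpus
#'
#' Synthetic counterpart of a collated literature dataset: a mixture of
#' individual-level (`n = 1`) and study-mean records spanning the
#' post-sleep, daytime and post-nap phases. Lens-wear points are
#' post-sleep records after a night in the lens (about a quarter with a
#' contralateral design: the lens in one eye only, both eyes measured);
#' no-overnight-wear points split between bare-eye nights, post-insertion
#' daytime swelling and post-nap deswelling. Individual records carry a
#' subject offset N(0, `sigma_u`^2) plus noise N(0, `sigma_e`^2);
#' study-mean records average `n` simulated individuals (drawn uniformly
#' from 5-30), shrinking both components by `sqrt(n)`.
#'
#' @param p A [deswell_params()] set used as generating truth.
#' @param spec A [corpus_spec()].
#' @return A records data frame in the collated schema.
#' @export
gen_overnight_corpus <- function(p = edema_params(), spec = corpus_spec()) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, {
    menu <- spec$dkt_menu
    n_lens <- spec$n_lens_points
    n_nol <- spec$n_nolens_points
    # phase layout: lens points are post-sleep; no-overnight-wear points
    # split 40/40/20 between bare-eye nights, daytime and naps
    ph <- c(rep("post_sleep", n_lens),
            rep("post_sleep_bare", round(0.4 * n_nol)),
            rep("daytime", round(0.4 * n_nol)))
    ph <- c(ph, rep("post_nap", n_lens + n_nol - length(ph)))
    m <- length(ph)
    di <- sample(menu, m, replace = TRUE)
    dc <- di
    # contralateral designs among lens-wear overnight records
    is_lens_night <- ph == "post_sleep"
    contra <- is_lens_night & stats::runif(m) < 0.25
    half <- contra & stats::runif(m) < 0.5
    dc[contra] <- p$DN          # lens in measured eye only
    di[half] <- p$DN            # measured eye bare, fellow eye lensed
    dc[half] <- sample(menu, sum(half), replace = TRUE)
    bare <- ph == "post_sleep_bare"
    di[bare] <- p$DN
    dc[bare] <- p$DN
    ph[bare] <- "post_sleep"
    t <- numeric(m)
    t[ph == "post_sleep"] <- sample(.t_post_sleep,
                                    sum(ph == "post_sleep"), TRUE)
    t[ph == "daytime"] <- sample(.t_daytime, sum(ph == "daytime"), TRUE)
    t[ph == "post_nap"] <- sample(.t_post_nap, sum(ph == "post_nap"), TRUE)

    rec <- new_record(study_id = sprintf("study%03d", 1 + (seq_len(m) - 1) %/% 25),
                      subject_id = NA_character_, study_mean = FALSE,
                      n = 1, phase = ph, t = t, dkt_ipsi = di,
                      dkt_contra = dc, oxygen = NA_real_,
                      swelling = NA_real_, instrument = sample(
                        c("optical", "ultrasonic"), m, TRUE))
    truth <- predict_swelling(rec, p)

    n_ind <- round(spec$individual_fraction * m)
    ind <- seq_len(m) %in% sample.int(m, n_ind)  # split within rounding
    rec$study_mean <- !ind
    rec$n[!ind] <- sample(5:30, sum(!ind), replace = TRUE)
    # individual records: a few observations per subject so the subject
    # variance component is estimable from residuals
    subj <- 1 + (seq_len(n_ind) - 1) %/% 3   # ~3 observations per subject
    rec$subject_id[ind] <- sprintf("subj%04d", subj)
    u <- stats::rnorm(max(subj), 0, spec$sigma_u)
    noise <- numeric(m)
    noise[ind] <- u[subj] + stats::rnorm(n_ind, 0, spec$sigma_e)
    noise[!ind] <- stats::rnorm(sum(!ind), 0,
                                sqrt(spec$sigma_u^2 + spec$sigma_e^2) /
                                  sqrt(rec$n[!ind]))
    rec$swelling <- truth + noise
    rec
  })
}

#' Continuous-wear deswelling consistency series
#'
#' Simulates seven chained days of continuous (overnight) wear for
#' several lens types and records swelling at eye opening and 1, 5 and
#' 12 h later on days 2-7, the classic repeated-pachymetry design. The
#' summary attribute reports the mean 12-h deswelling (eye-opening level
#' minus the level 12 h later), for comparison with the clinically
#' reported ~8% daytime deswelling after overnight lens wear.
#'
#' @param p,po Parameter sets.
#' @param dkt_values Lens Dk/t values to simulate.
#' @param dt Trajectory grid step (h).
#' @return Records data frame (noise-free, phase `"post_sleep"`) with a
#'   `day` column and attribute `mean_deswell_12h`.
#' @export
gen_deswell_check <- function(p = edema_params(),
                              po = edema_params("table1_2021"),
                              dkt_values = c(11, 27, 46), dt = 1 / 60) {
  out <- list()
  for (dkt in dkt_values) {
    lens <- lens_config(dkt)
    tr <- simulate_days(rep("continuous_wear_day", 7), lens, po, p,
                        dt = dt)
    for (day in 2:7) {
      wake <- (day - 1) * 24 + 8
      tt <- c(0, 1, 5, 12)
      sw <- vapply(wake + tt, function(x)
        tr$swelling[which.min(abs(tr$time - x))], numeric(1))
      out[[length(out) + 1L]] <- cbind(
        new_record(study_id = sprintf("cw_dkt%d", dkt),
                   subject_id = NA_character_, study_mean = TRUE,
                   n = 1, phase = "post_sleep", t = tt,
                   dkt_ipsi = dkt, dkt_contra = dkt, oxygen = NA_real_,
                   swelling = sw, instrument = "ultrasonic"),
        day = day)
    }
  }
  rec <- do.call(rbind, out)
  open <- rec$t == 0
  late <- rec$t == 12
  attr(rec, "mean_deswell_12h") <- mean(rec$swelling[open]) -
    mean(rec$swelling[late])
  rec
}

#' Read / write a collated swelling corpus as CSV
#'
#' Plain-text round trip for the collated-record schema used by the
#' fitting functions (UTF-8, header row, empty cells for missing values).
#'
#' @param records Records data frame.
#' @param path CSV file path.
#' @return `read_corpus_csv()` returns the records data frame;
#'   `write_corpus_csv()` returns `path` invisibly.
#' @export
write_corpus_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_corpus_csv
#' @export
read_corpus_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "",
                         colClasses = c(study_id = "character",
                                        subject_id = "character",
                                        instrument = "character"))
  rec$study_mean <- as.logical(rec$study_mean)
  check_records(rec)
  rec
}
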