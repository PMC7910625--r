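# Closed-form swelling/deswelling equations evaluated as pure functions.

# residual swelling term, shared by the post-sleep, post-nap and daytime
# curves; identically 0 when the ipsilateral eye is bare (dkt = DN)
residual_term <- function(dkt_ipsi, p, scale) {
  scale * (dkt_ipsi^(-p$b) - p$DN^(-p$b))
}

deswell_exponent <- function(t, lens, p) {
  lens$dkt_ipsi * (p$kD + p$k2 * t) +
    lens$dkt_contra * (p$kcD + p$kc2 * t) +
    p$kdeswell * t
}

#' Corneal swelling at eye opening after overnight sleep
#'
#' The post-sleep deswelling curve evaluated at the moment of eye opening
#' (`t = 0`): a lens-attenuated exponential scale `(Bnap + Bdiff)` plus the
#' residual swelling term. With the packaged parameters this reproduces the
#' published eye-opening anchors: 10.8% for a Dk/t-11 lens worn in the
#' measured eye only, 3.9% for the bare fellow eye of such a wearer, and
#' 3.3% with no lens in either eye.
#'
#' @param lens A [lens_config()].
#' @param p A [deswell_params()] coefficient set.
#' @return Swelling at eye opening (%), never negative.
#' @export
#' @examples
#' p <- edema_params()
#' eye_opening_swelling(lens_config(11, p$DN), p)   # ~10.8
#' eye_opening_swelling(no_lens(p), p)              # ~3.3
eye_opening_swelling <- function(lens, p) {
  deswell_after_sleep(0, lens, p)
}

#' Deswelling after overnight sleep
#'
#' Open-eye swelling `t` hours after eye opening following a full night of
#' sleep:
#' \deqn{(B_{nap}+B_{diff}) e^{-[D(k_D + k_2 t) + D_c(k_{cD} + k_{c2} t)
#'   + k_{deswell} t]} + (L_0+L_{diff})(D^{-b} - D_N^{-b}),}
#' where `D` and `Dc` are the ipsilateral and contralateral Dk/t. The curve
#' is non-increasing in `t` and tends to the residual term as `t` grows.
#'
#' @param t Hours since eye opening (vectorised, `t >= 0`).
#' @inheritParams eye_opening_swelling
#' @return Swelling (%), clamped at 0.
#' @export
deswell_after_sleep <- function(t, lens, p) {
  lens <- check_lens(lens, p)
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be non-negative hours since eye opening", call. = FALSE)
  s <- (p$Bnap + p$Bdiff) * exp(-deswell_exponent(t, lens, p)) +
    residual_term(lens$dkt_ipsi, p, p$L0 + p$Ldiff)
  pmax(s, 0)
}

#' Deswelling after a one-hour nap
#'
#' As [deswell_after_sleep()] but with the post-nap scale `Bnap` in place
#' of `(Bnap + Bdiff)`. Because a nap interrupts an ongoing open-eye day,
#' the result is floored at `floor` (the level the uninterrupted daytime
#' curve would have reached): post-nap swelling cannot drop below the
#' background it was superimposed on.
#'
#' @param t Hours since the end of the nap (vectorised, `t >= 0`).
#' @param floor Background swelling level(s) (%) to floor the curve at;
#'   scalar or vector recycled against `t`.
#' @inheritParams eye_opening_swelling
#' @return Swelling (%), clamped at 0.
#' @export
deswell_after_nap <- function(t, lens, p, floor = 0) {
  lens <- check_lens(lens, p)
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be non-negative hours since nap end", call. = FALSE)
  if (any(floor < 0))
    stop("`floor` must be non-negative", call. = FALSE)
  s <- p$Bnap * exp(-deswell_exponent(t, lens, p)) +
    residual_term(lens$dkt_ipsi, p, p$L0 + p$Ldiff)
  pmax(s, floor, 0)
}

#' Daytime swelling after lens insertion
#'
#' Swelling accumulated by open-eye lens wear, `t` hours after insertion:
#' \deqn{L_0 (D^{-b} - D_N^{-b}) \log(k_{day} t + 1).}
#' Zero at insertion, non-decreasing, and identically zero for a bare eye
#' (`Dk/t = DN`).
#'
#' @param t Hours since lens insertion (vectorised, `t >= 0`).
#' @inheritParams eye_opening_swelling
#' @return Swelling (%), clamped at 0.
#' @export
daytime_swelling <- function(t, lens, p) {
  lens <- check_lens(lens, p)
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be non-negative hours since lens insertion",
         call. = FALSE)
  pmax(residual_term(lens$dkt_ipsi, p, p$L0) * log(p$kday * t + 1), 0)
}

#' Closed-eye swelling curve (normalised shape)
#'
#' Swelling during a closed-eye interval follows
#' \eqn{A \log(B_h t + 1)/\mathrm{oxygen}}; expressed relative to the level
#' reached at the end of the interval, the oxygen term cancels and only the
#' logarithmic shape remains:
#' \deqn{S(t) = s_{open} \log(B_h t + 1) / \log(B_h\,\mathrm{sleep}_h + 1).}
#'
#' @param t Hours since eye closure (vectorised, `0 <= t <= sleep_h`).
#' @param s_open Swelling at eye opening (%), i.e. at `t = sleep_h`.
#' @param po An [overnight_params()] set.
#' @param sleep_h Duration of eye closure (h).
#' @return Swelling (%).
#' @export
overnight_curve <- function(t, s_open, po, sleep_h = 8) {
  if (!is.finite(sleep_h) || sleep_h <= 0)
    stop("`sleep_h` must be positive", call. = FALSE)
  if (any(s_open < 0)) stop("`s_open` must be non-negative", call. = FALSE)
  if (any(t < 0 - 1e-12) || any(t > sleep_h + 1e-12))
    stop("`t` must lie in [0, sleep_h]", call. = FALSE)
  s_open * log(po$Bh * pmin(pmax(t, 0), sleep_h) + 1) /
    log(po$Bh * sleep_h + 1)
}

# closed-form primitive of log(a t + 1): int_0^T log(a t + 1) dt
log_ramp_auc <- function(a, T) (T + 1 / a) * log(a * T + 1) - T

#' Area under the closed-eye swelling curve
#'
#' Closed-form \eqn{\int_0^{sleep_h} S(t)\,dt} of [overnight_curve()],
#' in %-hours. Used by the load calculator as a fast cross-checked
#' alternative to trapezoid integration of the overnight segment.
#'
#' @inheritParams overnight_curve
#' @return Area (%\eqn{\cdot}h).
#' @export
overnight_auc <- function(s_open, po, sleep_h = 8) {
  s_open * log_ramp_auc(po$Bh, sleep_h) / log(po$Bh * sleep_h + 1)
}

#' Oxygen availability equivalent to a lens configuration
#'
#' The closed-eye oxygen level at which the overnight curve ends exactly at
#' the configuration's eye-opening swelling: `oxygen` solves
#' \eqn{(A/\mathrm{oxygen}) \log(B_h\,\mathrm{sleep}_h + 1) = s_{open}}.
#' Strictly decreasing in eye-opening swelling.
#'
#' @inheritParams eye_opening_swelling
#' @param po An [overnight_params()] set.
#' @param sleep_h Hours of sleep.
#' @return Oxygen availability (model units, the scale of the goggle-study
#'   denominator).
#' @export
equivalent_oxygen <- function(lens, po, p, sleep_h = 8) {
  s0 <- eye_opening_swelling(lens, p)
  if (s0 <= 0)
    stop("eye-opening swelling is not positive; oxygen equivalent undefined",
         call. = FALSE)
  po$A * log(po$Bh * sleep_h + 1) / s0
}

#' Convert corneal thickness to swelling
#'
#' Percentage swelling relative to a baseline corneal thickness:
#' `100 * (ct - baseline) / baseline`.
#'
#' @param ct Corneal thickness (micrometres), vectorised.
#' @param baseline Baseline thickness (micrometres), positive.
#' @return Swelling (%).
#' @export
#' @examples
#' thickness_to_swelling(605, 550)  # 10
thickness_to_swelling <- function(ct, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("`baseline` must be positive", call. = FALSE)
  100 * (ct - baseline) / baseline
}
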