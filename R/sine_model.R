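#' Parameters of the sigmoidal load-force curve
#'
#' The planned load-force profile during the loading phase is modelled as a
#' sigmoid: the double integral of a single period of a sine. The sine's
#' frequency and amplitude are fully determined by the cube weight `m` and
#' the loading duration `d`:
#' \deqn{f = 2\pi/d, \qquad G = 2\pi m / d^2,}
#' so that the curve rises from 0 at `onset` and saturates at exactly `m`
#' (the object's weight, in newtons) at `onset + d`, when the object lifts
#' off the surface.
#'
#' @param m Cube weight in newtons (mass_kg * 9.81), > 0.
#' @param d Loading-phase duration in seconds, > 0.
#' @param onset Curve onset time in seconds (grip-force onset / object
#'   contact); default 0.
#' @return An object of class `sine_lift_params` with fields `m`, `d`,
#'   `onset` and the derived `f` (rad/s) and `G` (N/s^2).
#' @seealso [lf_curve()], [model_curve()]
#' @export
sine_lift_params <- function(m, d, onset = 0) {
  stopifnot(is.numeric(m), length(m) == 1L, m > 0,
            is.numeric(d), length(d) == 1L, d > 0,
            is.numeric(onset), length(onset) == 1L)
  m <- unname(m); d <- unname(d); onset <- unname(onset)
  structure(list(m = m, d = d, onset = onset,
                 f = 2 * pi / d, G = 2 * pi * m / d^2),
            class = "sine_lift_params")
}

#' @export
print.sine_lift_params <- function(x, ...) {
  cat(sprintf("sigmoid lift curve: m = %.4g N, d = %.4g s, onset = %.4g s\n",
              x$m, x$d, x$onset))
  cat(sprintf("  derived f = %.4g rad/s, G = %.4g N/s^2\n", x$f, x$G))
  invisible(x)
}

#' Visual-delay specification for the delay models
#'
#' @param delay Visual delay in seconds (>= 0).
#' @param w_v Relative weight of vision; `w_h = 1 - w_v` is the haptic
#'   weight. Values outside \[0, 1\] are permitted (the fit may wander
#'   slightly outside), but must be finite.
#' @return An object of class `delay_spec` with fields `delay`, `w_v`, `w_h`.
#' @export
delay_spec <- function(delay, w_v) {
  stopifnot(is.numeric(delay), length(delay) == 1L, delay >= 0,
            is.numeric(w_v), length(w_v) == 1L, is.finite(w_v))
  structure(list(delay = delay, w_v = w_v, w_h = 1 - w_v),
            class = "delay_spec")
}

#' Evaluate the sigmoidal load-force curve
#'
#' Closed form of the double integral of `G sin(f (t - onset))`:
#' 0 before `onset`, `(m/d) * ((t - onset) - sin(f (t - onset)) / f)` during
#' the loading phase, and the plateau `m` after `onset + d`. Continuous and
#' non-decreasing; its derivative is the bell-shaped load-force rate with
#' peak `2 m / d` at the midpoint.
#'
#' @param p A [sine_lift_params()] object.
#' @param times Numeric vector of times (s).
#' @return Load-force values in newtons, same length as `times`.
#' @export
lf_curve <- function(p, times) {
  stopifnot(inherits(p, "sine_lift_params"), is.numeric(times))
  u <- times - p$onset
  out <- numeric(length(times))
  rising <- u > 0 & u < p$d
  out[rising] <- (p$m / p$d) * (u[rising] - sin(p$f * u[rising]) / p$f)
  out[u >= p$d] <- p$m
  out
}

#' Load-force curve under one of the three visual-delay models
#'
#' Transforms the baseline sigmoid under a visual delay according to the
#' chosen model:
#' \describe{
#'   \item{shift}{the whole curve's onset is translated by `w_v * delay`;
#'     duration and amplitude are unchanged.}
#'   \item{stretch}{the onset is unchanged but the duration becomes
#'     `d + w_v * delay`; the sine amplitude is recomputed from the new
#'     duration so the curve still saturates at `m`.}
#'   \item{sum}{a weighted superposition of a haptic-locked curve at `onset`
#'     (weight `w_h`) and a vision-locked copy at `onset + delay`
#'     (weight `w_v`).}
#' }
#' With `delay = 0` or `w_v = 0` all three reduce to the baseline curve, and
#' `sum` with `w_v = 1` equals `shift` with `w_v = 1`.
#'
#' @param kind One of `"shift"`, `"stretch"`, `"sum"`.
#' @param p Baseline [sine_lift_params()].
#' @param ds A [delay_spec()].
#' @param times Numeric vector of times (s).
#' @return Load-force values in newtons.
#' @export
model_curve <- function(kind = c("shift", "stretch", "sum"), p, ds, times) {
  kind <- match.arg(kind)
  stopifnot(inherits(p, "sine_lift_params"), inherits(ds, "delay_spec"))
  switch(kind,
    shift = lf_curve(sine_lift_params(p$m, p$d, p$onset + ds$w_v * ds$delay),
                     times),
    stretch = lf_curve(sine_lift_params(p$m, p$d + ds$w_v * ds$delay, p$onset),
                       times),
    sum = {
      haptic <- lf_curve(p, times)
      visual <- lf_curve(sine_lift_params(p$m, p$d, p$onset + ds$delay), times)
      ds$w_h * haptic + ds$w_v * visual
    })
}
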