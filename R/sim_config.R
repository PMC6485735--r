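GRAVITY <- 9.81 # m/s^2

#' Configuration of the synthetic lift-trial generator
#'
#' Bundles the apparatus constants and generative parameters used by
#' [synth_lift_trial()] and [synth_reach()]. Forces are generated directly
#' from the closed-form sigmoid model curves; the haptic device's spring
#' stiffness and damping constants are retained as documentation-only
#' configuration (`stiffness_n_per_mm`, `damping_kg_per_s`) and do not enter
#' the generation.
#'
#' @param sampling_rate Sampling rate, Hz.
#' @param cube_mass Cube mass in grams; its weight in newtons is
#'   `cube_mass / 1000 * 9.81`.
#' @param visual_delay Visual delay in ms (0, 100 or 200 in the designs).
#' @param true_duration_d Planned loading-phase duration `d`, seconds.
#' @param true_w_v Planted relative weight of vision in \[0, 1\].
#' @param generative_model Which delay model generates the trace:
#'   `"shift"`, `"stretch"` or `"sum"` (default).
#' @param grip_gain Newtons of grip force per newton of load force.
#' @param grip_baseline Preload grip level (N) reached during the squeeze
#'   ramp after contact.
#' @param post_liftoff_grip_increment_per_delay Extra grip force after
#'   lift-off, N per ms of visual delay.
#' @param preload_dip Magnitude (N) of the brief negative load-force dip
#'   between contact and load onset (pressing the object into the table).
#' @param noise_sd SD (N) of the measurement noise added to each force
#'   channel; the white noise is shaped by the same 15 Hz low-pass used in
#'   preprocessing, so it is smooth.
#' @param hold_duration Time (s) the plateau is held after lift-off.
#' @param preload_duration Duration (s) of the grip squeeze ramp at contact.
#' @param reach_amplitude Start-to-cube distance, mm.
#' @param reach_duration Reach time, s.
#' @param delay_curvature_gain Peak perpendicular path deviation per ms of
#'   delay, mm/ms.
#' @param delay_overshoot_gain Terminal overshoot of the contact position
#'   along the reach axis per ms of delay, mm/ms.
#' @param start_offset Offset (mm) of the hand's start position from the
#'   nominal start, used to synthesise not-at-start trials.
#' @param seed Optional integer seed applied on entry to the generator.
#' @return An object of class `lift_sim_config` (a validated list).
#' @export
lift_sim_config <- function(sampling_rate = 500,
                            cube_mass = 200,
                            visual_delay = 0,
                            true_duration_d = 0.4,
                            true_w_v = 0.36,
                            generative_model = c("sum", "shift", "stretch"),
                            grip_gain = 0.7,
                            grip_baseline = 0.5,
                            post_liftoff_grip_increment_per_delay = 0.003,
                            preload_dip = 0.2,
                            noise_sd = 0.01,
                            hold_duration = 1.0,
                            preload_duration = 0.1,
                            reach_amplitude = 200,
                            reach_duration = 0.8,
                            delay_curvature_gain = 0.05,
                            delay_overshoot_gain = 0.025,
                            start_offset = 0,
                            seed = NULL) {
  generative_model <- match.arg(generative_model)
  stopifnot(sampling_rate > 0, cube_mass > 0, true_duration_d > 0,
            true_w_v >= 0, true_w_v <= 1, noise_sd >= 0, visual_delay >= 0,
            grip_baseline > 0.1, preload_duration > 0, hold_duration > 0,
            reach_amplitude > 0, reach_duration > 0)
  structure(list(sampling_rate = sampling_rate, cube_mass = cube_mass,
                 visual_delay = visual_delay,
                 true_duration_d = true_duration_d, true_w_v = true_w_v,
                 generative_model = generative_model, grip_gain = grip_gain,
                 grip_baseline = grip_baseline,
                 post_liftoff_grip_increment_per_delay =
                   post_liftoff_grip_increment_per_delay,
                 preload_dip = preload_dip, noise_sd = noise_sd,
                 hold_duration = hold_duration,
                 preload_duration = preload_duration,
                 reach_amplitude = reach_amplitude,
                 reach_duration = reach_duration,
                 delay_curvature_gain = delay_curvature_gain,
                 delay_overshoot_gain = delay_overshoot_gain,
                 start_offset = start_offset, seed = seed,
                 stiffness_n_per_mm = 0.4, damping_kg_per_s = 2),
            class = "lift_sim_config")
}

#' Configuration of the simulated observer
#'
#' A synthetic stand-in for a participant judging heaviness. Felt heaviness
#' is the cube mass inflated by a delay-dependent fractional gain; magnitude
#' estimates follow a Stevens power law on a participant-specific scale, and
#' two-interval comparisons are decided by the larger noisy felt weight.
#'
#' @param delay_heaviness_gain Named numeric vector mapping delay (ms, as
#'   names) to the fractional heaviness increase, e.g. `c("200" = 0.18)`.
#'   Delays absent from the map have gain 0.
#' @param judgment_sd Internal comparison noise, grams.
#' @param stevens_exponent Exponent of the heaviness power law.
#' @param rating_scale Participant-specific multiplier on ratings (removed
#'   by z-scoring).
#' @param seed Optional integer seed.
#' @return An object of class `observer_config`.
#' @export
observer_config <- function(delay_heaviness_gain = c("0" = 0, "100" = 0.04,
                                                     "200" = 0.18),
                            judgment_sd = 10,
                            stevens_exponent = 1.45,
                            rating_scale = 1,
                            seed = NULL) {
  stopifnot(judgment_sd >= 0, rating_scale > 0, stevens_exponent > 0,
            is.numeric(delay_heaviness_gain),
            !is.null(names(delay_heaviness_gain)))
  structure(list(delay_heaviness_gain = delay_heaviness_gain,
                 judgment_sd = judgment_sd,
                 stevens_exponent = stevens_exponent,
                 rating_scale = rating_scale, seed = seed),
            class = "observer_config")
}

# delay (ms) -> fractional heaviness gain
observer_gain <- function(obs, delay) {
  g <- unname(obs$delay_heaviness_gain[as.character(delay)])
  g[is.na(g)] <- 0
  g
}
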