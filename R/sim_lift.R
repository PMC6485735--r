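#' Experiment-1 trial design
#'
#' Builds the randomized trial list for the magnitude-estimation experiment:
#' four cube masses (100, 200, 300, 400 g) crossed with visual delays of
#' 0, 100 and 200 ms, with 40 no-delay and 10 trials per delayed condition
#' per mass (240 trials in total, 160 without delay).
#'
#' @param seed Integer seed for the order randomization.
#' @param participant Participant label attached to every trial.
#' @return A data.frame of class `experiment_design` with columns
#'   `trial`, `participant`, `mass`, `delay`, `repetition`, plus attributes
#'   `seed` and `label`.
#' @export
make_design_exp1 <- function(seed = 1L, participant = "P01") {
  masses <- c(100, 200, 300, 400)
  grid <- do.call(rbind, lapply(masses, function(m) {
    data.frame(mass = m,
               delay = c(rep(0, 40), rep(100, 10), rep(200, 10)))
  }))
  grid$repetition <- stats::ave(grid$mass, grid$mass, grid$delay,
                                FUN = seq_along)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
  out <- data.frame(trial = seq_len(nrow(grid)),
                    participant = participant,
                    mass = grid$mass, delay = grid$delay,
                    repetition = grid$repetition,
                    row.names = NULL)
  attr(out, "seed") <- seed
  attr(out, "label") <- "exp1"
  class(out) <- c("experiment_design", "data.frame")
  out
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# smoothstep ramp: 0 -> 1 with zero slope at both ends
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# ground-truth event times implied by the generative model (continuous time)
truth_events_for <- function(cfg, t_contact, t_onset) {
  m <- cfg$cube_mass / 1000 * GRAVITY
  d <- cfg$true_duration_d
  delay_s <- cfg$visual_delay / 1000
  w_v <- cfg$true_w_v
  liftoff <- switch(cfg$generative_model,
    shift = t_onset + w_v * delay_s + d,
    stretch = t_onset + d + w_v * delay_s,
    sum = if (w_v > 0) t_onset + delay_s + d else t_onset + d)
  p <- sine_lift_params(m, d, t_onset)
  ds <- delay_spec(delay_s, w_v)
  curve <- function(t) model_curve(cfg$generative_model, p, ds, t)
  lf_onset <- if (curve(t_onset) >= 0.1) t_onset else
    stats::uniroot(function(t) curve(t) - 0.1,
                   lower = t_onset, upper = liftoff, tol = 1e-10)$root
  list(contact = t_contact, gf_onset = t_onset, lf_onset = lf_onset,
       liftoff = liftoff)
}

#' Generate one synthetic lift trial
#'
#' Produces a full trial: a reach phase with zero forces, a preload phase in
#' which the grip squeeze ramps up while the load force briefly dips
#' negative (the object is pressed into the table), a sigmoidal load-force
#' rise to the cube's weight generated by the configured delay model, and a
#' hold plateau. Grip force is an affine function of load force plus a
#' delay-proportional increment after lift-off. The load-curve onset is
#' defined as the instant the grip force crosses the 0.1 N detection
#' threshold during the squeeze ramp, so grip-force onset coincides exactly
#' with the model curve's onset, as the downstream fitting assumes.
#'
#' @param cfg A [lift_sim_config()].
#' @param trial_id,participant_id Labels stored in the record.
#' @return An object of class `trial_record`: a list with the
#'   [force_trace()] (`trace`), ground-truth event times (`truth_events`:
#'   contact, gf_onset, lf_onset, liftoff, in s) and generative parameters
#'   (`truth_params`: d, w_v, model, weight_n).
#' @export
synth_lift_trial <- function(cfg, trial_id = 1L, participant_id = "P01") {
  stopifnot(inherits(cfg, "lift_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$sampling_rate
  dt <- 1 / fs
  m <- cfg$cube_mass / 1000 * GRAVITY
  d <- cfg$true_duration_d
  delay_s <- cfg$visual_delay / 1000

  t_contact <- cfg$reach_duration
  # grip squeeze ramp: baseline * smoothstep; load onset where it crosses 0.1 N
  cross_u <- stats::uniroot(function(u) {
    cfg$grip_baseline * smoothstep(u) - 0.1
  }, lower = 0, upper = 1, tol = 1e-12)$root
  # snap the onset to the sample grid so the detected grip onset coincides
  # exactly with the model curve's onset (the fit assumes they match)
  t_onset <- max(round((t_contact + cross_u * cfg$preload_duration) * fs),
                 round(t_contact * fs) + 1) / fs
  preload_dur <- (t_onset - t_contact) / cross_u

  truth <- truth_events_for(cfg, t_contact, t_onset)
  loading <- truth$liftoff - truth$gf_onset
  if (cfg$hold_duration < loading)
    stop("hold_duration shorter than the generated loading phase")
  t_end <- truth$liftoff + cfg$hold_duration
  times <- seq(0, t_end, by = dt)

  p <- sine_lift_params(m, d, t_onset)
  ds <- delay_spec(delay_s, cfg$true_w_v)
  lf_model <- model_curve(cfg$generative_model, p, ds, times)

  # negative preload dip, confined between contact and load onset
  dip <- numeric(length(times))
  in_dip <- times >= t_contact & times <= t_onset
  if (cfg$preload_dip > 0 && t_onset > t_contact) {
    u <- (times[in_dip] - t_contact) / (t_onset - t_contact)
    dip[in_dip] <- -cfg$preload_dip * sin(pi * u)
  }
  lf <- lf_model + dip

  # grip: squeeze ramp + affine coupling to load + post-lift-off increment
  ramp <- cfg$grip_baseline *
    smoothstep((times - t_contact) / preload_dur)
  # guard the threshold sample against floating-point round-down
  i_on <- round(t_onset * fs) + 1L
  if (i_on <= length(times)) ramp[i_on] <- max(ramp[i_on], 0.1)
  inc <- cfg$post_liftoff_grip_increment_per_delay * cfg$visual_delay *
    smoothstep((times - truth$liftoff) / 0.3)
  gf <- ramp + cfg$grip_gain * lf_model + inc

  pos <- synth_reach(cfg, times = times)

  shaped_noise <- function(n) {
    if (cfg$noise_sd == 0) return(numeric(n))
    lowpass_filtfilt(stats::rnorm(n, 0, cfg$noise_sd), fs, 15)
  }
  n <- length(times)
  trace <- force_trace(
    time = times,
    thumb_vertical = lf / 2 + shaped_noise(n),
    index_vertical = lf / 2 + shaped_noise(n),
    thumb_normal = gf + shaped_noise(n),
    index_normal = gf + shaped_noise(n),
    thumb_pos = pos$thumb, index_pos = pos$index,
    mass = cfg$cube_mass, delay = cfg$visual_delay,
    participant = participant_id, trial = trial_id)

  structure(list(trial_id = trial_id, participant_id = participant_id,
                 mass = cfg$cube_mass, delay = cfg$visual_delay,
                 trace = trace, valid = TRUE, reason = "none",
                 truth_events = truth,
                 truth_params = list(d = d, w_v = cfg$true_w_v,
                                     model = cfg$generative_model,
                                     weight_n = m)),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("synthetic lift trial %s/%s: %g g, %g ms delay (%s model)\n",
              x$participant_id, x$trial_id, x$mass, x$delay,
              x$truth_params$model))
  cat(sprintf("  truth: contact %.3f s, gf onset %.3f s, lift-off %.3f s\n",
              x$truth_events$contact, x$truth_events$gf_onset,
              x$truth_events$liftoff))
  invisible(x)
}

#' Generate fingertip reach trajectories
#'
#' Minimum-jerk reach from the start positions to the cube's contact
#' positions along the y axis, with two delay-dependent perturbations: a
#' perpendicular (x) deviation with peak `delay_curvature_gain * delay` mm
#' at mid-reach, and a terminal overshoot that moves the contact position
#' `delay_overshoot_gain * delay` mm farther along the reach axis. With zero
#' gains or zero delay the path is a straight minimum-jerk reach whose peak
#' tangential speed is `1.875 * amplitude / duration`.
#'
#' @param cfg A [lift_sim_config()].
#' @param times Optional time vector (s); defaults to the reach phase only.
#' @return List with `thumb` and `index`: n x 3 matrices (x, y, z in mm).
#' @export
synth_reach <- function(cfg, times = NULL) {
  stopifnot(inherits(cfg, "lift_sim_config"))
  if (is.null(times))
    times <- seq(0, cfg$reach_duration, by = 1 / cfg$sampling_rate)
  u <- pmin(pmax(times / cfg$reach_duration, 0), 1)
  s <- u^3 * (10 - 15 * u + 6 * u^2)          # minimum-jerk position profile
  overshoot <- cfg$delay_overshoot_gain * cfg$visual_delay
  curve_amp <- cfg$delay_curvature_gain * cfg$visual_delay
  y <- cfg$start_offset + (cfg$reach_amplitude + overshoot -
                             cfg$start_offset) * s
  xdev <- curve_amp * sin(pi * u)
  aperture <- 25 # mm half-aperture between thumb and index
  mk <- function(sign) {
    cbind(x = sign * aperture + xdev, y = y, z = rep(0, length(y)))
  }
  list(thumb = mk(-1), index = mk(1))
}

#' Simulate a magnitude-estimation heaviness rating
#'
#' @param obs An [observer_config()].
#' @param mass Cube mass, grams (> 0).
#' @param delay Visual delay, ms.
#' @return A strictly positive rating:
#'   `rating_scale * (mass * (1 + gain(delay)))^stevens_exponent` times
#'   multiplicative log-normal noise with coefficient of variation
#'   `judgment_sd / mass`.
#' @export
simulate_rating <- function(obs, mass, delay = 0) {
  stopifnot(inherits(obs, "observer_config"), mass > 0)
  if (!is.null(obs$seed)) set.seed(obs$seed)
  felt <- mass * (1 + observer_gain(obs, delay))
  noise <- if (obs$judgment_sd == 0) 1 else
    exp(stats::rnorm(1, 0, obs$judgment_sd / mass))
  obs$rating_scale * felt^obs$stevens_exponent * noise
}

#' Simulate a two-interval heaviness comparison
#'
#' Each cube's felt weight is its mass inflated by the delay gain plus
#' zero-mean Gaussian noise (`judgment_sd` grams); the interval with the
#' larger felt weight is reported, ties broken by a fresh coin flip.
#'
#' @param obs An [observer_config()].
#' @param first,second Length-2 numeric vectors `c(mass_g, delay_ms)`.
#' @return `"first"` or `"second"`.
#' @export
simulate_choice <- function(obs, first, second) {
  stopifnot(inherits(obs, "observer_config"),
            length(first) == 2L, length(second) == 2L,
            first[1] > 0, second[1] > 0)
  if (!is.null(obs$seed)) set.seed(obs$seed)
  felt <- function(md) {
    md[1] * (1 + observer_gain(obs, md[2])) +
      if (obs$judgment_sd > 0) stats::rnorm(1, 0, obs$judgment_sd) else 0
  }
  f1 <- felt(first); f2 <- felt(second)
  if (f1 > f2) "first"
  else if (f2 > f1) "second"
  else if (stats::runif(1) < 0.5) "first" else "second"
}
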