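# Shared fixtures, built in code.

# noiseless synthetic trial with convenient defaults
noiseless_trial <- function(mass = 200, delay = 0, d = 0.4, w_v = 0.36,
                            model = "sum", ...) {
  cfg <- lift_sim_config(cube_mass = mass, visual_delay = delay,
                         true_duration_d = d, true_w_v = w_v,
                         generative_model = model, noise_sd = 0, ...)
  synth_lift_trial(cfg)
}

# trial -> grip/load series without the (noise-targeted) filtering stage
gls_of <- function(rec, filter = FALSE) {
  grip_load(preprocess(rec$trace, filter = filter))
}

# hand-built grip/load series from explicit lf/gf vectors
make_gls <- function(lf, gf = lf, rate = 500) {
  n <- length(lf)
  tr <- force_trace(time = (seq_len(n) - 1) / rate,
                    thumb_normal = gf, index_normal = gf,
                    thumb_vertical = lf / 2, index_vertical = lf / 2)
  grip_load(tr)
}

# average no-delay and delayed curves for one simulated participant
participant_averages <- function(n0 = 20, n1 = 10, mass = 200, delay = 200,
                                 d_mean = 0.4, d_jitter = 0.015,
                                 w_v = 0.36, noise_sd = 0.05,
                                 model = "sum") {
  weight <- mass / 1000 * 9.81
  gen <- function(dly, n) {
    recs <- lapply(seq_len(n), function(i) {
      d_i <- max(0.2, d_mean + stats::rnorm(1, 0, d_jitter))
      cfg <- lift_sim_config(cube_mass = mass, visual_delay = dly,
                             true_duration_d = d_i, true_w_v = w_v,
                             generative_model = model, noise_sd = noise_sd)
      synth_lift_trial(cfg)
    })
    gls <- lapply(recs, function(r)
      grip_load(preprocess(r$trace, filter = noise_sd > 0)))
    evs <- lapply(gls, detect_events, cube_weight = weight)
    ok <- vapply(evs, function(e) isTRUE(e$ok), logical(1))
    average_curves(gls[ok], evs[ok], cube_weight = weight)
  }
  list(base = gen(0, n0), delayed = gen(delay, n1), weight = weight)
}
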