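test_that("preprocessing passes DC, kills 50 Hz, interpolates gaps", {
  t <- seq(0, 2, by = 1 / 500)
  n <- length(t)
  mk <- function(x) force_trace(t, x, x, x, x)
  # DC
  out <- preprocess(mk(rep(1, n)))
  expect_lt(max(abs(out$thumb_normal - 1)), 1e-9)
  # 50 Hz unit sinusoid: squared 2nd-order Butterworth at 50/15 is tiny
  out <- preprocess(mk(sin(2 * pi * 50 * t)))
  expect_lt(max(abs(out$thumb_normal[100:(n - 100)])), 0.05)
  # single missing interior sample between 1.0 and 2.0
  x <- rep(1, n); x[500] <- NA; x[501:n] <- 2
  x[499] <- 1; x[501] <- 2
  out <- preprocess(mk(x), filter = FALSE)
  expect_equal(out$thumb_normal[500], 1.5)
})

test_that("excessive missing data raises a technical rejection", {
  t <- seq(0, 1.5, by = 1 / 500)
  x <- rep(1, length(t))
  x[seq_len(round(0.2 * length(t)))] <- NA
  tr <- force_trace(t, x, x, x, x)
  expect_error(preprocess(tr), class = "vhlift_technical")
})

test_that("filtering is zero-phase on a symmetric pulse", {
  t <- seq(0, 2, by = 1 / 500)
  pulse <- exp(-((t - 1) / 0.05)^2)
  y <- lowpass_filtfilt(pulse, 500)
  expect_equal(t[which.max(y)], t[which.max(pulse)], tolerance = 1 / 500)
})

test_that("grip/load combination sums verticals and averages normals", {
  n <- 500
  tt <- (seq_len(n) - 1) / 500
  tr <- force_trace(tt,
                    thumb_normal = rep(2, n), index_normal = rep(4, n),
                    thumb_vertical = rep(1, n), index_vertical = rep(1, n))
  gls <- grip_load(tr)
  expect_true(all(gls$lf == 2))
  expect_true(all(gls$gf == 3))
  # ramp of slope 3 N/s differentiates to 3 away from the endpoints
  gls2 <- make_gls(3 * tt)
  expect_lt(max(abs(gls2$lfr[2:(n - 1)] - 3)), 1e-9)
})

test_that("events are detected at the stated threshold crossings", {
  tt <- (0:1500) / 500
  gls <- make_gls(tt)                    # lf(t) = t
  ev <- detect_events(gls, 1.962)
  expect_true(ev$ok)
  expect_equal(ev$lf_onset, 0.1, tolerance = 1 / 500)
  expect_equal(ev$liftoff, 1.962, tolerance = 1 / 500)
  # all-zero load force: no lift
  ev0 <- detect_events(make_gls(rep(0, 600)), 1.962)
  expect_false(ev0$ok)
  expect_identical(ev0$reason, "no_lift")
  # reaches onset but never the weight
  ev1 <- detect_events(make_gls(pmin(tt, 0.5)), 1.962)
  expect_false(ev1$ok)
  expect_identical(ev1$reason, "no_liftoff")
})

test_that("noiseless trial events match ground truth within one sample", {
  set.seed(3)
  cases <- list(list(mass = 200, delay = 0, d = 0.4, w_v = 0.36),
                list(mass = 400, delay = 200, d = 0.5, w_v = 0.5),
                list(mass = 100, delay = 100, d = 0.35, w_v = 0.25,
                     model = "shift"))
  for (cs in cases) {
    rec <- do.call(noiseless_trial, cs)
    gls <- gls_of(rec)
    ev <- detect_events(gls, rec$truth_params$weight_n)
    expect_true(ev$ok)
    expect_lt(abs(ev$gf_onset - rec$truth_events$gf_onset), 2e-3 + 1e-12)
    expect_lt(abs(ev$lf_onset - rec$truth_events$lf_onset), 2e-3 + 1e-12)
    expect_lt(abs(ev$liftoff - rec$truth_events$liftoff), 2e-3 + 1e-12)
  }
})

test_that("force parameters follow their definitions", {
  rec <- noiseless_trial(mass = 200, d = 0.4)
  gls <- gls_of(rec)
  ev <- detect_events(gls, 1.962)
  fp <- force_parameters(gls, ev)
  expect_equal(fp$lfr_max, 9.81, tolerance = 1e-3)   # 2m/d
  expect_equal(fp$lpd, ev$liftoff - ev$lf_onset)
  # gf ramp 5t with lift-off at 0.6 s -> GFatLO = 3.0 N
  tt <- (0:600) / 500
  gls2 <- make_gls(lf = 4 * tt, gf = 5 * tt)
  ev2 <- detect_events(gls2, 4 * 0.6)
  fp2 <- force_parameters(gls2, ev2)
  expect_equal(fp2$gf_at_lo, 3.0, tolerance = 1e-6)
  # events at 0.2 s and 0.7 s -> lpd = 0.5 s exactly
  ev3 <- structure(list(lf_onset = 0.2, gf_onset = 0.2, liftoff = 0.7,
                        ok = TRUE, reason = "none"), class = "lift_events")
  expect_equal(force_parameters(gls2, ev3)$lpd, 0.5)
})

test_that("binned areas are exact on simple signals and additive", {
  n <- 800
  tt <- (seq_len(n) - 1) / 500
  gls <- make_gls(rep(1, n))
  ev <- structure(list(lf_onset = 0, gf_onset = 0, liftoff = 0.5, ok = TRUE,
                       reason = "none"), class = "lift_events")
  ba <- binned_areas(gls, ev)
  expect_equal(nrow(ba), 10L)
  expect_equal(ba$lf, rep(0.1, 10))
  expect_equal(ba$gf, rep(0.1, 10))
  # additivity: bins sum to the full-window trapezoid
  gls2 <- make_gls(sin(2 * pi * 1.3 * tt) + tt)
  ba2 <- binned_areas(gls2, ev)
  full <- sum((gls2$lf[2:501] + gls2$lf[1:500]) / 2) / 500
  expect_equal(sum(ba2$lf), full, tolerance = 1e-9)
  # ramp from onset: first bin is the integral of t over [0, 0.1]
  ba3 <- binned_areas(make_gls(tt), ev)
  expect_equal(ba3$lf[1], 0.005, tolerance = 1e-9)
  # pre-onset trimming does not change the areas
  ev2 <- structure(list(lf_onset = 0.2, gf_onset = 0.2, liftoff = 0.5,
                        ok = TRUE, reason = "none"), class = "lift_events")
  gls3 <- make_gls(c(rep(0, 100), rep(1, n)))
  ba4 <- binned_areas(gls3, ev2)
  expect_equal(ba4$lf, rep(0.1, 10))
  expect_error(binned_areas(make_gls(rep(1, 300)), ev), "1 s")
})

test_that("kinematics recovers reach geometry", {
  rec <- noiseless_trial(delay = 0)
  gls <- gls_of(rec)
  ev <- detect_events(gls, rec$truth_params$weight_n)
  km <- kinematics(rec$trace, ev)
  expect_true(km$ok)
  # straight reach: path equals start-contact distance, curvature ~ 0
  expect_equal(km$curvature, 0, tolerance = 1e-9)
  i_start <- which.min(abs(rec$trace$time - km$movement_start))
  i_contact <- which.min(abs(rec$trace$time - ev$gf_onset))
  straight <- sqrt(sum((rec$trace$index_pos[i_start, ] -
                          rec$trace$index_pos[i_contact, ])^2))
  expect_equal(km$path_length, straight, tolerance = 1e-6)
  expect_equal(km$peak_velocity, 1.875 * 200 / 0.8, tolerance = 1)
  # delay adds curvature
  rec2 <- noiseless_trial(delay = 200)
  ev2 <- detect_events(gls_of(rec2), rec2$truth_params$weight_n)
  km2 <- kinematics(rec2$trace, ev2)
  expect_gt(km2$curvature, 5)
})

test_that("screening applies drop, multiple-lift and start-position rules", {
  rec <- noiseless_trial()
  gls <- gls_of(rec)
  w <- rec$truth_params$weight_n
  ev <- detect_events(gls, w)
  clean <- list(gls = gls, events = ev, weight = w)
  # mid-hold dip to 0.3 x weight -> drop
  gls_drop <- gls
  i <- which(gls$time > ev$liftoff + 0.3)[1:40]
  gls_drop$lf[i] <- 0.3 * w
  dropped <- list(gls = gls_drop, events = ev, weight = w)
  # dip below weight-0.1 then back up -> multiple lift
  gls_two <- gls
  gls_two$lf[i] <- w - 0.15
  double <- list(gls = gls_two, events = ev, weight = w)
  # away from start: kinematics-only exclusion
  offstart <- list(gls = gls, events = ev, weight = w, start_offset = 20)
  rep <- screen_trials(list(clean, dropped, double, offstart))
  expect_equal(rep$reason, c("none", "drop", "multiple_lift", "not_at_start"))
  expect_equal(rep$keep_forces, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(rep$keep_kinematics, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("curve averaging is idempotent, aligned, and brackets lift-off", {
  rec <- noiseless_trial(d = 0.4)
  gls <- gls_of(rec)
  w <- rec$truth_params$weight_n
  ev <- detect_events(gls, w)
  av <- average_curves(list(gls, gls, gls), list(ev, ev, ev), w)
  i0 <- which.min(abs(gls$time - ev$gf_onset))
  expect_equal(av$lf, gls$lf[i0:(i0 + length(av$lf) - 1)])
  expect_equal(av$time[1], 0)
  # averaging d = 0.38 and 0.42 puts the mean lift-off between the two
  r1 <- noiseless_trial(d = 0.38); r2 <- noiseless_trial(d = 0.42)
  g1 <- gls_of(r1); g2 <- gls_of(r2)
  e1 <- detect_events(g1, w); e2 <- detect_events(g2, w)
  av2 <- average_curves(list(g1, g2), list(e1, e2), w)
  expect_gt(av2$liftoff, 0.38)
  expect_lt(av2$liftoff, 0.42 + 2 / 500)
  # different pre-onset padding: onset stays at time zero
  expect_equal(which(av2$lf >= 0.1)[1] > 1, TRUE)
})
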