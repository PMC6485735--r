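test_that("experiment-1 design has the published counts", {
  des <- make_design_exp1(seed = 1)
  expect_equal(nrow(des), 240L)
  expect_equal(sum(des$delay == 0), 160L)
  expect_equal(sum(des$delay > 0), 80L)
  counts <- table(des$mass, des$delay)
  expect_true(all(counts[, "0"] == 40))
  expect_true(all(counts[, "100"] == 10))
  expect_true(all(counts[, "200"] == 10))
})

test_that("design order is a seeded permutation of a fixed multiset", {
  a <- make_design_exp1(seed = 1)
  b <- make_design_exp1(seed = 1)
  c <- make_design_exp1(seed = 2)
  expect_identical(a$mass, b$mass)
  expect_identical(a$delay, b$delay)
  expect_false(identical(a$mass, c$mass) && identical(a$delay, c$delay))
  key <- function(d) sort(paste(d$mass, d$delay))
  expect_identical(key(a), key(c))
})

test_that("identical seeds give bit-identical trials", {
  cfg <- lift_sim_config(noise_sd = 0.02, seed = 99L)
  r1 <- synth_lift_trial(cfg)
  r2 <- synth_lift_trial(cfg)
  expect_identical(r1$trace$thumb_vertical, r2$trace$thumb_vertical)
  expect_identical(r1$trace$index_normal, r2$trace$index_normal)
})

test_that("noiseless plateau equals the cube weight", {
  for (mass in c(100, 200, 400)) {
    rec <- noiseless_trial(mass = mass)
    gls <- gls_of(rec)
    w <- mass / 1000 * 9.81
    hold <- gls$time > rec$truth_events$liftoff + 1e-9
    expect_lt(max(abs(gls$lf[hold] - w)), 1e-9)
  }
})

test_that("peak load-force rate matches 2m/d on a noiseless trial", {
  # 200 g cube (weight 1.962 N), d = 0.4 s: peak rate 2m/d = 9.81 N/s
  # (within the loading window; the preload dip is steeper but lies before
  # load-force onset and outside the analysis window)
  rec <- noiseless_trial(mass = 200, d = 0.4)
  gls <- gls_of(rec)
  ev <- detect_events(gls, rec$truth_params$weight_n)
  expect_equal(force_parameters(gls, ev)$lfr_max, 9.81, tolerance = 1e-3)
})

test_that("zero visual weighting makes delay trials identical to no-delay", {
  r0 <- noiseless_trial(delay = 0, w_v = 0)
  r2 <- noiseless_trial(delay = 200, w_v = 0)
  n <- min(length(r0$trace$time), length(r2$trace$time))
  expect_equal(r0$trace$thumb_vertical[1:n], r2$trace$thumb_vertical[1:n])
})

test_that("hold shorter than the loading phase is rejected", {
  expect_error(noiseless_trial(d = 1.2, hold_duration = 0.5),
               "hold_duration")
})

test_that("minimum-jerk reach peak speed is 1.875 L/T, straight when unperturbed", {
  cfg <- lift_sim_config(visual_delay = 0, reach_amplitude = 200,
                         reach_duration = 0.8)
  pos <- synth_reach(cfg)
  v <- sqrt(rowSums((diff(pos$index) * 500)^2))
  expect_equal(max(v), 1.875 * 200 / 0.8, tolerance = 1e-3)
  # deviation from the straight start-contact line is zero
  seg <- pos$index
  a <- seg[1, ]; b <- seg[nrow(seg), ]
  ab <- (b - a) / sqrt(sum((b - a)^2))
  rel <- sweep(seg, 2, a)
  perp <- rel - (rel %*% ab) %*% t(ab)
  expect_lt(max(sqrt(rowSums(perp^2))), 1e-9)
})

test_that("visual delay lengthens the reach path", {
  path_len <- function(delay) {
    cfg <- lift_sim_config(visual_delay = delay)
    p <- synth_reach(cfg)$index
    sum(sqrt(rowSums(diff(p)^2)))
  }
  expect_gt(path_len(200), path_len(0))
})

test_that("magnitude estimation follows the planted power law", {
  obs <- observer_config(judgment_sd = 0, stevens_exponent = 1,
                         rating_scale = 1,
                         delay_heaviness_gain = c("200" = 0.18))
  expect_equal(simulate_rating(obs, 200, 200), 236)
  # monotone in mass
  obs2 <- observer_config(judgment_sd = 0, delay_heaviness_gain = c("0" = 0))
  r <- vapply(c(100, 200, 300, 400), simulate_rating, numeric(1), obs = obs2)
  expect_true(all(diff(r) > 0))
})

test_that("z-scored ratings do not depend on the rating scale", {
  masses <- rep(c(100, 200, 300, 400), each = 5)
  mk <- function(scale) {
    obs <- observer_config(judgment_sd = 5, stevens_exponent = 1.45,
                           rating_scale = scale,
                           delay_heaviness_gain = c("0" = 0))
    set.seed(7)
    data.frame(participant = "P", mass = masses, delay = 0,
               rating = vapply(masses, simulate_rating, numeric(1),
                               obs = obs))
  }
  z1 <- zscore_ratings(mk(1))
  z9 <- zscore_ratings(mk(9.3))
  expect_equal(z1$mean_z, z9$mean_z, tolerance = 1e-12)
})

test_that("two-interval choice is decided by felt weight", {
  obs <- observer_config(judgment_sd = 0,
                         delay_heaviness_gain = c("200" = 0.18))
  expect_identical(simulate_choice(obs, c(290, 0), c(200, 0)), "first")
  expect_identical(simulate_choice(obs, c(200, 0), c(290, 0)), "second")
  # delayed 200 g vs non-delayed 236 g feel identical: choices split evenly
  obs10 <- observer_config(judgment_sd = 10,
                           delay_heaviness_gain = c("200" = 0.18))
  set.seed(11)
  picks <- replicate(10000,
                     simulate_choice(obs10, c(200, 200), c(236, 0)))
  expect_lt(abs(mean(picks == "first") - 0.5), 0.02)
})
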