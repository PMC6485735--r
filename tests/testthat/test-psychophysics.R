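test_that("z-scoring centres, scales, and preserves order", {
  ratings <- data.frame(participant = "P1",
                        mass = rep(c(100, 200, 300, 400), each = 4),
                        delay = 0,
                        rating = rep(c(8, 10, 12, 14), each = 4) +
                          rep(c(-1, 0, 0, 1), 4))
  z <- zscore_ratings(ratings)
  # a rating at mean + 1 sd maps to z = 1
  g <- ratings$rating
  expect_equal(((mean(g) + sd(g)) - mean(g)) / sd(g), 1)
  all_z <- (g - mean(g)) / sd(g)
  expect_lt(abs(mean(all_z)), 1e-9)
  expect_true(all(diff(z$mean_z[order(z$mass)]) > 0))
  expect_error(zscore_ratings(data.frame(participant = "Q", mass = 1,
                                         delay = 0,
                                         rating = rep(3, 5))),
               "variance")
})

test_that("staircase stepping follows one-up/one-down with saturation", {
  s <- staircase_session(delay_placement = "test")
  # chain 1 starts at 110: 'lighter' steps up
  s1 <- staircase_next(s, "test_lighter", chain = 1)
  expect_equal(s1$chain_mass[1], 125)
  # chain 2 starts at 290: 'heavier' steps down
  s2 <- staircase_next(s, "test_heavier", chain = 2)
  expect_equal(s2$chain_mass[2], 275)
  # saturation at the top of the grid
  s3 <- staircase_next(s, "test_lighter", chain = 2)
  expect_equal(s3$chain_mass[2], 290)
  # masses never leave the 13-level grid
  set.seed(5)
  s4 <- staircase_session(delay_placement = "test")
  for (k in 1:15)
    s4 <- staircase_next(s4, sample(c("test_heavier", "test_lighter"), 1))
  expect_true(all(s4$history$test_mass %in% seq(110, 290, 15)))
  expect_error(staircase_next(s4, "test_heavier"), "budget")
})

test_that("a full session runs 15 comparisons and is reproducible", {
  obs <- observer_config(judgment_sd = 10, seed = 21L)
  s <- run_session(obs, staircase_session(delay_placement = "standard",
                                          delay_level = 200))
  expect_equal(nrow(s$history), 15L)
  pd <- psychometric_data(s)
  expect_equal(sum(pd$n_presented), 15L)   # 30 lifts
  s2 <- run_session(obs, staircase_session(delay_placement = "standard",
                                           delay_level = 200))
  expect_identical(s$history, s2$history)
  # chains alternate strictly
  expect_true(all(abs(diff(s$history$chain)) == 1))
})

test_that("a deterministic observer converges to within one step of its PSE", {
  # felt PSE of the delayed 200-g standard is 236 g
  obs <- observer_config(judgment_sd = 0,
                         delay_heaviness_gain = c("200" = 0.18), seed = 3L)
  s <- run_session(obs, staircase_session(delay_placement = "standard",
                                          delay_level = 200))
  expect_lt(abs(staircase_pse(s) - 236), 15)
  expect_true(all(abs(s$chain_mass - 236) <= 15 + 1e-9))
  # planted PSE at the standard itself
  obs0 <- observer_config(judgment_sd = 0,
                          delay_heaviness_gain = c("0" = 0), seed = 4L)
  s0 <- run_session(obs0, staircase_session(delay_placement = "test",
                                            delay_level = 0))
  expect_lt(abs(staircase_pse(s0) - 200), 15 + 1e-9)
})

test_that("psychometric fit recovers planted parameters and scales weights", {
  set.seed(31)
  masses <- seq(110, 290, 15)
  p <- pnorm((masses - 236) / 25)
  d <- data.frame(mass = masses, n_presented = 200,
                  n_test_heavier = rbinom(length(masses), 200, p))
  fit <- fit_psychometric(d)
  expect_lt(abs(fit$mu - 236), 2)
  expect_lt(abs(fit$sigma - 25), 3)
  # halfway point: model passes 50% at mu
  expect_equal(100 * pnorm((fit$mu - fit$mu) / fit$sigma), 50)
  # doubling all counts leaves the fit unchanged
  d2 <- d; d2$n_presented <- d$n_presented * 2L
  d2$n_test_heavier <- d$n_test_heavier * 2L
  fit2 <- fit_psychometric(d2)
  expect_equal(fit2$mu, fit$mu, tolerance = 1e-6)
  expect_equal(fit2$sigma, fit$sigma, tolerance = 1e-6)
  # zero-count levels are ignored
  d3 <- rbind(d, data.frame(mass = 305, n_presented = 0, n_test_heavier = 0))
  expect_equal(fit_psychometric(d3)$mu, fit$mu, tolerance = 1e-9)
  # one-sided data are refused
  bad <- data.frame(mass = masses, n_presented = 5, n_test_heavier = 0)
  expect_error(fit_psychometric(bad), class = "vhlift_degenerate_fit")
})

test_that("total bias combines, signs, and clamps session biases", {
  mk <- function(mu) structure(list(mu = mu, sigma = 20, residual = 0,
                                    weights = 1, n_points = 13,
                                    converged = TRUE),
                               class = "psychometric_fit")
  b <- total_bias(mk(236), mk(164))
  expect_equal(b$total_bias, 18)
  expect_false(b$clamped)
  expect_equal(total_bias(mk(200), mk(200))$total_bias, 0)
  # out-of-range session bias is clamped to 45%
  b2 <- total_bias(mk(320), mk(200))
  expect_true(b2$clamped)
  expect_equal(b2$bias_standard_delay, 45)
  expect_equal(b2$total_bias, 22.5)
  # positive bias means the delayed cube feels heavier in both placements
  expect_gt(total_bias(mk(236), mk(200))$total_bias, 0)
  expect_gt(total_bias(mk(200), mk(170))$total_bias, 0)
})
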