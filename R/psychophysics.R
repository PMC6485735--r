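#' Z-score magnitude-estimation ratings
#'
#' Converts each participant's ratings to z-scores over all of that
#' participant's trials (removing the self-chosen rating scale), then
#' averages within each participant x mass x delay cell.
#'
#' @param ratings data.frame with columns `participant`, `mass`, `delay`,
#'   `rating` (ratings > 0).
#' @return data.frame with columns `participant`, `mass`, `delay`,
#'   `mean_z`, `n`.
#' @export
zscore_ratings <- function(ratings) {
  stopifnot(is.data.frame(ratings),
            all(c("participant", "mass", "delay", "rating")
                %in% names(ratings)),
            all(ratings$rating > 0))
  parts <- split(ratings, ratings$participant)
  out <- lapply(parts, function(g) {
    if (length(unique(g$rating)) < 2L)
      stop(sprintf("participant %s has zero rating variance",
                   g$participant[1L]))
    g$z <- (g$rating - mean(g$rating)) / stats::sd(g$rating)
    cells <- split(g, list(g$mass, g$delay), drop = TRUE)
    do.call(rbind, lapply(cells, function(cc) {
      data.frame(participant = cc$participant[1L], mass = cc$mass[1L],
                 delay = cc$delay[1L], mean_z = mean(cc$z), n = nrow(cc),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$participant, out$delay, out$mass), , drop = FALSE]
}

#' Create an adaptive staircase session
#'
#' Two interleaved one-up/one-down chains compare a 200-g standard against
#' a variable test mass on a 13-level grid (110 to 290 g in 15-g steps),
#' chains starting at the two extremes. The session terminates after 15
#' comparisons (30 lifts). Either the standard or the test cube carries the
#' visual delay, per `delay_placement`.
#'
#' @param delay_placement `"standard"` or `"test"`: which cube is lifted
#'   with the visual delay.
#' @param delay_level Visual delay, ms.
#' @param standard_mass Standard mass, g.
#' @param starts Starting test masses of the two chains, g.
#' @param step Staircase step, g.
#' @param bounds Test-mass range, g; chains saturate at the bounds.
#' @param budget Total number of comparisons across both chains.
#' @return An object of class `staircase_session`.
#' @export
staircase_session <- function(delay_placement = c("standard", "test"),
                              delay_level = 200,
                              standard_mass = 200,
                              starts = c(110, 290), step = 15,
                              bounds = c(110, 290), budget = 15L) {
  delay_placement <- match.arg(delay_placement)
  stopifnot(length(starts) == 2L, all(starts >= bounds[1]),
            all(starts <= bounds[2]), step > 0, budget >= 1L)
  structure(list(delay_placement = delay_placement,
                 delay_level = delay_level,
                 standard_mass = standard_mass,
                 chain_mass = starts, step = step, bounds = bounds,
                 budget = as.integer(budget),
                 history = data.frame(comparison = integer(), chain = integer(),
                                      test_mass = numeric(),
                                      test_first = logical(),
                                      response = character(),
                                      stringsAsFactors = FALSE)),
            class = "staircase_session")
}

#' Advance a staircase chain
#'
#' Applies the one-up/one-down rule to one chain: the test mass increases
#' one step when the test was perceived lighter and decreases one step when
#' perceived heavier, saturating at the grid bounds.
#'
#' @param s A [staircase_session()].
#' @param response `"test_heavier"` or `"test_lighter"`.
#' @param chain Chain index (1 or 2); defaults to the chain due next under
#'   strict alternation.
#' @return The updated session (the response is appended to the history and
#'   the chain's test mass moved).
#' @export
staircase_next <- function(s, response = c("test_heavier", "test_lighter"),
                           chain = NULL) {
  response <- match.arg(response)
  stopifnot(inherits(s, "staircase_session"))
  done <- nrow(s$history)
  if (done >= s$budget) stop("staircase budget exhausted")
  if (is.null(chain)) chain <- done %% 2L + 1L
  cur <- s$chain_mass[chain]
  nxt <- if (response == "test_lighter") cur + s$step else cur - s$step
  nxt <- min(max(nxt, s$bounds[1]), s$bounds[2])
  s$history <- rbind(s$history,
                     data.frame(comparison = done + 1L, chain = chain,
                                test_mass = cur, test_first = NA,
                                response = response,
                                stringsAsFactors = FALSE))
  s$chain_mass[chain] <- nxt
  s
}

#' Run a full staircase session with a simulated observer
#'
#' Runs the session's full comparison budget, strictly alternating the two
#' chains (starting chain randomized), randomizing the presentation order of
#' standard and test on every comparison, and obtaining each response from
#' [simulate_choice()] with the delay applied to the cube given by the
#' session's `delay_placement`.
#'
#' @param obs An [observer_config()].
#' @param s A fresh [staircase_session()].
#' @return The completed session; its `history` holds one row per
#'   comparison and [psychometric_data()] can aggregate it.
#' @export
run_session <- function(obs, s) {
  stopifnot(inherits(obs, "observer_config"),
            inherits(s, "staircase_session"), nrow(s$history) == 0L)
  if (!is.null(obs$seed)) set.seed(obs$seed)
  first_chain <- sample(1:2, 1L)
  d_std <- if (s$delay_placement == "standard") s$delay_level else 0
  d_tst <- if (s$delay_placement == "test") s$delay_level else 0
  for (k in seq_len(s$budget)) {
    chain <- (k - 1L + first_chain - 1L) %% 2L + 1L
    test_mass <- s$chain_mass[chain]
    test_first <- stats::runif(1) < 0.5
    std <- c(s$standard_mass, d_std)
    tst <- c(test_mass, d_tst)
    ans <- if (test_first) simulate_choice(obs, tst, std)
           else simulate_choice(obs, std, tst)
    test_heavier <- (test_first && ans == "first") ||
      (!test_first && ans == "second")
    s <- staircase_next(s, if (test_heavier) "test_heavier"
                           else "test_lighter", chain = chain)
    s$history$test_first[k] <- test_first
  }
  s
}

#' Aggregate staircase history into psychometric data
#'
#' @param s A completed [staircase_session()] (or any data.frame with
#'   `test_mass` and `response` columns).
#' @return data.frame of class `psychometric_data` with one row per visited
#'   test mass: `mass`, `n_presented`, `n_test_heavier`, `pct_heavier`.
#' @export
psychometric_data <- function(s) {
  h <- if (inherits(s, "staircase_session")) s$history else s
  stopifnot(all(c("test_mass", "response") %in% names(h)))
  masses <- sort(unique(h$test_mass))
  out <- do.call(rbind, lapply(masses, function(m) {
    g <- h[h$test_mass == m, ]
    data.frame(mass = m, n_presented = nrow(g),
               n_test_heavier = sum(g$response == "test_heavier"))
  }))
  out$pct_heavier <- 100 * out$n_test_heavier / out$n_presented
  class(out) <- c("psychometric_data", "data.frame")
  out
}

#' Staircase-level PSE estimate
#'
#' The mean of the test masses at response reversals (falling back to the
#' mean of the last two visited masses per chain when a chain has no
#' reversal). Robust for deterministic observers, whose psychometric data
#' are degenerate step functions.
#'
#' @param s A completed [staircase_session()].
#' @return PSE estimate in grams.
#' @export
staircase_pse <- function(s) {
  stopifnot(inherits(s, "staircase_session"))
  h <- s$history
  revs <- unlist(lapply(split(h, h$chain), function(g) {
    if (nrow(g) < 2L) return(numeric())
    flips <- which(g$response[-1L] != g$response[-nrow(g)]) + 1L
    g$test_mass[flips]
  }))
  if (length(revs)) mean(revs)
  else mean(unlist(lapply(split(h, h$chain), function(g)
    utils::tail(g$test_mass, 2L))))
}

#' Fit the cumulative-Gaussian psychometric curve
#'
#' Weighted least-squares fit of
#' \deqn{P(x) = 50 + 50\,\mathrm{erf}\!\big((x-\mu)/(\sqrt2\,\sigma)\big)}
#' to the per-mass percentages of "test heavier" answers, each point
#' weighted by its presentation count. Masses never presented are omitted.
#'
#' @param d A [psychometric_data()] data.frame.
#' @param sigma_bounds Bounds on sigma, g.
#' @return An object of class `psychometric_fit` with `mu`, `sigma`,
#'   `residual` (weighted RMS of percentage residuals), `weights`, `n_points`,
#'   `converged`.
#' @export
fit_psychometric <- function(d, sigma_bounds = c(0.5, 500)) {
  stopifnot(inherits(d, "data.frame"),
            all(c("mass", "n_presented", "n_test_heavier") %in% names(d)))
  d <- d[d$n_presented > 0, , drop = FALSE]
  if (nrow(d) < 2L) stop("need at least 2 test masses with presentations")
  pct <- 100 * d$n_test_heavier / d$n_presented
  w <- d$n_presented
  if (all(d$n_test_heavier == 0) || all(d$n_test_heavier == d$n_presented))
    stop(errorCondition(
      "degenerate psychometric data: all responses one-sided",
      class = "vhlift_degenerate_fit"))
  model <- function(par) 100 * stats::pnorm((d$mass - par[1]) / par[2])
  obj <- function(par) sum(w * (pct - model(par))^2)
  # initialize mu at the weighted 50% crossing, sigma from the mass spread
  ord <- order(d$mass)
  mu0 <- tryCatch(stats::approx(pct[ord], d$mass[ord], xout = 50,
                                ties = mean)$y, error = function(e) NA)
  if (is.na(mu0)) mu0 <- sum(w * d$mass) / sum(w)
  span <- diff(range(d$mass))
  best <- NULL
  for (s0 in c(span / 6, span / 2)) {
    o <- stats::optim(c(mu0, s0), obj, method = "L-BFGS-B",
                      lower = c(min(d$mass) - 10 * span, sigma_bounds[1]),
                      upper = c(max(d$mass) + 10 * span, sigma_bounds[2]),
                      control = list(factr = 1e4))
    if (is.null(best) || o$value < best$value) best <- o
  }
  structure(list(mu = best$par[1], sigma = best$par[2],
                 residual = sqrt(best$value / sum(w)),
                 weights = w, n_points = nrow(d),
                 converged = best$convergence == 0),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "psychometric fit: mu = %.1f g, sigma = %.1f g (%d levels, wRMS %.2f%%)\n",
    x$mu, x$sigma, x$n_points, x$residual))
  invisible(x)
}

#' Total perceptual bias from the two session fits
#'
#' Each session's bias is its fitted PSE minus the 200-g standard,
#' expressed as a percentage of the standard. A session bias whose
#' magnitude exceeds the representable range of the test-mass set is set to
#' the maximum (45%) before combining. The total bias is half the
#' difference between the standard-delay and test-delay session biases;
#' positive values mean delayed cubes feel heavier.
#'
#' @param fit_standard_delay [fit_psychometric()] result of the session in
#'   which the standard cube was delayed.
#' @param fit_test_delay Fit of the session in which the test cube was
#'   delayed.
#' @param standard Standard mass, g.
#' @param max_bias Largest representable session bias, % of standard.
#' @return An object of class `bias_result` with `mu_standard_delay`,
#'   `mu_test_delay`, `bias_standard_delay`, `bias_test_delay` (%, after
#'   clamping), `total_bias` (%), `clamped`.
#' @export
total_bias <- function(fit_standard_delay, fit_test_delay,
                       standard = 200, max_bias = 45) {
  stopifnot(inherits(fit_standard_delay, "psychometric_fit"),
            inherits(fit_test_delay, "psychometric_fit"))
  clamp <- function(mu) {
    b <- (mu - standard) / standard * 100
    if (abs(b) > max_bias) list(b = sign(b) * max_bias, cl = TRUE)
    else list(b = b, cl = FALSE)
  }
  b_sd <- clamp(fit_standard_delay$mu)
  b_td <- clamp(fit_test_delay$mu)
  structure(list(mu_standard_delay = fit_standard_delay$mu,
                 mu_test_delay = fit_test_delay$mu,
                 bias_standard_delay = b_sd$b,
                 bias_test_delay = b_td$b,
                 total_bias = (b_sd$b - b_td$b) / 2,
                 clamped = b_sd$cl || b_td$cl),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf(
    "total bias %.1f%% (standard-delay PSE %.1f g, test-delay PSE %.1f g)%s\n",
    x$total_bias, x$mu_standard_delay, x$mu_test_delay,
    if (x$clamped) " [clamped]" else ""))
  invisible(x)
}
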