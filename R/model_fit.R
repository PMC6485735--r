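rmse <- function(data, model) sqrt(mean((data - model)^2))

#' Fit the loading duration on an averaged no-delay curve
#'
#' With no visual delay all three delay models coincide with the baseline
#' sigmoid, so the no-delay average identifies the participant- and
#' mass-specific loading duration `d`. The fit minimises the RMSE between
#' the measured mean load-force curve and the model over the samples from
#' curve onset (grip-force onset of the average, time 0 of an aligned curve)
#' up to the lift-off detected on the averaged curve.
#'
#' @param mean_lf Numeric vector: averaged load force (N), sampled at
#'   `rate_hz`, time zero at grip-force onset.
#' @param m Cube weight in newtons.
#' @param rate_hz Sampling rate (Hz).
#' @param gf_onset Curve onset time (s) relative to the first sample;
#'   default 0 (aligned curve).
#' @param liftoff Lift-off time (s) on the averaged curve; if `NULL`,
#'   re-detected as the first sample where `mean_lf >= m`.
#' @param d_bounds Search interval for `d` in seconds.
#' @return A list of class `lift_fit` with `kind = "base"`, `d`, `rmse`, `n`,
#'   `converged`.
#' @seealso [fit_weight()]
#' @export
fit_duration <- function(mean_lf, m, rate_hz, gf_onset = 0, liftoff = NULL,
                         d_bounds = c(0.05, 3)) {
  stopifnot(is.numeric(mean_lf), m > 0, rate_hz > 0)
  times <- (seq_along(mean_lf) - 1L) / rate_hz
  if (is.null(liftoff)) {
    idx <- which(mean_lf >= m - 1e-9 & times >= gf_onset)
    if (!length(idx)) stop("averaged curve never reaches the cube weight")
    liftoff <- times[idx[1L]]
  }
  if (liftoff <= gf_onset) stop("lift-off must follow curve onset")
  win <- times >= gf_onset & times <= liftoff
  n <- sum(win)
  if (n < 2L) stop("fewer than 2 samples in the fit window")
  obj <- function(d) {
    rmse(mean_lf[win], lf_curve(sine_lift_params(m, d, gf_onset), times[win]))
  }
  opt <- stats::optimize(obj, interval = d_bounds, tol = 1e-10)
  structure(list(kind = "base", d = opt$minimum, w_v = NA_real_,
                 rmse = opt$objective, n = n, converged = TRUE),
            class = "lift_fit")
}

#' Fit the visual weight on an averaged delay curve
#'
#' Takes the duration `d` fitted on the same participant-and-mass no-delay
#' average (assumed independent of the delay) and finds the visual weight
#' `w_v` that minimises the RMSE between the chosen delay model and the
#' measured averaged delay curve, over the samples up to the lift-off
#' detected on the delay curve.
#'
#' @param mean_lf Averaged load force (N) for a delay condition, time zero
#'   at grip-force onset.
#' @param kind Delay model: `"shift"`, `"stretch"` or `"sum"`.
#' @param p Baseline [sine_lift_params()] with `d` from the no-delay fit and
#'   `onset` matching the curve's time base (0 for aligned curves).
#' @param delay Visual delay in seconds.
#' @param rate_hz Sampling rate (Hz).
#' @param liftoff Lift-off (s) on the delay curve; re-detected if `NULL`.
#' @param bounds Optional length-2 numeric bounds on `w_v`. The default
#'   `NULL` leaves `w_v` effectively unconstrained (a wide internal interval
#'   is used, truncated where the stretch model would need a non-positive
#'   duration).
#' @return A list of class `lift_fit` with `kind`, `w_v`, `rmse`, `n`,
#'   `converged`.
#' @export
fit_weight <- function(mean_lf, kind = c("shift", "stretch", "sum"), p, delay,
                       rate_hz, liftoff = NULL, bounds = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(p, "sine_lift_params"), delay >= 0, rate_hz > 0)
  times <- (seq_along(mean_lf) - 1L) / rate_hz
  if (is.null(liftoff)) {
    idx <- which(mean_lf >= p$m - 1e-9 & times >= p$onset)
    if (!length(idx)) stop("delay curve never reaches the cube weight")
    liftoff <- times[idx[1L]]
  }
  win <- times >= p$onset & times <= liftoff
  n <- sum(win)
  if (n < 2L) stop("fewer than 2 samples in the fit window")
  if (is.null(bounds)) {
    bounds <- c(-2, 3)
    if (kind == "stretch" && delay > 0) {
      # keep the stretched duration positive
      bounds[1] <- max(bounds[1], -(p$d - 1e-3) / delay)
    }
  }
  if (delay == 0) {
    # all models reduce to the baseline; w_v is unidentifiable
    r <- rmse(mean_lf[win], lf_curve(p, times[win]))
    return(structure(list(kind = kind, w_v = NA_real_, rmse = r, n = n,
                          converged = FALSE), class = "lift_fit"))
  }
  obj <- function(w) {
    rmse(mean_lf[win], model_curve(kind, p, delay_spec(delay, w), times[win]))
  }
  opt <- stats::optimize(obj, interval = bounds, tol = 1e-10)
  conv <- opt$minimum > bounds[1] + 1e-6 && opt$minimum < bounds[2] - 1e-6
  structure(list(kind = kind, w_v = opt$minimum, rmse = opt$objective,
                 n = n, converged = conv),
            class = "lift_fit")
}

#' @export
print.lift_fit <- function(x, ...) {
  cat(sprintf("%s model fit: ", x$kind))
  if (!is.na(x$w_v)) cat(sprintf("w_v = %.3f, ", x$w_v))
  if (x$kind == "base") cat(sprintf("d = %.4f s, ", x$d))
  cat(sprintf("RMSE = %.4g N over %d samples (%s)\n", x$rmse, x$n,
              if (isTRUE(x$converged)) "converged" else "flagged"))
  invisible(x)
}

#' Compare the three delay models across fits
#'
#' Collates per-fit RMSE values into a per-case table (one row per
#' participant x condition, one RMSE column per model, the winning model,
#' and a tie flag) and an aggregate table (mean RMSE, win counts and mean
#' fitted `w_v` per model).
#'
#' @param fits A data.frame with columns `participant`, `condition`, `kind`,
#'   `w_v`, `rmse` (and optionally `converged`), holding all three kinds for
#'   each participant x condition on identical data windows.
#' @param tie_tol Absolute RMSE difference below which two models are
#'   declared tied.
#' @return List with `by_case` and `aggregate` data.frames.
#' @export
compare_models <- function(fits, tie_tol = 1e-12) {
  stopifnot(is.data.frame(fits),
            all(c("participant", "condition", "kind", "w_v", "rmse")
                %in% names(fits)))
  kinds <- c("shift", "stretch", "sum")
  case_key <- interaction(fits$participant, fits$condition, drop = TRUE)
  rows <- lapply(split(fits, case_key), function(g) {
    stopifnot(setequal(g$kind, kinds))
    r <- g$rmse[match(kinds, g$kind)]
    best_i <- which.min(r)
    tie <- sum(r - min(r) <= tie_tol) > 1L
    data.frame(participant = g$participant[1L], condition = g$condition[1L],
               rmse_shift = r[1L], rmse_stretch = r[2L], rmse_sum = r[3L],
               best = if (tie) "tie" else kinds[best_i], tie = tie,
               stringsAsFactors = FALSE)
  })
  by_case <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  aggregate <- do.call(rbind, lapply(kinds, function(k) {
    g <- fits[fits$kind == k, ]
    data.frame(kind = k,
               mean_rmse = mean(g$rmse),
               wins = sum(by_case$best == k),
               mean_w_v = mean(g$w_v, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(by_case = by_case, aggregate = aggregate)
}
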