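#' Construct a force trace
#'
#' One trial's uniformly sampled per-finger force (and optional position)
#' series with condition metadata.
#'
#' @param time Time base, s, strictly increasing and uniform.
#' @param thumb_normal,index_normal Normal (grip) force per finger, N.
#' @param thumb_vertical,index_vertical Vertical (load) force per finger, N.
#' @param thumb_pos,index_pos Optional n x 3 position matrices, mm.
#' @param mass Cube mass, g.
#' @param delay Visual delay, ms.
#' @param participant,trial Identifiers.
#' @param rate_tol Allowed deviation from a uniform time step, s.
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(time, thumb_normal, index_normal,
                        thumb_vertical, index_vertical,
                        thumb_pos = NULL, index_pos = NULL,
                        mass = NA_real_, delay = NA_real_,
                        participant = NA_character_, trial = NA_integer_,
                        rate_tol = 1e-6) {
  n <- length(time)
  stopifnot(n >= 2L,
            length(thumb_normal) == n, length(index_normal) == n,
            length(thumb_vertical) == n, length(index_vertical) == n)
  dts <- diff(time)
  if (any(dts <= 0) || max(dts) - min(dts) > rate_tol)
    stop("non-uniform time base (jitter exceeds tolerance)")
  if (!is.null(thumb_pos)) stopifnot(nrow(thumb_pos) == n, ncol(thumb_pos) == 3)
  if (!is.null(index_pos)) stopifnot(nrow(index_pos) == n, ncol(index_pos) == 3)
  structure(list(time = time, rate = 1 / stats::median(dts),
                 thumb_normal = thumb_normal, index_normal = index_normal,
                 thumb_vertical = thumb_vertical,
                 index_vertical = index_vertical,
                 thumb_pos = thumb_pos, index_pos = index_pos,
                 mass = mass, delay = delay,
                 participant = participant, trial = trial),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf(
    "force trace: %d samples at %.6g Hz (%.3g s), mass %g g, delay %g ms\n",
    length(x$time), x$rate, diff(range(x$time)), x$mass, x$delay))
  invisible(x)
}

#' Preprocess a force trace
#'
#' Linearly interpolates missing samples (`NA`) and applies the zero-phase
#' second-order low-pass Butterworth filter (15 Hz cutoff) to every force
#' channel. Positions are interpolated but not filtered.
#'
#' @param trace A [force_trace()].
#' @param cutoff_hz Filter cutoff, Hz.
#' @param filter Apply the low-pass stage? Disable for noiseless synthetic
#'   traces whose smooth curves need no smoothing.
#' @param max_missing Maximum tolerated fraction of missing samples per
#'   channel; above it the trial is rejected as a technical error.
#' @return The preprocessed `force_trace`.
#' @export
preprocess <- function(trace, cutoff_hz = 15, filter = TRUE,
                       max_missing = 0.1) {
  stopifnot(inherits(trace, "force_trace"))
  if (diff(range(trace$time)) < 1) stop("need at least 1 s of data")
  fix <- function(x) {
    miss <- mean(is.na(x))
    if (miss > max_missing)
      stop(errorCondition(sprintf(
        "missing fraction %.1f%% exceeds %.1f%%: technical error",
        100 * miss, 100 * max_missing), class = "vhlift_technical"))
    if (miss > 0)
      x <- stats::approx(trace$time[!is.na(x)], x[!is.na(x)],
                         xout = trace$time, rule = 2)$y
    if (filter) lowpass_filtfilt(x, trace$rate, cutoff_hz) else x
  }
  for (ch in c("thumb_normal", "index_normal",
               "thumb_vertical", "index_vertical"))
    trace[[ch]] <- fix(trace[[ch]])
  trace
}

#' Grip and load force series with rates
#'
#' Load force (LF) is the sum of the two vertical components; grip force
#' (GF) is the mean of the two normal components. Rates (LFR, GFR) are
#' central differences scaled by the sampling rate, one-sided at the
#' endpoints.
#'
#' @param trace A preprocessed [force_trace()].
#' @return An object of class `grip_load_series` with `time`, `lf`, `gf`,
#'   `lfr`, `gfr`, `rate` and the trace metadata.
#' @export
grip_load <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  lf <- trace$thumb_vertical + trace$index_vertical
  gf <- (trace$thumb_normal + trace$index_normal) / 2
  deriv <- function(x) {
    n <- length(x)
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * trace$rate / 2
    d[1] <- (x[2] - x[1]) * trace$rate
    d[n] <- (x[n] - x[n - 1]) * trace$rate
    d
  }
  structure(list(time = trace$time, rate = trace$rate,
                 lf = lf, gf = gf, lfr = deriv(lf), gfr = deriv(gf),
                 mass = trace$mass, delay = trace$delay,
                 participant = trace$participant, trial = trace$trial),
            class = "grip_load_series")
}

#' Detect lift events
#'
#' Load- and grip-force onsets are the first samples at or above a 0.1 N
#' threshold; lift-off is the first sample at or above the cube's weight,
#' at or after load-force onset.
#'
#' @param gls A [grip_load()] series.
#' @param cube_weight Cube weight, N.
#' @param threshold Onset threshold, N.
#' @param weight_tol Numerical slack (N) on the weight crossing, matching
#'   the generator's plateau guarantee.
#' @return An object of class `lift_events` with `lf_onset`, `gf_onset`,
#'   `liftoff` (s; `NA` when not found), `ok` and `reason`
#'   (`"none"`, `"no_lift"`, `"no_liftoff"`).
#' @export
detect_events <- function(gls, cube_weight, threshold = 0.1,
                          weight_tol = 1e-9) {
  stopifnot(inherits(gls, "grip_load_series"), cube_weight > 0)
  cube_weight <- cube_weight - weight_tol
  first_at <- function(x, level, from = 1L) {
    i <- which(x[from:length(x)] >= level)
    if (!length(i)) NA_integer_ else from + i[1L] - 1L
  }
  i_lf <- first_at(gls$lf, threshold)
  i_gf <- first_at(gls$gf, threshold)
  if (is.na(i_lf) || is.na(i_gf)) {
    return(structure(list(lf_onset = NA_real_, gf_onset = NA_real_,
                          liftoff = NA_real_, ok = FALSE,
                          reason = "no_lift"), class = "lift_events"))
  }
  i_lo <- first_at(gls$lf, cube_weight, from = i_lf)
  if (is.na(i_lo)) {
    return(structure(list(lf_onset = gls$time[i_lf],
                          gf_onset = gls$time[i_gf],
                          liftoff = NA_real_, ok = FALSE,
                          reason = "no_liftoff"), class = "lift_events"))
  }
  structure(list(lf_onset = gls$time[i_lf], gf_onset = gls$time[i_gf],
                 liftoff = gls$time[i_lo], ok = TRUE, reason = "none"),
            class = "lift_events")
}

#' @export
print.lift_events <- function(x, ...) {
  if (x$ok)
    cat(sprintf(
      "lift events: LF onset %.3f s, GF onset %.3f s, lift-off %.3f s\n",
      x$lf_onset, x$gf_onset, x$liftoff))
  else cat(sprintf("lift events: invalid (%s)\n", x$reason))
  invisible(x)
}

#' Scalar force-scaling parameters
#'
#' Computes the four force-scaling outcomes: the maximum load- and
#' grip-force rates within a window from 50 ms before the respective onset
#' to 50 ms after lift-off, the loading-phase duration (lift-off minus
#' load-force onset), and the grip force at the lift-off sample.
#'
#' @param gls A [grip_load()] series.
#' @param ev Valid [detect_events()] result.
#' @param margin Window margin around onset/lift-off, s.
#' @return An object of class `force_parameters` with `lfr_max`, `gfr_max`,
#'   `lpd`, `gf_at_lo` and a `truncated` flag set when the window had to be
#'   clipped to the available samples.
#' @export
force_parameters <- function(gls, ev, margin = 0.05) {
  stopifnot(inherits(gls, "grip_load_series"), inherits(ev, "lift_events"),
            isTRUE(ev$ok))
  t <- gls$time
  truncated <- FALSE
  win_max <- function(x, from, to) {
    if (from < t[1] || to > t[length(t)]) truncated <<- TRUE
    sel <- t >= max(from, t[1]) & t <= min(to, t[length(t)])
    max(x[sel])
  }
  lfr_max <- win_max(gls$lfr, ev$lf_onset - margin, ev$liftoff + margin)
  gfr_max <- win_max(gls$gfr, ev$gf_onset - margin, ev$liftoff + margin)
  i_lo <- which.min(abs(t - ev$liftoff))
  structure(list(lfr_max = lfr_max, gfr_max = gfr_max,
                 lpd = ev$liftoff - ev$lf_onset,
                 gf_at_lo = gls$gf[i_lo], truncated = truncated),
            class = "force_parameters")
}

#' @export
print.force_parameters <- function(x, ...) {
  cat(sprintf(
    "LFRmax %.3g N/s, GFRmax %.3g N/s, LPD %.3f s, GFatLO %.3g N%s\n",
    x$lfr_max, x$gfr_max, x$lpd, x$gf_at_lo,
    if (x$truncated) " (window truncated)" else ""))
  invisible(x)
}

#' Binned force-profile areas
#'
#' Signed trapezoidal areas of each signal (`lf`, `gf`, `lfr`, `gfr`) in
#' consecutive 100-ms bins starting at grip-force onset, over a 1-s window
#' (10 bins).
#'
#' @param gls A [grip_load()] series.
#' @param ev Valid [detect_events()] result (supplies the GF-onset
#'   alignment).
#' @param n_bins Number of bins.
#' @param bin_width Bin width, s.
#' @return A data.frame with columns `bin`, `t_start`, `lf`, `gf`, `lfr`,
#'   `gfr`; areas in signal units times seconds.
#' @export
binned_areas <- function(gls, ev, n_bins = 10L, bin_width = 0.1) {
  stopifnot(inherits(gls, "grip_load_series"), isTRUE(ev$ok))
  t <- gls$time
  i0 <- which.min(abs(t - ev$gf_onset))
  per_bin <- round(bin_width * gls$rate)
  need <- i0 + n_bins * per_bin
  if (need > length(t))
    stop("need at least 1 s of data after GF onset for binned areas")
  trapz <- function(x, i, j) sum((x[(i + 1):j] + x[i:(j - 1)]) / 2) / gls$rate
  out <- lapply(seq_len(n_bins), function(b) {
    i <- i0 + (b - 1L) * per_bin
    j <- i + per_bin
    data.frame(bin = b, t_start = (b - 1L) * bin_width,
               lf = trapz(gls$lf, i, j), gf = trapz(gls$gf, i, j),
               lfr = trapz(gls$lfr, i, j), gfr = trapz(gls$gfr, i, j))
  })
  do.call(rbind, out)
}

#' Reach kinematic parameters
#'
#' Movement start is the first sample at which either finger's velocity
#' component along the reach axis (the straight line from its start
#' position to its contact position) reaches 10 mm/s. Peak tangential
#' velocity and travelled path are computed per finger between movement
#' start and object contact (GF onset) and averaged over fingers; curvature
#' is the maximum perpendicular deviation from the straight start-contact
#' segment, averaged over fingers; the contact position along the reach
#' axis is reported per finger.
#'
#' @param trace A [force_trace()] carrying positions.
#' @param ev Valid [detect_events()] result (GF onset = contact).
#' @param speed_threshold Movement-start velocity threshold, mm/s.
#' @return An object of class `kinematic_parameters`: `peak_velocity`
#'   (mm/s), `path_length` (mm), `curvature` (mm), `contact_position`
#'   (named vector, mm along the reach axis), `movement_start` (s), `ok`.
#' @export
kinematics <- function(trace, ev, speed_threshold = 10) {
  stopifnot(inherits(trace, "force_trace"), isTRUE(ev$ok))
  if (is.null(trace$thumb_pos) || is.null(trace$index_pos))
    stop("trace carries no position data")
  t <- trace$time
  i_contact <- which.min(abs(t - ev$gf_onset))
  fingers <- list(thumb = trace$thumb_pos, index = trace$index_pos)
  axes <- lapply(fingers, function(p) {
    v <- p[i_contact, ] - p[1, ]
    v / sqrt(sum(v^2))
  })
  vel <- lapply(fingers, function(p) {
    rbind((p[2, ] - p[1, ]) * trace$rate,
          (p[3:i_contact, , drop = FALSE] -
             p[1:(i_contact - 2), , drop = FALSE]) * trace$rate / 2,
          (p[i_contact, ] - p[i_contact - 1, ]) * trace$rate)
  })
  along <- mapply(function(v, ax) as.numeric(v %*% ax), vel, axes,
                  SIMPLIFY = FALSE)
  started <- which(along$thumb >= speed_threshold |
                     along$index >= speed_threshold)
  if (!length(started))
    return(structure(list(peak_velocity = NA_real_, path_length = NA_real_,
                          curvature = NA_real_,
                          contact_position = c(thumb = NA_real_,
                                               index = NA_real_),
                          movement_start = NA_real_, ok = FALSE),
                     class = "kinematic_parameters"))
  i_start <- started[1L]
  per_finger <- mapply(function(p, v, ax) {
    seg <- p[i_start:i_contact, , drop = FALSE]
    speeds <- sqrt(rowSums(v[i_start:i_contact, , drop = FALSE]^2))
    steps <- diff(seg)
    path <- sum(sqrt(rowSums(steps^2)))
    a <- seg[1, ]; b <- seg[nrow(seg), ]
    ab <- b - a
    ab <- ab / sqrt(sum(ab^2))
    rel <- sweep(seg, 2, a)
    proj <- rel %*% ab
    perp <- rel - proj %*% t(ab)
    curv <- max(sqrt(rowSums(perp^2)))
    c(peak = max(speeds), path = path, curv = curv,
      contact = as.numeric(p[i_contact, ] %*% ax))
  }, fingers, vel, axes)
  structure(list(peak_velocity = mean(per_finger["peak", ]),
                 path_length = mean(per_finger["path", ]),
                 curvature = mean(per_finger["curv", ]),
                 contact_position = c(thumb = per_finger["contact", "thumb"],
                                      index = per_finger["contact", "index"]),
                 movement_start = t[i_start], ok = TRUE),
            class = "kinematic_parameters")
}

#' Screen trials for exclusion
#'
#' Applies the exclusion rules: `multiple_lift` when the load force
#' re-crosses `weight - tol` downward and then upward again after lift-off;
#' `drop` when the load force falls below `drop_frac * weight` during the
#' hold window; `technical` when events could not be detected;
#' `not_at_start` (kinematics only) when the start-position offset exceeds
#' the tolerance. Force analyses keep `not_at_start` trials.
#'
#' @param trials List of lists, each with elements `gls`
#'   ([grip_load()] series), `events` ([detect_events()] result), `weight`
#'   (N) and optionally `start_offset` (mm) and `hold_window` (length-2
#'   times, s).
#' @param tol Re-crossing tolerance below the weight, N.
#' @param drop_frac Fraction of the weight defining a drop.
#' @param start_tol Start-position tolerance, mm.
#' @return An `exclusion_report` data.frame: one row per trial with `trial`,
#'   `keep_forces`, `keep_kinematics`, `reason`.
#' @export
screen_trials <- function(trials, tol = 0.1, drop_frac = 0.5,
                          start_tol = 10) {
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    ev <- tr$events
    reason <- "none"
    keep <- TRUE
    if (!isTRUE(ev$ok)) {
      reason <- "technical"
      keep <- FALSE
    } else {
      t <- tr$gls$time
      hold <- if (!is.null(tr$hold_window)) tr$hold_window
              else c(ev$liftoff + 0.1, max(t))
      post <- t >= ev$liftoff & t <= hold[2]
      lf_post <- tr$gls$lf[post]
      in_hold <- t >= hold[1] & t <= hold[2]
      if (any(tr$gls$lf[in_hold] < drop_frac * tr$weight)) {
        reason <- "drop"; keep <- FALSE
      } else {
        below <- lf_post < tr$weight - tol
        # downward crossing followed by an upward one = a second lift
        if (any(below)) {
          first_down <- which(below)[1L]
          if (any(!below[first_down:length(below)])) {
            reason <- "multiple_lift"; keep <- FALSE
          }
        }
      }
    }
    off <- if (is.null(tr$start_offset)) 0 else abs(tr$start_offset)
    keep_kin <- keep && off <= start_tol
    if (keep && !keep_kin) reason <- "not_at_start"
    data.frame(trial = i, keep_forces = keep, keep_kinematics = keep_kin,
               reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("exclusion_report", "data.frame")
  out
}

#' Average grip/load curves across trials
#'
#' Aligns every trial at its grip-force onset (time zero), truncates to the
#' shortest available post-onset duration, and averages sample-wise.
#' Lift-off is re-detected on the averaged load-force curve.
#'
#' @param gls_list List of [grip_load()] series (equal sampling rates).
#' @param events_list List of matching valid [detect_events()] results.
#' @param cube_weight Cube weight (N) used to re-detect lift-off on the
#'   average; `NULL` skips re-detection.
#' @return List with `time` (s, starting at 0), `lf`, `gf` (means), `n`
#'   (trials averaged), and `liftoff` (s, or `NA`).
#' @export
average_curves <- function(gls_list, events_list, cube_weight = NULL) {
  stopifnot(length(gls_list) >= 1L,
            length(gls_list) == length(events_list))
  rate <- gls_list[[1L]]$rate
  aligned <- mapply(function(g, e) {
    stopifnot(abs(g$rate - rate) < 1e-6, isTRUE(e$ok))
    i0 <- which.min(abs(g$time - e$gf_onset))
    list(lf = g$lf[i0:length(g$lf)], gf = g$gf[i0:length(g$gf)])
  }, gls_list, events_list, SIMPLIFY = FALSE)
  len <- min(vapply(aligned, function(a) length(a$lf), integer(1)))
  lf <- rowMeans(vapply(aligned, function(a) a$lf[1:len], numeric(len)))
  gf <- rowMeans(vapply(aligned, function(a) a$gf[1:len], numeric(len)))
  time <- (seq_len(len) - 1L) / rate
  liftoff <- NA_real_
  if (!is.null(cube_weight)) {
    i <- which(lf >= cube_weight)
    if (length(i)) liftoff <- time[i[1L]]
  }
  list(time = time, lf = lf, gf = gf, n = length(gls_list),
       liftoff = liftoff, rate = rate)
}
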