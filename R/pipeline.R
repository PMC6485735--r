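# participant- and mass-specific loading duration used by the simulator:
# heavier cubes take longer to load, plus a small participant idiosyncrasy
sim_duration_for <- function(mass, participant_idx) {
  0.28 + 0.06 * mass / 100 + 0.015 * ((participant_idx - 1L) %% 5L - 2L)
}

scaled_design <- function(cfg, participant) {
  f <- cfg$rep_fraction
  n_nodelay <- max(1L, round(40 * f))
  n_delay <- max(1L, round(10 * f))
  grid <- do.call(rbind, lapply(cfg$masses, function(m) {
    data.frame(mass = m, delay = c(rep(0, n_nodelay),
                                   rep(cfg$delays[cfg$delays > 0],
                                       each = n_delay)))
  }))
  grid$participant <- participant
  grid$trial <- seq_len(nrow(grid))
  grid
}

stage_simulate <- function(cfg, outdir, log) {
  trace_dir <- file.path(outdir, "traces")
  dir.create(trace_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (pi in seq_len(cfg$participants)) {
    part <- sprintf("P%02d", pi)
    design <- scaled_design(cfg, part)
    set.seed(cfg$seed + 1000L * pi)
    design <- design[sample.int(nrow(design)), , drop = FALSE]
    design$trial <- seq_len(nrow(design))
    for (k in seq_len(nrow(design))) {
      m <- design$mass[k]; dly <- design$delay[k]
      d_true <- sim_duration_for(m, pi) + stats::rnorm(1, 0, 0.015)
      d_true <- max(0.2, d_true)
      sim <- lift_sim_config(cube_mass = m, visual_delay = dly,
                             true_duration_d = d_true,
                             true_w_v = cfg$true_w_v,
                             generative_model = cfg$generative_model,
                             noise_sd = cfg$noise_sd)
      rec <- synth_lift_trial(sim, trial_id = design$trial[k],
                              participant_id = part)
      file <- sprintf("%s_t%03d.csv", part, design$trial[k])
      write_trace_file(rec$trace, file.path(trace_dir, file))
      rows[[length(rows) + 1L]] <- data.frame(
        file = file.path("traces", file), participant = part,
        trial = design$trial[k], mass = m, delay = dly, valid = TRUE,
        true_d = d_true, true_w_v = cfg$true_w_v,
        true_contact = rec$truth_events$contact,
        true_liftoff = rec$truth_events$liftoff,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(outdir, "manifest.json"),
                 dataset_id = sprintf("synthetic-%s", cfg$design),
                 seed = cfg$seed)
  log("simulate", sprintf("wrote %d trials for %d participants",
                          nrow(manifest), cfg$participants))
  invisible(manifest)
}

stage_process <- function(cfg, outdir, log) {
  man <- read_manifest(file.path(outdir, "manifest.json"))
  trials <- man$trials
  params <- list(); bins <- list(); kin <- list(); screened <- list()
  curves <- list()
  for (k in seq_len(nrow(trials))) {
    tr <- read_trace_file(file.path(outdir, trials$file[k]),
                          mass = trials$mass[k], delay = trials$delay[k],
                          participant = trials$participant[k],
                          trial = trials$trial[k])
    tr <- preprocess(tr, cutoff_hz = cfg$filter_cutoff_hz)
    gls <- grip_load(tr)
    weight <- trials$mass[k] / 1000 * GRAVITY
    ev <- detect_events(gls, weight, threshold = cfg$onset_threshold_n)
    screened[[k]] <- list(gls = gls, events = ev, weight = weight)
    key <- sprintf("%s|%g|%g", trials$participant[k], trials$mass[k],
                   trials$delay[k])
    if (ev$ok) {
      fp <- force_parameters(gls, ev)
      params[[k]] <- data.frame(
        participant = trials$participant[k], trial = trials$trial[k],
        mass = trials$mass[k], delay = trials$delay[k],
        lf_onset_s = ev$lf_onset, gf_onset_s = ev$gf_onset,
        liftoff_s = ev$liftoff, lfr_max_n_s = fp$lfr_max,
        gfr_max_n_s = fp$gfr_max, lpd_s = fp$lpd, gf_at_lo_n = fp$gf_at_lo,
        stringsAsFactors = FALSE)
      ba <- binned_areas(gls, ev)
      ba <- cbind(data.frame(participant = trials$participant[k],
                             trial = trials$trial[k], mass = trials$mass[k],
                             delay = trials$delay[k]), ba)
      bins[[k]] <- ba
      km <- kinematics(tr, ev)
      if (km$ok)
        kin[[k]] <- data.frame(
          participant = trials$participant[k], trial = trials$trial[k],
          mass = trials$mass[k], delay = trials$delay[k],
          peak_velocity_mm_s = km$peak_velocity,
          path_length_mm = km$path_length, curvature_mm = km$curvature,
          contact_thumb_mm = km$contact_position[["thumb"]],
          contact_index_mm = km$contact_position[["index"]],
          stringsAsFactors = FALSE)
      curves[[key]] <- c(curves[[key]], list(list(gls = gls, ev = ev,
                                                  k = k)))
    }
  }
  report <- screen_trials(screened)
  report$participant <- trials$participant
  report$mass <- trials$mass
  report$delay <- trials$delay
  utils::write.csv(do.call(rbind, params),
                   file.path(outdir, "trial_parameters.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, bins),
                   file.path(outdir, "binned_areas.csv"), row.names = FALSE)
  if (length(kin))
    utils::write.csv(do.call(rbind, kin),
                     file.path(outdir, "kinematics.csv"), row.names = FALSE)
  utils::write.csv(report, file.path(outdir, "exclusions.csv"),
                   row.names = FALSE)
  avg_rows <- lapply(names(curves), function(key) {
    cc <- curves[[key]]
    cc <- cc[vapply(cc, function(x) report$keep_forces[x$k], logical(1))]
    if (!length(cc)) return(NULL)
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    weight <- as.numeric(parts[2]) / 1000 * GRAVITY
    av <- average_curves(lapply(cc, `[[`, "gls"),
                         lapply(cc, `[[`, "ev"), cube_weight = weight)
    data.frame(participant = parts[1], mass = as.numeric(parts[2]),
               delay = as.numeric(parts[3]), time_s = av$time,
               mean_lf_n = av$lf, mean_gf_n = av$gf, n_trials = av$n,
               liftoff_s = av$liftoff, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, avg_rows),
                   file.path(outdir, "averaged_curves.csv"),
                   row.names = FALSE)
  excl_counts <- table(report$reason)
  log("process", sprintf("processed %d trials; exclusions: %s",
                         nrow(trials),
                         paste(names(excl_counts), excl_counts,
                               sep = "=", collapse = ", ")))
  invisible(report)
}

stage_psych <- function(cfg, outdir, log) {
  # experiment-1 style magnitude estimates
  rating_rows <- list()
  for (pi in seq_len(cfg$participants)) {
    part <- sprintf("P%02d", pi)
    obs <- observer_config(delay_heaviness_gain = cfg$delay_heaviness_gain,
                           judgment_sd = cfg$judgment_sd,
                           rating_scale = 10 * pi)
    set.seed(cfg$seed + 2000L * pi)
    design <- scaled_design(cfg, part)
    for (k in seq_len(nrow(design)))
      rating_rows[[length(rating_rows) + 1L]] <- data.frame(
        participant = part, mass = design$mass[k], delay = design$delay[k],
        rating = simulate_rating(obs, design$mass[k], design$delay[k]),
        stringsAsFactors = FALSE)
  }
  ratings <- do.call(rbind, rating_rows)
  utils::write.csv(ratings, file.path(outdir, "ratings.csv"),
                   row.names = FALSE)
  utils::write.csv(zscore_ratings(ratings), file.path(outdir, "zscores.csv"),
                   row.names = FALSE)
  # experiment-2 style staircase sessions, both delay placements
  bias_rows <- list()
  for (pi in seq_len(cfg$participants)) {
    part <- sprintf("P%02d", pi)
    fits <- lapply(c("standard", "test"), function(pl) {
      obs <- observer_config(delay_heaviness_gain = cfg$delay_heaviness_gain,
                             judgment_sd = cfg$judgment_sd,
                             seed = cfg$seed + 3000L * pi +
                               as.integer(pl == "test"))
      s <- run_session(obs, staircase_session(
        delay_placement = pl, delay_level = cfg$exp2_delay))
      tryCatch(fit_psychometric(psychometric_data(s)),
               vhlift_degenerate_fit = function(e) NULL)
    })
    if (any(vapply(fits, is.null, logical(1)))) next
    br <- total_bias(fits[[1]], fits[[2]])
    bias_rows[[length(bias_rows) + 1L]] <- data.frame(
      participant = part, delay = cfg$exp2_delay,
      mu_standard_delay_g = br$mu_standard_delay,
      mu_test_delay_g = br$mu_test_delay,
      total_bias_pct = br$total_bias, clamped = br$clamped,
      stringsAsFactors = FALSE)
  }
  bias <- do.call(rbind, bias_rows)
  utils::write.csv(bias, file.path(outdir, "bias.csv"), row.names = FALSE)
  log("psych", sprintf("%d participants rated; %d bias sessions fitted",
                       cfg$participants, nrow(bias)))
  invisible(bias)
}

stage_modelfit <- function(cfg, outdir, log) {
  av <- utils::read.csv(file.path(outdir, "averaged_curves.csv"))
  fit_rows <- list()
  for (part in unique(av$participant)) {
    for (m in unique(av$mass[av$participant == part])) {
      sel0 <- av$participant == part & av$mass == m & av$delay == 0
      if (!any(sel0)) next
      base <- av[sel0, ]
      weight <- m / 1000 * GRAVITY
      rate <- 1 / stats::median(diff(base$time_s))
      lo0 <- base$liftoff_s[1]
      if (is.na(lo0)) next
      fd <- fit_duration(base$mean_lf_n, weight, rate, liftoff = lo0,
                         d_bounds = cfg$d_bounds)
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        participant = part, mass = m, delay = 0, kind = "base",
        d_s = fd$d, w_v = NA_real_, rmse_n = fd$rmse, n = fd$n,
        converged = fd$converged, stringsAsFactors = FALSE)
      for (dly in setdiff(unique(av$delay[av$participant == part &
                                            av$mass == m]), 0)) {
        dc <- av[av$participant == part & av$mass == m & av$delay == dly, ]
        if (is.na(dc$liftoff_s[1])) next
        p <- sine_lift_params(weight, fd$d, 0)
        for (kind in c("shift", "stretch", "sum")) {
          fw <- fit_weight(dc$mean_lf_n, kind, p, dly / 1000, rate,
                           liftoff = dc$liftoff_s[1], bounds = cfg$w_v_bounds)
          fit_rows[[length(fit_rows) + 1L]] <- data.frame(
            participant = part, mass = m, delay = dly, kind = kind,
            d_s = fd$d, w_v = fw$w_v, rmse_n = fw$rmse, n = fw$n,
            converged = fw$converged, stringsAsFactors = FALSE)
        }
      }
    }
  }
  fits <- do.call(rbind, fit_rows)
  utils::write.csv(fits, file.path(outdir, "model_fits.csv"),
                   row.names = FALSE)
  dfits <- fits[fits$kind != "base", ]
  if (nrow(dfits)) {
    dfits$condition <- sprintf("%gg_%gms", dfits$mass, dfits$delay)
    dfits$rmse <- dfits$rmse_n
    cmp <- compare_models(dfits[, c("participant", "condition", "kind",
                                    "w_v", "rmse")])
    utils::write.csv(cmp$by_case,
                     file.path(outdir, "model_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(cmp$aggregate,
                     file.path(outdir, "model_comparison_aggregate.csv"),
                     row.names = FALSE)
  }
  log("modelfit", sprintf("fitted %d curves", nrow(fits)))
  invisible(fits)
}

stage_report <- function(cfg, outdir, log) {
  read_if <- function(f) {
    p <- file.path(outdir, f)
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  params <- read_if("trial_parameters.csv")
  excl <- read_if("exclusions.csv")
  bias <- read_if("bias.csv")
  agg <- read_if("model_comparison_aggregate.csv")
  by_cond <- NULL
  if (!is.null(params)) {
    sp <- split(params, list(params$mass, params$delay), drop = TRUE)
    by_cond <- do.call(rbind, lapply(sp, function(g) data.frame(
      mass = g$mass[1], delay = g$delay[1], n = nrow(g),
      mean_lfr_max = mean(g$lfr_max_n_s), mean_gfr_max = mean(g$gfr_max_n_s),
      mean_lpd = mean(g$lpd_s), mean_gf_at_lo = mean(g$gf_at_lo_n))))
    row.names(by_cond) <- NULL
  }
  report <- list(
    seed = cfg$seed,
    force_parameters_by_condition = by_cond,
    exclusion_counts = if (!is.null(excl)) as.list(table(excl$reason)),
    mean_total_bias_pct = if (!is.null(bias)) mean(bias$total_bias_pct),
    model_comparison = agg)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  log("report", "report.json written")
  invisible(report)
}

#' Run the simulate-process-psych-modelfit-report pipeline
#'
#' Executes the requested stages in order on one output directory. The run
#' is a pure function of (config, seed): identical inputs give identical
#' output tables. Each stage appends a line to `pipeline.log` in the output
#' directory.
#'
#' @param config A [read_run_config()] list (or `NULL` for defaults).
#' @param outdir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("simulate", "process", "psych", "modelfit", "report")`.
#' @return Invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(config = NULL, outdir,
                         stages = c("simulate", "process", "psych",
                                    "modelfit", "report")) {
  if (is.null(config)) config <- read_run_config()
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "pipeline.log")
  log <- function(stage, msg) {
    cat(sprintf("[%s] seed=%s %s\n", stage, config$seed, msg),
        file = log_path, append = TRUE)
  }
  runners <- list(simulate = stage_simulate, process = stage_process,
                  psych = stage_psych, modelfit = stage_modelfit,
                  report = stage_report)
  results <- list()
  order_all <- c("simulate", "process", "psych", "modelfit", "report")
  for (st in order_all[order_all %in% stages])
    results[[st]] <- runners[[st]](config, outdir, log)
  invisible(results)
}

#' Command-line entry point
#'
#' `Rscript -e 'vhlift::vhlift_main()' <stage|all> --outdir DIR [--config
#' FILE] [--seed N] [--verbose]`. Stages: simulate, process, psych,
#' modelfit, report, all.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
vhlift_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--outdir", type = "character", default = "out"),
    optparse::make_option("--verbose", action = "store_true",
                          default = FALSE))
  parser <- optparse::OptionParser(
    usage = "%prog [simulate|process|psych|modelfit|report|all] [options]",
    option_list = spec)
  parsed <- optparse::parse_args(parser, args = args,
                                 positional_arguments = TRUE)
  stage <- if (length(parsed$args)) parsed$args[1L] else "all"
  opts <- parsed$options
  overrides <- list()
  if (!is.null(opts$seed)) overrides$seed <- opts$seed
  cfg <- read_run_config(opts$config, overrides)
  stages <- if (stage == "all")
    c("simulate", "process", "psych", "modelfit", "report") else stage
  status <- tryCatch({
    run_pipeline(cfg, opts$outdir, stages)
    if (opts$verbose)
      message("pipeline finished: ", paste(stages, collapse = ", "))
    0L
  }, error = function(e) {
    message("pipeline failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
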