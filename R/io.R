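TRACE_COLUMNS <- c("time_s", "thumb_normal_n", "index_normal_n",
                   "thumb_vertical_n", "index_vertical_n")
POS_COLUMNS <- c("thumb_x_mm", "thumb_y_mm", "thumb_z_mm",
                 "index_x_mm", "index_y_mm", "index_z_mm")

#' Write a force trace to a CSV file
#'
#' One header row naming the units; one row per sample.
#'
#' @param trace A [force_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_file <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  df <- data.frame(time_s = trace$time,
                   thumb_normal_n = trace$thumb_normal,
                   index_normal_n = trace$index_normal,
                   thumb_vertical_n = trace$thumb_vertical,
                   index_vertical_n = trace$index_vertical)
  if (!is.null(trace$thumb_pos) && !is.null(trace$index_pos)) {
    pos <- cbind(trace$thumb_pos, trace$index_pos)
    colnames(pos) <- POS_COLUMNS
    df <- cbind(df, pos)
  }
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a force trace from a CSV file
#'
#' Expects the schema written by [write_trace_file()]: mandatory columns
#' `time_s`, `thumb_normal_n`, `index_normal_n`, `thumb_vertical_n`,
#' `index_vertical_n`, optional per-finger position columns in mm. The time
#' base is checked for uniform sampling.
#'
#' @param path CSV file path.
#' @param mass,delay,participant,trial Metadata attached to the trace
#'   (usually from the dataset manifest).
#' @param rate_tol Allowed time-step jitter, s.
#' @return A [force_trace()].
#' @export
read_trace_file <- function(path, mass = NA_real_, delay = NA_real_,
                            participant = NA_character_, trial = NA_integer_,
                            rate_tol = 1e-6) {
  if (!file.exists(path)) stop("no such trace file: ", path)
  df <- utils::read.csv(path)
  missing <- setdiff(TRACE_COLUMNS, names(df))
  if (length(missing))
    stop("trace file ", basename(path),
         " lacks mandatory column(s): ", paste(missing, collapse = ", "))
  has_pos <- all(POS_COLUMNS %in% names(df))
  force_trace(time = df$time_s,
              thumb_normal = df$thumb_normal_n,
              index_normal = df$index_normal_n,
              thumb_vertical = df$thumb_vertical_n,
              index_vertical = df$index_vertical_n,
              thumb_pos = if (has_pos)
                as.matrix(df[, POS_COLUMNS[1:3]]) else NULL,
              index_pos = if (has_pos)
                as.matrix(df[, POS_COLUMNS[4:6]]) else NULL,
              mass = mass, delay = delay,
              participant = participant, trial = trial,
              rate_tol = rate_tol)
}

#' Write a dataset manifest
#'
#' @param trials data.frame with one row per trial (file, participant,
#'   mass, delay, validity, and ground-truth columns when synthetic).
#' @param path Output JSON path.
#' @param dataset_id Identifier string.
#' @param seed Creation seed.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(trials, path, dataset_id = "synthetic", seed = NA) {
  jsonlite::write_json(list(dataset_id = dataset_id, seed = seed,
                            schema_version = 1L, n_trials = nrow(trials),
                            trials = trials),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset manifest
#' @param path Manifest JSON path.
#' @return List with `dataset_id`, `seed`, `trials` (data.frame).
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a run configuration
#'
#' YAML key-value file; missing keys fall back to package defaults.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @param overrides Named list applied on top of the file.
#' @return List of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1L,
    design = "exp1",
    participants = 2L,
    rep_fraction = 0.1,       # fraction of the full exp-1 repetition counts
    masses = c(100, 200, 300, 400),
    delays = c(0, 100, 200),
    noise_sd = 0.01,
    true_w_v = 0.36,
    generative_model = "sum",
    filter_cutoff_hz = 15,
    onset_threshold_n = 0.1,
    exp2_delay = 200,
    delay_heaviness_gain = c("0" = 0, "100" = 0.04, "200" = 0.18),
    judgment_sd = 10,
    w_v_bounds = NULL,
    d_bounds = c(0.05, 3))
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}
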