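# One-call pipeline runner tying the stages into reproducible, config-driven
# runs. Every run writes the fully resolved configuration next to its
# outputs so any result file can be regenerated from disk.

PIPELINE_STAGES <- c("simulate", "score-plate", "fit-binding", "fit-dose",
                     "synergy", "flow-stats")

# allowed configuration keys per stage (unknown keys are rejected)
stage_keys <- function(stage) {
  common <- c("stage", "out_dir", "seed", "log_level")
  extra <- switch(stage,
    "simulate" = c("what", "kd_b_molar", "sigma_mp", "n_events",
                   "mitotic_fraction", "pt288_loss_prob", "ec50_molar",
                   "doses_molar", "bump_value", "plate_name"),
    "score-plate" = c("image_dir", "plate_map", "pixel_size", "decile",
                      "kernel_diameter_um", "window_um", "segment_factor",
                      "marker_factor", "tophat_factor", "mask_kind",
                      "min_well_cells", "min_control_cells"),
    "fit-binding" = c("titration", "mode", "p0_molar", "l0_molar",
                      "kd_l_molar", "r_free_mp", "r_bound_mp", "q",
                      "n_boot"),
    "fit-dose" = c("scores", "dose_column", "response_column"),
    "synergy" = "checkerboard",
    "flow-stats" = c("treated", "vehicle", "dna_window", "ph3_threshold",
                     "pt288_threshold", "n_boot"),
    stop("unknown stage: ", stage, call. = FALSE))
  c(common, extra)
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$stage)) {
    stop("config must be a list (or YAML file) with a `stage` entry",
         call. = FALSE)
  }
  if (!config$stage %in% PIPELINE_STAGES) {
    stop("unknown stage '", config$stage, "' (expected one of: ",
         paste(PIPELINE_STAGES, collapse = ", "), ")", call. = FALSE)
  }
  unknown <- setdiff(names(config), stage_keys(config$stage))
  if (length(unknown)) {
    stop("unknown config key(s) for stage ", config$stage, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  config$seed <- config$seed %||% 1L
  config$out_dir <- config$out_dir %||% stop("config needs `out_dir`", call. = FALSE)
  config$log_level <- config$log_level %||% "info"
  config
}

pipe_log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}

require_input <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop(sprintf("missing input for %s: %s", what, path %||% "<unset>"),
         call. = FALSE)
  }
  path
}

#' Run one pipeline stage from a configuration
#'
#' Executes the named stage (`simulate`, `score-plate`, `fit-binding`,
#' `fit-dose`, `synergy`, or `flow-stats`) deterministically from a
#' configuration list or YAML file, writing its artifacts plus the resolved
#' configuration (`resolved_config.yaml`) under `out_dir`. Unknown
#' configuration keys are rejected. Inputs are checked before any output is
#' written, so a failed run leaves no partial artifacts.
#'
#' @param config Configuration list or path to a YAML file. Must contain
#'   `stage` and `out_dir`; `seed` defaults to 1. Stage-specific keys are
#'   documented in the package vignette.
#' @return A list of result objects, invisibly; artifacts on disk under
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- resolve_config(config)
  result <- switch(config$stage,
    "simulate" = stage_simulate(config),
    "score-plate" = stage_score_plate(config),
    "fit-binding" = stage_fit_binding(config),
    "fit-dose" = stage_fit_dose(config),
    "synergy" = stage_synergy(config),
    "flow-stats" = stage_flow_stats(config))
  yaml::write_yaml(config, file.path(config$out_dir, "resolved_config.yaml"))
  invisible(result)
}

ensure_out_dir <- function(config) {
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
}

stage_simulate <- function(config) {
  what <- config$what %||% "fp"
  ensure_out_dir(config)
  if (what == "fp") {
    sys <- binding_system(KdB = config$kd_b_molar %||% 19e-9)
    gen <- generate_fp_titration(sys, sigma_mP = config$sigma_mp %||% 2,
                                 seed = config$seed)
    path <- file.path(config$out_dir, "fp_titration.csv")
    write.csv(gen$series, path, row.names = FALSE)
    jsonlite::write_json(gen$truth, file.path(config$out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    pipe_log(config, "simulate fp: %d observations -> %s", nrow(gen$series), path)
    return(gen)
  }
  if (what == "flow") {
    gen <- generate_flow(n_events = config$n_events %||% 10000L,
                         mitotic_fraction = config$mitotic_fraction %||% 0.05,
                         pt288_loss_prob = config$pt288_loss_prob %||% 0.4,
                         seed = config$seed)
    path <- file.path(config$out_dir, "flow_events.csv")
    write.csv(gen$events, path, row.names = FALSE)
    jsonlite::write_json(gen$truth, file.path(config$out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    pipe_log(config, "simulate flow: %d events -> %s", nrow(gen$events), path)
    return(gen)
  }
  if (what == "checkerboard") {
    gen <- generate_checkerboard(seed = config$seed,
                                 bump = if (!is.null(config$bump_value)) {
                                   list(value = config$bump_value,
                                        rows = 4:5, cols = 4:5)
                                 })
    path <- file.path(config$out_dir, "checkerboard.csv")
    write_checkerboard_csv(gen$grid, path)
    jsonlite::write_json(gen$truth[names(gen$truth) != "null_inhibition"],
                         file.path(config$out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    pipe_log(config, "simulate checkerboard -> %s", path)
    return(gen)
  }
  if (what == "plate") {
    doses <- config$doses_molar %||% (1e-8 * 2^(0:8))
    map <- make_plate_map(doses)
    plate <- generate_plate(plate_spec(), map,
                            misloc_curve(config$ec50_molar %||% 5e-8),
                            seed = config$seed, out_dir = config$out_dir,
                            plate_name = config$plate_name %||% "plate1")
    pipe_log(config, "simulate plate: %d wells -> %s",
             sum(map$role != "blank"), config$out_dir)
    return(plate)
  }
  stop("unknown simulate target: ", what, call. = FALSE)
}

stage_score_plate <- function(config) {
  image_dir <- require_input(config$image_dir, "score-plate images")
  map <- load_plate_map(require_input(config$plate_map, "plate map"))
  ensure_out_dir(config)
  cfg <- hcs_config(
    pixel_size = config$pixel_size %||% 0.65,
    decile = config$decile %||% 0.10,
    kernel_diameter_um = config$kernel_diameter_um %||% 25,
    window_um = config$window_um %||% 60,
    segment_factor = config$segment_factor %||% 100,
    marker_factor = config$marker_factor %||% 100,
    tophat_factor = config$tophat_factor %||% 100,
    mask_kind = config$mask_kind %||% "spindle",
    min_well_cells = config$min_well_cells %||% 20,
    min_control_cells = config$min_control_cells %||% 10)
  res <- score_plate(image_dir, map, cfg)
  write.csv(res$well_scores, file.path(config$out_dir, "well_scores.csv"),
            row.names = FALSE)
  write.csv(res$cells, file.path(config$out_dir, "cell_qc.csv"),
            row.names = FALSE)
  pipe_log(config,
           "score-plate: %d cells scored, %d nuclei, %d mitotic, %d empty masks; threshold %.4g",
           nrow(res$cells), res$qc["nuclei"], res$qc["mitotic"],
           res$qc["empty_mask"], res$threshold$threshold)
  res
}

stage_fit_binding <- function(config) {
  series <- read_titration_csv(require_input(config$titration, "titration table"))
  mode <- config$mode %||% "competition"
  cal <- anisotropy_calibration(config$r_free_mp %||% 60,
                                config$r_bound_mp %||% 120,
                                config$q %||% 1)
  ensure_out_dir(config)
  fit <- if (mode == "competition") {
    sys <- binding_system(P0 = config$p0_molar %||% 30e-9,
                          L0 = config$l0_molar %||% 10e-9,
                          KdL = config$kd_l_molar %||% 1.2e-9)
    fit_competition_kd(series, sys, cal, n_boot = config$n_boot %||% 1000L,
                       boot_seed = config$seed)
  } else {
    fit_direct_kd(series, L0 = config$l0_molar %||% 11e-9, cal = cal,
                  n_boot = config$n_boot %||% 1000L, boot_seed = config$seed)
  }
  write_fit_report(fit, file.path(config$out_dir, "binding_fit.json"))
  pipe_log(config, "fit-binding (%s): estimate %.4g M, converged %s",
           mode, fit$estimate, fit$converged)
  fit
}

stage_fit_dose <- function(config) {
  path <- require_input(config$scores, "dose-response table")
  d <- read.csv(path, stringsAsFactors = FALSE)
  dose_col <- config$dose_column %||% "dose_molar"
  resp_col <- config$response_column %||% "percent"
  if (!all(c(dose_col, resp_col) %in% names(d))) {
    stop("dose-response table needs columns ", dose_col, ", ", resp_col,
         call. = FALSE)
  }
  if ("flag" %in% names(d)) d <- d[is.na(d$flag) | d$flag == "", , drop = FALSE]
  ensure_out_dir(config)
  fit <- fit_4pl(d[[dose_col]], d[[resp_col]])
  write_fit_report(fit, file.path(config$out_dir, "dose_response_fit.json"))
  pipe_log(config, "fit-dose: midpoint %.4g M, converged %s",
           fit$ec50, fit$converged)
  fit
}

stage_synergy <- function(config) {
  grid <- read_checkerboard_csv(require_input(config$checkerboard,
                                              "checkerboard table"))
  ensure_out_dir(config)
  res <- bliss_analysis(grid)
  write_checkerboard_csv(res, file.path(config$out_dir, "synergy_surface.csv"))
  jsonlite::write_json(res$summary, file.path(config$out_dir, "synergy_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  pipe_log(config, "synergy: mean score %.4f, max 2x2 window %.4f",
           res$summary$mean_score, res$summary$max_window_mean)
  res
}

stage_flow_stats <- function(config) {
  treated <- read.csv(require_input(config$treated, "treated events"),
                      stringsAsFactors = FALSE)
  vehicle <- read.csv(require_input(config$vehicle, "vehicle events"),
                      stringsAsFactors = FALSE)
  ensure_out_dir(config)
  gcfg <- gate_config(
    dna_window = config$dna_window %||% c(1.8, 2.2),
    ph3_threshold = config$ph3_threshold %||% 3,
    pt288_threshold = config$pt288_threshold %||% 3)
  fold <- ph3_fold_change(treated, vehicle, gcfg,
                          n_boot = config$n_boot %||% 1000L,
                          boot_seed = config$seed)
  loss <- pthr288_loss(treated, gcfg, n_boot = config$n_boot %||% 1000L,
                       boot_seed = config$seed)
  out <- list(ph3_fold_change = fold, pt288_loss = loss)
  jsonlite::write_json(out, file.path(config$out_dir, "flow_stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  pipe_log(config, "flow-stats: fold %.3f, loss fraction %.3f",
           fold$fold, loss$fraction)
  out
}
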