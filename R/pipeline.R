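RUN_CONFIG_SCHEMA <- list(
  plate_dir = "character", layout = "character", out_dir = "character",
  mode = "character", seed = "numeric", verbosity = "numeric",
  simulate = "list", segmentation = "list", quantify = "list",
  screen = "list", kinetics = "list")

SEGMENTATION_KEYS <- c("threshold_method", "fixed_threshold",
                       "min_object_area_px", "ring_dilation_width_px",
                       "nucleus_erosion_px", "split_min_peak_distance_px")
SIMULATE_KEYS <- c("n_wells_negative", "n_wells_positive", "fields_per_well",
                   "n_cells", "field_shape", "crowding_px")
QUANTIFY_KEYS <- c("intensity_floor", "high_ratio_gate", "ratio_of_means")
SCREEN_KEYS <- c("fold_threshold")
KINETICS_KEYS <- c("max_displacement_px", "min_segment_len")

#' Validate a pipeline run configuration
#'
#' Configurations are plain YAML/JSON key-value documents. Unknown keys
#' (at the top level and inside each stage block) are rejected before any
#' stage runs.
#'
#' @param config a named list, or a path to a YAML (or JSON) file.
#' @return The validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                                 simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or a YAML/JSON path")
  unknown <- setdiff(names(config), names(RUN_CONFIG_SCHEMA))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  check_block <- function(name, allowed) {
    bad <- setdiff(names(config[[name]]), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", name,
                   paste(bad, collapse = ", ")))
  }
  check_block("segmentation", SEGMENTATION_KEYS)
  check_block("simulate", SIMULATE_KEYS)
  check_block("quantify", QUANTIFY_KEYS)
  check_block("screen", SCREEN_KEYS)
  check_block("kinetics", KINETICS_KEYS)
  defaults <- list(mode = "nuclear-ring", seed = 1L, verbosity = 1,
                   segmentation = list(), quantify = list(), screen = list(),
                   kinetics = list(), simulate = list())
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (!config$mode %in% c("nuclear-ring", "intensity"))
    stop("mode must be 'nuclear-ring' or 'intensity'")
  config
}

config_segmentation_params <- function(config) {
  do.call(segmentation_params, config$segmentation)
}

#' Run the end-to-end screening pipeline
#'
#' Orchestrates (optionally) simulate, then segment, quantify and screen,
#' writing a deterministic output tree: per-cell CSV, per-well CSV, a
#' screen-result JSON + hit CSV, a JSON-lines run log, and a manifest
#' recording the normalized config, its MD5 hash and the seed. CSVs are
#' written atomically (temp file + rename), so a failing stage never
#' leaves a partial table.
#'
#' @param config run configuration (list or YAML/JSON path), see
#'   \code{\link{validate_config}}. Either \code{plate_dir} + \code{layout}
#'   must name an existing plate, or a \code{simulate} block requests a
#'   synthetic one.
#' @param fields optional pre-loaded list of fields (skips reading
#'   \code{plate_dir}).
#' @return Invisibly, a list with the cell records, well summaries and
#'   \code{screen_result}; outputs are under \code{config$out_dir}.
#' @export
run_pipeline <- function(config, fields = NULL) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config needs an out_dir")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  logline <- function(stage, ...) {
    rec <- list(stage = stage, ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
    if (isTRUE(config$verbosity >= 1))
      message(sprintf("[%s] %s", stage,
                      paste(names(rec)[-1], unlist(rec[-1]),
                            sep = "=", collapse = " ")))
  }

  if (!is.null(config$simulate) && length(config$simulate)) {
    sim <- config$simulate
    n_neg <- sim$n_wells_negative %||% 4
    n_pos <- sim$n_wells_positive %||% 4
    layout <- data.frame(
      well_id = sprintf("%s%02d", rep(c("B", "C"), c(n_neg, n_pos)),
                        c(seq_len(n_neg), seq_len(n_pos))),
      role = rep(c("negative_control", "positive_control"), c(n_neg, n_pos)),
      treatment_label = rep(c("mock", "max_response"), c(n_neg, n_pos)),
      concentration = "")
    sc <- scene_spec(n_cells = sim$n_cells %||% 40,
                     field_shape = sim$field_shape %||% c(256, 256),
                     crowding_px = sim$crowding_px %||% 28)
    plate <- generate_plate(layout, fields_per_well = sim$fields_per_well %||% 1,
                            scene = sc, noise = noise_spec(seed = config$seed))
    fields <- plate
    logline("simulate", wells = nrow(layout), fields = length(plate),
            seed = config$seed)
  } else {
    layout <- read_layout(config$layout)
    if (is.null(fields)) {
      if (is.null(config$plate_dir)) stop("config needs plate_dir or simulate")
      fields <- read_plate(config$plate_dir, layout)
    }
    logline("read", fields = length(fields))
  }
  if (!"negative_control" %in% layout$role)
    stop("layout has no negative_control wells; fold-change and gating ",
         "need mock-treated controls")

  params <- config_segmentation_params(config)
  floor <- config$quantify$intensity_floor %||% 9
  records <- analyze_fields(fields, mode = config$mode, params = params,
                            intensity_floor = floor)
  write_cell_table(records, file.path(out_dir, "cells.csv"))
  logline("quantify", mode = config$mode, cells = nrow(records))

  wells <- well_summary(records, layout,
                        high_ratio_gate = config$quantify$high_ratio_gate)
  wcopy <- wells
  num <- vapply(wcopy, is.numeric, logical(1))
  wcopy[num] <- lapply(wcopy[num], function(x) {
    y <- formatC(x, digits = 15, format = "g"); y[is.na(x)] <- ""; y
  })
  write_atomic(wcopy, file.path(out_dir, "wells.csv"))

  screen <- call_hits(wells, layout,
                      fold_threshold = config$screen$fold_threshold %||% 3.0)
  write_atomic(screen$hits, file.path(out_dir, "hits.csv"))
  sj <- list(z_prime = screen$z_prime,
             control_stats = as.list(screen$control_stats),
             positive_stats = as.list(screen$positive_stats),
             fold_threshold = screen$fold_threshold,
             n_hits = sum(screen$hits$is_hit))
  writeLines(jsonlite::toJSON(sj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "screen.json"))
  logline("screen", z_prime = round(screen$z_prime, 4),
          hits = sum(screen$hits$is_hit))

  norm_cfg <- config[order(names(config))]
  cfg_path <- file.path(out_dir, "config_normalized.yaml")
  yaml::write_yaml(norm_cfg, cfg_path)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = config$seed, mode = config$mode,
                   n_fields = length(fields), n_cells = nrow(records))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(list(records = records, wells = wells, screen = screen,
                 layout = layout))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
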