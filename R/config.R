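# Experiment configuration (YAML), reproducible experiment runner, fixtures.

#' Read / write an experiment configuration
#'
#' A YAML file tying one reproducible experiment together: tissue source
#' (raster file or synthetic-brain spec), parameter values, treatment
#' schedule, snapshot days, optional tracking window, seed. The
#' configuration round-trips losslessly through the file.
#'
#' @param path YAML file path.
#' @return object of class `experiment_config` (a named list).
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg, path)
  if (!is.null(cfg$snapshot_days))
    cfg$snapshot_days <- as.numeric(unlist(cfg$snapshot_days))
  class(cfg) <- "experiment_config"
  cfg
}

#' @rdname read_experiment_config
#' @param config an `experiment_config` (or plain list in the same layout).
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg, path = "<config>") {
  need <- c("tissue", "parameters", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop(path, ": missing required field(s): ", paste(miss, collapse = ", "))
  if (is.null(cfg$tissue$file) && is.null(cfg$tissue$synthetic))
    stop(path, ": tissue must name either 'file' or a 'synthetic' spec")
  rg <- param_ranges()
  unknown <- setdiff(names(cfg$parameters),
                     c(rg$param, "kappa", "dt", "end_day", "injection_radius",
                       "injection_site", "n_injected", "n_recruited0",
                       "quiescent_migrate", "max_cells"))
  if (length(unknown))
    stop(path, ": unknown parameter field(s): ", paste(unknown, collapse = ", "))
  invisible(cfg)
}

config_domain <- function(cfg, base_dir = ".") {
  if (!is.null(cfg$tissue$file)) {
    p <- cfg$tissue$file
    if (!file.exists(p)) p <- file.path(base_dir, cfg$tissue$file)
    load_tissue_raster(p, px_size = cfg$tissue$px_size %||% 17.4)
  } else {
    s <- cfg$tissue$synthetic
    make_synthetic_brain(
      width_mm = s$width_mm, height_mm = s$height_mm,
      tract = s$tract, ventricles = s$ventricles,
      px_size = s$px_size %||% 17.4, shape = s$shape %||% "rect",
      seed = s$seed %||% cfg$seed)
  }
}

config_params <- function(cfg) {
  pf <- cfg$parameters
  fixed <- intersect(names(pf), c("kappa", "dt", "end_day", "injection_radius",
                                  "injection_site", "n_injected",
                                  "n_recruited0", "quiescent_migrate",
                                  "max_cells"))
  rg <- param_ranges()
  do.call(parameter_set, c(pf[intersect(names(pf), rg$param)], pf[fixed]))
}

config_schedule <- function(cfg) {
  if (is.null(cfg$treatment)) return(NULL)
  tr <- cfg$treatment
  treatment_schedule(kind = tr$kind %||% "none",
                     start_day = tr$start_day %||% 14,
                     end_day = tr$end_day %||% 42,
                     ap_threshold = tr$ap_threshold %||% 60,
                     am_factor = tr$am_factor %||% 0.1)
}

#' Run a configured experiment
#'
#' Executes the simulation described by a config file and writes a
#' reproducible artifact directory: a copy of the configuration, the metrics
#' JSON (one entry per snapshot day), cell/track CSV snapshots, and a run log.
#' Re-running with the same config reproduces identical outputs.
#'
#' @param config path to a YAML config, or an `experiment_config`.
#' @param out_dir output directory (created; must be writable).
#' @param base_dir directory against which relative tissue paths resolve.
#' @return `out_dir`, invisibly; side effect: artifact files.
#' @export
run_experiment <- function(config, out_dir, base_dir = ".") {
  cfg <- if (is.character(config)) read_experiment_config(config) else {
    validate_config(config); config
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  domain <- config_domain(cfg, base_dir)
  params <- config_params(cfg)
  schedule <- config_schedule(cfg)
  tracking <- cfg$tracking

  run <- simulate_tumor(domain, params, schedule = schedule,
                        record_days = unlist(cfg$snapshot_days),
                        seed = cfg$seed, tracking = tracking)

  write_experiment_config(cfg, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(run$reports, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(cells_df(run$final$pop),
                   file.path(out_dir, "cells_final.csv"), row.names = FALSE)
  utils::write.csv(run$log, file.path(out_dir, "log.csv"), row.names = FALSE)
  if (!is.null(run$tracks))
    write_tracks_csv(run$tracks, file.path(out_dir, "tracks.csv"))
  grid <- density_grid(run$final$pop, domain, params$kappa)
  utils::write.csv(data.frame(node = seq_along(grid$counts),
                              x_um = grid$cx, y_um = grid$cy,
                              count = grid$counts, capacity = grid$capacity),
                   file.path(out_dir, "density_final.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Write the bundled fixture set
#'
#' Miniature, analytically convenient inputs used by the examples and tests:
#' a small tissue map with a white-matter band, a reference-metrics CSV
#' holding the experimental calibration values, and toy track tables with
#' known statistics (a straight mover and a stop-and-go walker).
#'
#' @param out_dir target directory.
#' @return invisible character vector of written paths.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  dom <- make_synthetic_brain(2, 2, tract = list(y_mm = 1, thickness_mm = 0.4),
                              px_size = 20, seed = 42)
  p <- file.path(out_dir, "mini_brain.pgm")
  write_tissue_raster(dom, p); paths <- c(paths, p)

  ref <- reference_metrics(extended = TRUE)
  p <- file.path(out_dir, "reference_metrics.csv")
  utils::write.csv(ref, p, row.names = FALSE); paths <- c(paths, p)

  # straight mover: 20 um/h for 10 h at 3-min frames
  t_h <- seq(0, 10, by = 0.05)
  straight <- data.frame(track_id = 1L, cell_id = 1L, lineage = "INFECTED",
                         t_h = t_h, x_um = 20 * t_h, y_um = 0,
                         divided = FALSE, mother = FALSE)
  p <- file.path(out_dir, "track_straight.csv")
  write_tracks_csv(straight, p); paths <- c(paths, p)

  # stop-and-go: 30 um/h for 10 h, then stopped for 10 h
  t_h <- seq(0, 20, by = 0.05)
  x <- pmin(t_h, 10) * 30
  sg <- data.frame(track_id = 2L, cell_id = 2L, lineage = "RECRUITED",
                   t_h = t_h, x_um = x, y_um = 0,
                   divided = FALSE, mother = FALSE)
  p <- file.path(out_dir, "track_stop_go.csv")
  write_tracks_csv(sg, p); paths <- c(paths, p)

  invisible(paths)
}
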