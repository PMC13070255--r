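# Stage driver: YAML run configuration, schema validation, execution with
# provenance capture. One flat schema with per-stage key sets; unknown
# keys are errors (silent typo-defaults are worse than a failed run).

stage_schemas <- list(
  simulate_pattern = c("field_size", "mode", "species_densities",
                       "cluster_diameter", "cluster_occupancy", "n_clusters",
                       "contact_gap", "localization_precision_sd"),
  simulate_trace = c("n_steps", "unit_intensity", "frame_interval",
                     "bleach_rate", "noise_sd", "baseline", "n_frames"),
  simulate_tracks = c("model", "D", "corral_diameter", "velocity",
                      "n_tracks", "track_length", "frame_interval",
                      "localization_error_sd"),
  simulate_scene = c("n_cells", "beads_internal_per_cell",
                     "beads_external_per_cell", "dye_per_target", "px_nm"),
  smlm_gr = c("reference", "target", "roi", "bin_width", "r_max", "n_reps"),
  smlm_relations = c("table_a", "table_b", "roi", "min_points",
                     "max_reach_nm", "contact_dist_nm", "intermix_frac"),
  bleach_count = c("trace", "direct_count_limit", "window_last_k",
                   "baseline"),
  spt_analyze = c("tracks", "max_precision_nm", "min_length", "fit_lags",
                  "low", "high"),
  morph_uptake = c("targets", "outside", "dye", "cells", "px_nm", "mode",
                   "outside_overlap_frac", "control_mean")
)

#' Read and validate a run configuration
#'
#' A run configuration is a flat YAML mapping with the reserved keys
#' \code{stage}, \code{seed}, \code{out} plus the parameter keys of the
#' named stage. Unknown keys are errors naming the key.
#'
#' @param path YAML file path, or a list already in memory.
#' @return Validated config list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg$stage)) stop("config error: missing `stage`")
  if (!cfg$stage %in% names(stage_schemas)) {
    stop(sprintf("config error: unknown stage '%s' (known: %s)",
                 cfg$stage, paste(names(stage_schemas), collapse = ", ")))
  }
  allowed <- c("stage", "seed", "out", stage_schemas[[cfg$stage]])
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop(sprintf("config error: unknown key(s) for stage '%s': %s",
                 cfg$stage, paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$out)) stop("config error: missing `out` directory")
  class(cfg) <- "run_config"
  cfg
}

cfg_get <- function(cfg, key, default) cfg[[key]] %||% default

write_provenance <- function(out_dir, cfg, inputs = character(0)) {
  prov <- list(
    package = "efferoquant",
    version = as.character(utils::packageVersion("efferoquant")),
    stage = cfg$stage,
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("stage", "seed", "out"))],
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run a pipeline stage from a configuration
#'
#' Executes the configured stage against its input files, writes the
#' results and a provenance record (parameters, package version, seed,
#' input checksums) into \code{cfg$out}, and returns the result invisibly.
#'
#' Stages: \code{simulate_pattern}, \code{simulate_trace},
#' \code{simulate_tracks}, \code{simulate_scene} (generators, write data
#' plus ground-truth JSON); \code{smlm_gr} (radial distribution with
#' envelope), \code{smlm_relations}, \code{bleach_count},
#' \code{spt_analyze}, \code{morph_uptake} (analyses).
#'
#' @param cfg A \code{run_config} (or path / list accepted by
#'   \code{\link{read_run_config}}).
#' @return The stage result, invisibly.
#' @export
run_stage <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- read_run_config(cfg)
  out <- cfg$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  inputs <- character(0)

  result <- switch(cfg$stage,
    simulate_pattern = {
      spec <- pattern_spec(
        field_size = cfg_get(cfg, "field_size", 10000),
        mode = cfg_get(cfg, "mode", "csr"),
        species_densities = unlist(cfg_get(cfg, "species_densities", c(0.4, 0.4))),
        cluster_diameter = cfg_get(cfg, "cluster_diameter", 120),
        cluster_occupancy = unlist(cfg_get(cfg, "cluster_occupancy", c(10, 10))),
        n_clusters = cfg$n_clusters,
        contact_gap = cfg_get(cfg, "contact_gap", 0),
        localization_precision_sd = cfg_get(cfg, "localization_precision_sd", 10),
        seed = seed)
      pat <- gen_point_pattern(spec)
      write_localizations(pat$table, file.path(out, "localizations.csv"))
      write_roi_geojson(pat$roi, file.path(out, "roi.geojson"))
      jsonlite::write_json(list(centers = pat$centers),
                           file.path(out, "ground_truth.json"),
                           digits = NA, dataframe = "columns")
      pat
    },
    simulate_trace = {
      spec <- trace_spec(
        n_steps = cfg$n_steps,
        unit_intensity = cfg_get(cfg, "unit_intensity", 100),
        frame_interval = cfg_get(cfg, "frame_interval", 0.1),
        bleach_rate = cfg_get(cfg, "bleach_rate", 0.005),
        noise_sd = cfg_get(cfg, "noise_sd", 0),
        baseline = cfg_get(cfg, "baseline", 0),
        n_frames = cfg$n_frames, seed = seed)
      tr <- gen_bleach_trace(spec)
      utils::write.csv(tr$trace, file.path(out, "trace.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(step_frames = tr$step_frames,
                                n_steps = spec$n_steps),
                           file.path(out, "ground_truth.json"), digits = NA)
      tr
    },
    simulate_tracks = {
      spec <- motion_spec(
        model = cfg_get(cfg, "model", "brownian"),
        D = cfg_get(cfg, "D", 0.1),
        corral_diameter = cfg_get(cfg, "corral_diameter", 200),
        velocity = cfg_get(cfg, "velocity", 1),
        n_tracks = cfg_get(cfg, "n_tracks", 100),
        track_length = cfg_get(cfg, "track_length", 100),
        frame_interval = cfg_get(cfg, "frame_interval", 0.1),
        localization_error_sd = cfg_get(cfg, "localization_error_sd", 20),
        seed = seed)
      tj <- gen_trajectories(spec)
      write_trajectories(tj$tracks, file.path(out, "tracks.csv"))
      jsonlite::write_json(list(model = spec$model, D = spec$D),
                           file.path(out, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      tj
    },
    simulate_scene = {
      sc <- gen_uptake_scene(
        n_cells = cfg_get(cfg, "n_cells", 2),
        beads_internal_per_cell = cfg_get(cfg, "beads_internal_per_cell", 3),
        beads_external_per_cell = cfg_get(cfg, "beads_external_per_cell", 2),
        dye_per_target = cfg_get(cfg, "dye_per_target", 1000),
        px_nm = cfg_get(cfg, "px_nm", 200),
        seed = seed)
      for (ch in names(sc$channels)) {
        write_image_stack(sc$channels[[ch]],
                          file.path(out, paste0(ch, ".tif")))
      }
      jsonlite::write_json(sc$truth, file.path(out, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      sc
    },
    smlm_gr = {
      inputs <- c(cfg$reference, cfg$target, cfg$roi)
      ref <- read_localizations(cfg$reference)
      tgt <- read_localizations(cfg$target)
      roi <- read_roi_geojson(cfg$roi)
      bins <- seq(0, cfg_get(cfg, "r_max", 500),
                  by = cfg_get(cfg, "bin_width", 10))
      rd <- radial_distribution(ref, tgt, bins, roi)
      env <- mc_envelope(ref, tgt, bins, roi,
                         n_reps = cfg_get(cfg, "n_reps", 100), seed = seed)
      rd$envelope_low <- env$low
      rd$envelope_high <- env$high
      utils::write.csv(rd, file.path(out, "gr.csv"), row.names = FALSE)
      rd
    },
    smlm_relations = {
      inputs <- c(cfg$table_a, cfg$table_b, cfg$roi)
      ta <- read_localizations(cfg$table_a)
      tb <- read_localizations(cfg$table_b)
      roi <- read_roi_geojson(cfg$roi)
      ca <- extract_clusters(ta, min_points = cfg_get(cfg, "min_points", 5),
                             max_reach_nm = cfg_get(cfg, "max_reach_nm", 50))
      cb <- extract_clusters(tb, min_points = cfg_get(cfg, "min_points", 5),
                             max_reach_nm = cfg_get(cfg, "max_reach_nm", 50))
      rel <- classify_cluster_relations(
        ca, cb, contact_dist_nm = cfg_get(cfg, "contact_dist_nm", 20),
        intermix_frac = cfg_get(cfg, "intermix_frac", 0.5),
        roi = roi, seed = seed)
      jsonlite::write_json(unclass(rel)[c("colocalized_fraction",
                                          "contacting_fraction",
                                          "neither_fraction",
                                          "randomized_colocalized",
                                          "randomized_contacting", "params")],
                           file.path(out, "relations.json"),
                           auto_unbox = TRUE, digits = NA)
      rel
    },
    bleach_count = {
      inputs <- cfg$trace
      tr <- utils::read.csv(cfg$trace)
      fit <- count_molecules(
        tr, direct_count_limit = cfg_get(cfg, "direct_count_limit", 28),
        window_last_k = cfg_get(cfg, "window_last_k", 15),
        baseline = cfg_get(cfg, "baseline", 0))
      jsonlite::write_json(
        list(molecule_count = fit$molecule_count, n_steps = fit$n_steps,
             method = fit$method, unit_intensity = fit$unit_intensity,
             step_frames = fit$step_frames, metadata = fit$metadata),
        file.path(out, "stepfit.json"), auto_unbox = TRUE, digits = NA)
      fit
    },
    spt_analyze = {
      inputs <- cfg$tracks
      tj <- read_trajectories(cfg$tracks)
      filt <- filter_trajectories(
        tj, max_precision_nm = cfg_get(cfg, "max_precision_nm", 25),
        min_length = cfg_get(cfg, "min_length", 20))
      res <- analyze_tracks(filt,
                            fit_lags = cfg_get(cfg, "fit_lags", 4),
                            low = cfg_get(cfg, "low", 0.30),
                            high = cfg_get(cfg, "high", 0.63),
                            min_length = cfg_get(cfg, "min_length", 20))
      utils::write.csv(res, file.path(out, "per_track.csv"),
                       row.names = FALSE)
      summ <- fraction_confined(res, seed = seed)
      utils::write.csv(summ, file.path(out, "summary.csv"),
                       row.names = FALSE)
      list(per_track = res, summary = summ)
    },
    morph_uptake = {
      inputs <- c(cfg$targets, cfg$outside, cfg$dye, cfg$cells)
      cells <- lapply(jsonlite::read_json(cfg$cells, simplifyVector = TRUE),
                      function(m) as_polygon(m))
      scene <- list(
        channels = list(
          targets = read_image_stack(cfg$targets)[[1]],
          outside = read_image_stack(cfg$outside)[[1]],
          dye = if (!is.null(cfg$dye)) read_image_stack(cfg$dye)[[1]]),
        cells = cells, px_nm = cfg_get(cfg, "px_nm", 200))
      res <- uptake_index(scene, mode = cfg_get(cfg, "mode", "beads"),
                          outside_overlap_frac =
                            cfg_get(cfg, "outside_overlap_frac", 0.5),
                          control_mean = cfg$control_mean)
      jsonlite::write_json(unclass(res), file.path(out, "uptake.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    },
    stop(sprintf("stage '%s' not implemented", cfg$stage))
  )
  write_provenance(out, cfg, inputs)
  invisible(result)
}
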