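# End-to-end orchestration: simulate (or read) -> segment -> quantify ->
# kinetics -> report.

#' Configuration of a pipeline run
#'
#' Collects every tunable constant of the pipeline in one place: the imaging
#' layout, the segmentation parameters (absolute threshold 10, minimum size
#' 3 voxels, 26-connectivity by default), the 2-h reference time, the cycle
#' clock, the RNG seed, and any overrides for the synthetic generator.
#'
#' @param flow_rate `"0.1"`, `"0.5"`, `"1.5"` or `"4.0"` (ml/h per inlet).
#' @param n_x,areas,window_px,z_slices,n_cycles,t_first See [imaging_layout()].
#' @param t_ref Reference time in minutes for normalisation and the initial
#'   cluster count.
#' @param threshold,min_voxels,connectivity See [segment_stack()].
#' @param seed Integer RNG seed.
#' @param noise,blur Noise-model toggles for the generator.
#' @param input_dir Optional directory of existing TIFF stacks (named as in
#'   [stack_manifest()]); when given, stacks are read instead of simulated.
#' @param out_dir Optional directory for report CSVs.
#' @param ... Further overrides passed to [synthetic_params()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(flow_rate = "0.1", n_x = 12L, areas = "a",
                       window_px = 128L, z_slices = NULL, n_cycles = NULL,
                       t_first = 40, t_ref = 120,
                       threshold = 10, min_voxels = 3, connectivity = 26,
                       seed = 1L, noise = TRUE, blur = noise,
                       input_dir = NULL, out_dir = NULL, ...) {
  flow_rate <- match.arg(as.character(flow_rate), flow_rate_table()$flow_rate)
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    abort(paste0("input_dir does not exist: ", input_dir),
          class = "bff_not_found")
  }
  structure(list(flow_rate = flow_rate, n_x = n_x, areas = areas,
                 window_px = window_px, z_slices = z_slices,
                 n_cycles = n_cycles, t_first = t_first, t_ref = t_ref,
                 threshold = threshold, min_voxels = min_voxels,
                 connectivity = connectivity, seed = as.integer(seed),
                 noise = noise, blur = blur,
                 input_dir = input_dir, out_dir = out_dir,
                 params_overrides = list(...)),
            class = "run_config")
}

config_layout <- function(config) {
  imaging_layout(flow_rate = config$flow_rate, n_x = config$n_x,
                 areas = config$areas, window_px = config$window_px,
                 z_slices = config$z_slices, n_cycles = config$n_cycles,
                 t_first = config$t_first)
}

config_params <- function(config) {
  do.call(synthetic_params,
          c(list(flow_rate = config$flow_rate, noise = config$noise,
                 blur = config$blur), config$params_overrides))
}

# segment every cycle of one position's synthetic stacks, in memory
segment_position <- function(sim, position, layout, params, config) {
  purrr::map_dfr(seq_len(layout$n_cycles), function(n) {
    sph <- sim$spheres |> dplyr::filter(.data$cycle == n)
    stack <- render_stack(sph, layout, params)
    segment_stack(stack, threshold = config$threshold,
                  min_voxels = config$min_voxels,
                  connectivity = config$connectivity,
                  voxel_dims = layout$voxel_dims) |>
      dplyr::mutate(position = position, cycle = n, .before = 1)
  })
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the stacks of every position, segments them,
#' assembles the per-cycle quantification series, normalises to the 2-h
#' reference, fits exponential growth, detects dispersal onsets and
#' aggregates replicate areas per axial location. Deterministic for a fixed
#' `seed`. When `out_dir` is set, each stage's table is written as CSV; with
#' `resume = TRUE` an existing `series.csv` is read back instead of
#' re-simulating and re-segmenting.
#'
#' @param config A [run_config()].
#' @param resume Reuse `out_dir/series.csv` if present.
#' @return A list of class `pipeline_result`: `clusters`, `series` (with
#'   `vnorm`), `growth`, `onsets`, `by_location`, `propagation_min`, `truth`
#'   (per-position `g` and `t_disp`, synthetic runs only), `layout`, `config`.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  layout <- config_layout(config)
  params <- config_params(config)
  out_dir <- config$out_dir

  series_csv <- if (!is.null(out_dir)) file.path(out_dir, "series.csv")
  clusters <- NULL
  truth <- NULL

  if (resume && !is.null(series_csv) && file.exists(series_csv)) {
    series <- as_tibble(read.csv(series_csv, stringsAsFactors = FALSE))
  } else {
    set.seed(config$seed)
    pieces <- vector("list", nrow(layout$positions))
    truths <- vector("list", nrow(layout$positions))
    for (k in seq_len(nrow(layout$positions))) {
      pos <- layout$positions[k, ]
      if (!is.null(config$input_dir)) {
        pieces[[k]] <- purrr::map_dfr(seq_len(layout$n_cycles), function(n) {
          path <- file.path(config$input_dir,
                            sprintf("pos%s_cycle%03d.tif", pos$position, n))
          segment_stack(read_stack(path), threshold = config$threshold,
                        min_voxels = config$min_voxels,
                        connectivity = config$connectivity,
                        voxel_dims = layout$voxel_dims) |>
            dplyr::mutate(position = pos$position, cycle = n, .before = 1)
        })
      } else {
        sim <- evolve_clusters(params, layout, pos$x_index)
        truths[[k]] <- tibble(position = pos$position, x_index = pos$x_index,
                              g = sim$g, t_disp = sim$t_disp)
        pieces[[k]] <- segment_position(sim, pos$position, layout, params,
                                        config)
      }
    }
    clusters <- dplyr::bind_rows(pieces)
    truth <- if (is.null(config$input_dir)) dplyr::bind_rows(truths)
    series <- quantify_series(clusters, layout)
  }

  series <- normalize_series(series, t_ref = config$t_ref)
  growth <- fit_growth_by_position(series)
  onsets <- detect_dispersal_by_position(series)
  by_location <- summarize_by_location(series, layout, t_ref = config$t_ref)
  propagation <- tryCatch(propagation_stat(by_location),
                          error = function(e) NA_real_)

  result <- structure(list(clusters = clusters, series = series,
                           growth = growth, onsets = onsets,
                           by_location = by_location,
                           propagation_min = propagation,
                           truth = truth, layout = layout, config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_report(result, out_dir)
  result
}

#' Write the report bundle of a pipeline run
#'
#' Emits `series.csv`, `growth.csv`, `onsets.csv`, `by_location.csv`,
#' `clusters.csv` (when available) and a `run_log.json` with every parameter
#' of the run.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) if (!is.null(x)) {
    write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wr(result$series, "series.csv")
  wr(result$growth, "growth.csv")
  wr(result$onsets, "onsets.csv")
  wr(result$by_location, "by_location.csv")
  wr(result$clusters, "clusters.csv")
  log <- unclass(result$config)
  log$params_overrides <- NULL
  log <- log[!vapply(log, is.null, logical(1))]
  log$package_version <- as.character(utils::packageVersion("biofilmflow"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d positions x %d cycles (flow %s ml/h)\n",
              nrow(x$layout$positions), x$layout$n_cycles, x$config$flow_rate))
  cat(sprintf("  upstream-downstream onset difference: %.1f min\n",
              x$propagation_min))
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds any subset of [run_config()]'s arguments (including
#' generator overrides); unspecified fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such config file: ", path), class = "bff_not_found")
  }
  fields <- yaml::read_yaml(path)
  do.call(run_config, fields)
}
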