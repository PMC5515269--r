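# Synthetic confocal time-lapse generator with known ground truth.
#
# Emulates the statistical structure of the flow-cell experiments: Poisson
# attachment of small clusters, clonal exponential growth at a constant
# per-position rate, single-cell shedding that drifts downstream, and a
# dispersal wave that starts at the most downstream position and propagates
# upstream at a fixed delay per position, after which cluster biovolume
# decays exponentially. Stacks are rendered as spheres, blurred with an
# anisotropic Gaussian PSF and corrupted with Poisson shot noise plus
# Gaussian read noise on an 8-bit intensity scale.

# per-flow-rate kinetic defaults: doubling time (min; interpolated between the
# observed 68 +- 2 min at the lowest and 49 +- 2 min at the highest rate),
# dispersal onset at position 12 (min, run-1 means) and the time for the
# dispersal front to cross from position 12 to position 1 (min)
synthetic_kinetics_table <- function() {
  tibble(flow_rate = c("0.1", "0.5", "1.5", "4.0"),
         doubling_time = c(68, 62, 55, 49),
         onset_t12 = c(370, 432, 472, 539),
         propagation_span = c(63, 45, 32, 10))
}

#' Parameters of the synthetic biofilm experiment
#'
#' Defaults encode the study conditions of the emulated experiments; kinetic
#' defaults (doubling time, dispersal onset at position 12, upstream
#' propagation span) are selected per flow rate, see
#' `biofilmflow:::synthetic_kinetics_table()`.
#'
#' @param flow_rate One of `"0.1"`, `"0.5"`, `"1.5"`, `"4.0"` (ml/h per inlet).
#' @param mean_initial_clusters Expected number of clusters attached per
#'   window at the start of flow (Poisson mean).
#' @param single_cell_volume Biovolume of one cell, um^3.
#' @param initial_cluster_volume_max Maximum cluster biovolume (um^3) at the
#'   1-h observation point; attachment volumes are drawn uniformly so that no
#'   cluster exceeds this after one hour of growth.
#' @param doubling_time,growth_rate Growth kinetics; supply at most one.
#'   `growth_rate` is per minute; default `log(2) / doubling_time`.
#' @param detachment_rate Expected single-cell shedding events per cluster per
#'   imaging cycle once shedding starts.
#' @param detachment_start Time (min) at which shedding begins; before this
#'   the population grows purely clonally.
#' @param dispersal_onset_t12 Dispersal onset time (min) at position 12.
#' @param propagation_span Minutes for the dispersal front to travel from
#'   position 12 to position 1; the per-position delay is `span / 11`.
#' @param decay_halflife Biovolume half-life (min) after dispersal onset.
#' @param dispersal_shedding_fraction Fraction of the biovolume a dispersing
#'   cluster loses per cycle that reattaches within the window as transient
#'   single cells (the remainder washes out of the field of view).
#' @param dispersed_cell_lifetime Residence time, in imaging cycles, of a
#'   cell shed during dispersal before it washes away.
#' @param background_intensity,cell_intensity 8-bit counts. The default
#'   plateau of 20 places the segmentation threshold of 10 at half-plateau so
#'   the PSF-blurred cluster boundary is localised without bias.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF standard deviations, um.
#' @param read_noise_sd Gaussian read-noise standard deviation, counts.
#' @param noise,blur Toggles for the noise model and PSF blur.
#' @param edge_margin Minimum distance (um) of initial cluster centres from
#'   the lateral window border, so that windows sample cluster interiors.
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(flow_rate = "0.1",
                             mean_initial_clusters = 30,
                             single_cell_volume = 2,
                             initial_cluster_volume_max = 25,
                             doubling_time = NULL,
                             growth_rate = NULL,
                             detachment_rate = 0.02,
                             detachment_start = 120,
                             dispersal_onset_t12 = NULL,
                             propagation_span = NULL,
                             decay_halflife = 20,
                             dispersal_shedding_fraction = 0.05,
                             dispersed_cell_lifetime = 2,
                             background_intensity = 2,
                             cell_intensity = 20,
                             psf_sigma_xy = 0.2,
                             psf_sigma_z = 0.5,
                             read_noise_sd = 1.5,
                             noise = TRUE,
                             blur = TRUE,
                             edge_margin = 6) {
  flow_rate <- match.arg(as.character(flow_rate), flow_rate_table()$flow_rate)
  kin <- synthetic_kinetics_table() |>
    dplyr::filter(.data$flow_rate == !!flow_rate)
  if (!is.null(doubling_time) && !is.null(growth_rate)) {
    abort("supply only one of `doubling_time` and `growth_rate`",
          class = "bff_invalid_parameter")
  }
  if (is.null(growth_rate)) {
    if (is.null(doubling_time)) doubling_time <- kin$doubling_time
    check_positive(doubling_time, "doubling_time")
    growth_rate <- log(2) / doubling_time
  }
  check_positive(growth_rate, "growth_rate")
  if (is.null(dispersal_onset_t12)) dispersal_onset_t12 <- kin$onset_t12
  if (is.null(propagation_span)) propagation_span <- kin$propagation_span
  check_positive(mean_initial_clusters, "mean_initial_clusters")
  check_positive(single_cell_volume, "single_cell_volume")
  check_positive(decay_halflife, "decay_halflife")
  check_positive(cell_intensity, "cell_intensity")
  if (detachment_rate < 0 || background_intensity < 0 || read_noise_sd < 0 ||
      psf_sigma_xy < 0 || psf_sigma_z < 0 || propagation_span < 0 ||
      dispersal_shedding_fraction < 0 || dispersed_cell_lifetime < 0) {
    abort("rates, intensities and PSF widths must be non-negative",
          class = "bff_invalid_parameter")
  }
  if (cell_intensity <= 10 + 3 * read_noise_sd) {
    abort("cell_intensity must exceed the segmentation threshold (10) by more than 3 read-noise SDs",
          class = "bff_invalid_parameter")
  }
  check_flag(noise, "noise"); check_flag(blur, "blur")
  structure(list(
    flow_rate = flow_rate,
    mean_initial_clusters = mean_initial_clusters,
    single_cell_volume = single_cell_volume,
    initial_cluster_volume_max = initial_cluster_volume_max,
    growth_rate = growth_rate,
    detachment_rate = detachment_rate,
    detachment_start = detachment_start,
    dispersal_onset_t12 = dispersal_onset_t12,
    propagation_span = propagation_span,
    decay_halflife = decay_halflife,
    dispersal_shedding_fraction = dispersal_shedding_fraction,
    dispersed_cell_lifetime = dispersed_cell_lifetime,
    background_intensity = background_intensity,
    cell_intensity = cell_intensity,
    psf_sigma_xy = psf_sigma_xy,
    psf_sigma_z = psf_sigma_z,
    read_noise_sd = read_noise_sd,
    noise = noise, blur = blur,
    edge_margin = edge_margin
  ), class = "synthetic_params")
}

# dispersal onset time for an axial position (position 12 first, upstream
# positions delayed by propagation_span / 11 per step)
position_onset <- function(params, x_index) {
  params$dispersal_onset_t12 + params$propagation_span / 11 * (12 - x_index)
}

# cluster biovolume at time t: exponential growth from birth until the
# position's onset, then exponential decay with the configured half-life.
# Cells shed after the onset (birth_t > t_disp) keep their single-cell
# volume until they wash away.
cluster_volume_at <- function(t, birth_t, v0, g, t_disp, halflife) {
  n <- max(length(t), length(birth_t), length(v0))
  t <- rep_len(t, n); birth_t <- rep_len(birth_t, n); v0 <- rep_len(v0, n)
  grow_until <- pmin(t, t_disp)
  v <- v0 * exp(g * pmax(grow_until - birth_t, 0))
  decaying <- t > t_disp & birth_t <= t_disp
  v[decaying] <- v[decaying] * 2^(-(t[decaying] - t_disp) / halflife)
  v
}

#' Evolve the cluster population of one imaging window
#'
#' Simulates attachment, clonal growth, single-cell shedding and dispersal at
#' one axial position and returns per-cycle sphere geometries together with
#' the exact ground truth. Uses the current RNG state; seed the session (or
#' use [simulate_experiment()]) for reproducibility.
#'
#' @param params A [synthetic_params()] object.
#' @param layout An [imaging_layout()].
#' @param x_index Axial position index (1 = most upstream, 12 = at the outlet,
#'   where dispersal starts).
#' @return A list of class `synthetic_position`: `spheres` (tibble `cycle`,
#'   `t_min`, `id`, `x_um`, `y_um`, `z_um`, `r_um`, `v_true`), `registry`
#'   (per-cluster birth time and attachment volume), and `truth` (`g`,
#'   `t_disp`, per-cycle `n_true` and `v_total_true`).
#' @export
evolve_clusters <- function(params, layout, x_index) {
  stopifnot(inherits(params, "synthetic_params"),
            inherits(layout, "imaging_layout"))
  g <- params$growth_rate
  t_disp <- position_onset(params, x_index)
  w_um <- layout$window_um
  depth_um <- layout$z_slices * layout$voxel_dims[3]
  margin <- min(params$edge_margin, w_um / 4)
  times <- cycle_times(layout)

  # mean_initial_clusters refers to the standard 212.55-um window; reduced
  # windows observe the same surface density over a smaller field of view.
  # Every analysed window holds at least one cluster (empty fields of view
  # are not imaged).
  lambda <- params$mean_initial_clusters * (w_um / 212.55)^2
  n0 <- max(1L, rpois(1, lambda))
  v0_max <- max(params$single_cell_volume,
                params$initial_cluster_volume_max * exp(-g * 60))
  registry <- tibble(
    id = seq_len(n0),
    birth_t = 0,
    x_um = runif(n0, margin, w_um - margin),
    y_um = runif(n0, margin, w_um - margin),
    v0 = runif(n0, params$single_cell_volume, v0_max)
  )

  registry$death_t <- Inf
  spawn <- function(parents, t, death_t = Inf) {
    tot <- nrow(parents)
    tibble(
      id = max(registry$id) + seq_len(tot),
      birth_t = t,
      x_um = pmin(pmax(parents$x_um + runif(tot, 2, 10), 0.5), w_um - 0.5),
      y_um = pmin(pmax(parents$y_um + rnorm(tot, 0, 2), 0.5), w_um - 0.5),
      v0 = params$single_cell_volume,
      death_t = death_t
    )
  }

  # single-cell shedding, displaced downstream (+x) within the window.
  # During growth, each live cluster sheds Poisson(detachment_rate) cells per
  # cycle. During dispersal, a cluster releases its biovolume as cells, of
  # which a fraction reattaches within the window as transient single cells
  # (the rest washes out immediately); this reproduces the surge in cluster
  # count that accompanies the drop in biovolume at dispersal commencement.
  lifetime <- params$dispersed_cell_lifetime * layout$cycle_interval
  for (t in times[times >= params$detachment_start]) {
    founders <- registry$birth_t <= t & registry$birth_t <= t_disp
    if (!any(founders)) next
    parents <- registry[founders, ]
    if (t < t_disp) {
      if (params$detachment_rate <= 0) next
      n_new <- rpois(nrow(parents), params$detachment_rate)
      if (sum(n_new) == 0) next
      registry <- dplyr::bind_rows(
        registry, spawn(parents[rep(seq_len(nrow(parents)), n_new), ], t))
    } else {
      v_prev <- cluster_volume_at(t - layout$cycle_interval, parents$birth_t,
                                  parents$v0, g, t_disp,
                                  params$decay_halflife)
      v_now <- cluster_volume_at(t, parents$birth_t, parents$v0, g, t_disp,
                                 params$decay_halflife)
      shed <- pmax(v_prev - v_now, 0) / params$single_cell_volume
      n_new <- rpois(nrow(parents), params$dispersal_shedding_fraction * shed)
      if (sum(n_new) == 0) next
      registry <- dplyr::bind_rows(
        registry,
        spawn(parents[rep(seq_len(nrow(parents)), n_new), ], t,
              death_t = t + lifetime))
    }
  }

  spheres <- purrr::map_dfr(seq_along(times), function(n) {
    t <- times[n]
    live <- registry |>
      dplyr::filter(.data$birth_t <= t, .data$death_t > t)
    v <- cluster_volume_at(t, live$birth_t, live$v0, g, t_disp,
                           params$decay_halflife)
    r <- (3 * v / (4 * pi))^(1 / 3)
    z <- ifelse(2 * r <= depth_um, r, depth_um / 2) # sit on substrate if it fits
    tibble(cycle = n, t_min = t, id = live$id,
           x_um = live$x_um, y_um = live$y_um, z_um = z,
           r_um = r, v_true = v)
  })

  truth <- spheres |>
    dplyr::group_by(.data$cycle, .data$t_min) |>
    dplyr::summarise(n_true = dplyr::n(),
                     v_total_true = sum(.data$v_true), .groups = "drop")

  structure(list(x_index = x_index, g = g, t_disp = t_disp,
                 registry = registry, spheres = spheres, truth = truth),
            class = "synthetic_position")
}

#' Render one confocal z-stack from sphere geometries
#'
#' Voxels whose centre lies inside any sphere receive the cell plateau
#' intensity (others the background), the grid is convolved with an
#' anisotropic Gaussian PSF, Poisson shot noise is sampled per voxel and
#' Gaussian read noise added, and the result is clipped to the 8-bit range.
#'
#' @param spheres Tibble with `x_um`, `y_um`, `z_um`, `r_um` for one cycle.
#' @param layout An [imaging_layout()] (grid dimensions and voxel size).
#' @param params A [synthetic_params()] (intensities, PSF, noise toggles).
#' @return Integer 3-D array `window_px x window_px x z_slices`.
#' @export
render_stack <- function(spheres, layout, params) {
  dims <- c(layout$window_px, layout$window_px, layout$z_slices)
  vol <- cpp_render_spheres(dims, layout$voxel_dims,
                            spheres$x_um, spheres$y_um, spheres$z_um,
                            spheres$r_um,
                            params$cell_intensity, params$background_intensity)
  if (params$blur && (params$psf_sigma_xy > 0 || params$psf_sigma_z > 0)) {
    sigma_vox <- c(params$psf_sigma_xy / layout$voxel_dims[1],
                   params$psf_sigma_xy / layout$voxel_dims[2],
                   params$psf_sigma_z / layout$voxel_dims[3])
    vol <- cpp_blur3d(vol, dims, sigma_vox)
  }
  if (params$noise) {
    vol <- rpois(length(vol), vol) + rnorm(length(vol), 0, params$read_noise_sd)
  }
  array(as.integer(pmin(pmax(round(vol), 0), 255)), dim = dims)
}

#' Planned stack manifest of an experiment
#'
#' One row per (position, cycle) with the output filename used by
#' [simulate_experiment()].
#'
#' @param layout An [imaging_layout()].
#' @return Tibble with `position`, `cycle`, `filename`.
#' @export
stack_manifest <- function(layout) {
  tidyr::expand_grid(position = layout$positions$position,
                     cycle = seq_len(layout$n_cycles)) |>
    dplyr::mutate(filename = sprintf("pos%s_cycle%03d.tif",
                                     .data$position, .data$cycle))
}

#' Simulate a whole imaging experiment to disk
#'
#' Runs [evolve_clusters()] for every position in the layout, renders every
#' cycle with [render_stack()], writes one multi-page TIFF per (position,
#' cycle) and a ground-truth JSON. Deterministic for a fixed `seed`.
#'
#' @param params A [synthetic_params()].
#' @param layout An [imaging_layout()].
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param overwrite Overwrite existing stack files? Default `FALSE` (existing
#'   files raise an error).
#' @return Invisibly, the manifest tibble with absolute `path`s.
#' @export
simulate_experiment <- function(params, layout, out_dir, seed = NULL,
                                overwrite = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- stack_manifest(layout) |>
    dplyr::mutate(path = file.path(out_dir, .data$filename))
  clash <- file.exists(manifest$path)
  if (!overwrite && any(clash)) {
    abort(paste0("output files already exist, e.g. ", manifest$path[which(clash)[1]]),
          class = "bff_io_error")
  }

  truth <- list()
  for (k in seq_len(nrow(layout$positions))) {
    pos <- layout$positions[k, ]
    sim <- evolve_clusters(params, layout, pos$x_index)
    for (n in seq_len(layout$n_cycles)) {
      sph <- sim$spheres |> dplyr::filter(.data$cycle == n)
      stack <- render_stack(sph, layout, params)
      write_stack(stack, file.path(out_dir,
                                   sprintf("pos%s_cycle%03d.tif", pos$position, n)))
    }
    truth[[pos$position]] <- list(
      x_index = pos$x_index, g = sim$g, t_disp = sim$t_disp,
      cycles = as.list(sim$truth)
    )
  }
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
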