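# Per-window biovolume metrics: totals, normalisation, initial cluster
# count, size distribution and equivalent sphere diameters.

#' Total biovolume of a cluster list
#'
#' The total biovolume of an imaging window at one cycle is the sum of its
#' cluster biovolumes; an empty window has total 0.
#'
#' @param clusters Cluster tibble (from [segment_stack()]) or a numeric
#'   vector of cluster biovolumes in um^3.
#' @return Total biovolume in um^3.
#' @export
total_biovolume <- function(clusters) {
  v <- if (is.data.frame(clusters)) clusters$volume_um3 else clusters
  if (length(v) == 0) return(0)
  if (any(v < 0)) {
    abort("negative cluster biovolume in input", class = "bff_invariant_error")
  }
  sum(v)
}

#' Build a per-cycle quantification series from cluster tables
#'
#' Collapses per-cluster rows to one row per (position, cycle) with the
#' cluster count `n_clusters` and total biovolume `biovolume_um3`; cycles with
#' no clusters appear with zero count and volume.
#'
#' @param clusters Tibble with at least `position`, `cycle`, `volume_um3`.
#' @param layout An [imaging_layout()] providing the cycle clock.
#' @return Tibble `position`, `cycle`, `t_min`, `n_clusters`, `biovolume_um3`.
#' @export
quantify_series <- function(clusters, layout) {
  grid <- tidyr::expand_grid(position = unique(clusters$position),
                             cycle = seq_len(layout$n_cycles))
  clusters |>
    dplyr::group_by(.data$position, .data$cycle) |>
    dplyr::summarise(n_clusters = dplyr::n(),
                     biovolume_um3 = sum(.data$volume_um3), .groups = "drop") |>
    dplyr::right_join(grid, by = c("position", "cycle")) |>
    dplyr::mutate(n_clusters = dplyr::coalesce(.data$n_clusters, 0L),
                  biovolume_um3 = dplyr::coalesce(.data$biovolume_um3, 0),
                  t_min = cycle_to_time(.data$cycle, layout)) |>
    dplyr::arrange(.data$position, .data$cycle) |>
    dplyr::select("position", "cycle", "t_min", "n_clusters", "biovolume_um3")
}

# index of the cycle whose time is nearest t_ref (exact tie -> earlier cycle)
reference_cycle <- function(t_min, t_ref) {
  d <- abs(t_min - t_ref)
  which(d == min(d))[1]
}

#' Normalise a biovolume series to its reference cycle
#'
#' Divides each position's total biovolume by its value at the reference time
#' (default 2 h, by which cells are permanently attached), so positions with
#' different amounts of attached biomass can be compared. The reference cycle
#' is the one whose time is nearest `t_ref` (exact tie: the earlier cycle).
#'
#' @param series Tibble from [quantify_series()] (may hold many positions).
#' @param t_ref Reference time in minutes, default 120.
#' @return `series` with columns `vnorm`, `ref_cycle` and `ref_biovolume`
#'   added. A zero reference biovolume raises an error naming the positions.
#' @export
normalize_series <- function(series, t_ref = 120) {
  out <- series |>
    dplyr::group_by(.data$position) |>
    dplyr::mutate(ref_cycle = .data$cycle[reference_cycle(.data$t_min, t_ref)],
                  ref_biovolume = .data$biovolume_um3[.data$cycle == .data$ref_cycle[1]][1],
                  vnorm = .data$biovolume_um3 / .data$ref_biovolume) |>
    dplyr::ungroup()
  bad <- out |> dplyr::filter(.data$ref_biovolume == 0) |>
    dplyr::distinct(.data$position)
  if (nrow(bad) > 0) {
    abort(paste0("zero reference biovolume at position(s): ",
                 paste(bad$position, collapse = ", ")),
          class = "bff_normalization_error")
  }
  out
}

#' Number of initially attached clusters
#'
#' The cluster count at the reference cycle (default 2 h), one row per
#' position.
#'
#' @inheritParams normalize_series
#' @return Tibble `position`, `n_initial`.
#' @export
initial_cluster_count <- function(series, t_ref = 120) {
  series |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(
      n_initial = .data$n_clusters[reference_cycle(.data$t_min, t_ref)],
      .groups = "drop")
}

#' Cluster size distribution
#'
#' Sorts cluster biovolumes in ascending order against their rank, the
#' representation used for per-cycle cluster-size distribution plots.
#'
#' @param clusters Cluster tibble or numeric vector of biovolumes.
#' @return Tibble `rank`, `volume_um3` (stable ascending sort).
#' @export
size_distribution <- function(clusters) {
  v <- if (is.data.frame(clusters)) clusters$volume_um3 else clusters
  v <- sort(v, method = "radix") # stable
  tibble(rank = seq_along(v), volume_um3 = v)
}

#' Equivalent sphere diameter of a biovolume
#'
#' `D = (6 V / pi)^(1/3)`: the diameter of a sphere with the cluster's
#' biovolume, used as the bubble diameter in spatial cluster maps.
#'
#' @param v Biovolumes in um^3 (>= 0).
#' @return Diameters in um.
#' @examples
#' equivalent_diameter(pi / 6) # exactly 1
#' @export
equivalent_diameter <- function(v) {
  if (any(v < 0)) abort("biovolume must be >= 0", class = "bff_domain_error")
  (6 * v / pi)^(1 / 3)
}

#' Bubble-plot records for a cluster table
#'
#' One bubble per cluster: its centroid in the imaging plane and equivalent
#' sphere diameter.
#'
#' @param clusters Cluster tibble with `volume_um3`, `x_um`, `y_um`.
#' @return Tibble `id`, `x_um`, `y_um`, `d_um`.
#' @export
bubble_data <- function(clusters) {
  clusters |>
    dplyr::transmute(id = .data$id, x_um = .data$x_um, y_um = .data$y_um,
                     d_um = equivalent_diameter(.data$volume_um3))
}
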