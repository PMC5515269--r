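# Imaging layout: positions, window geometry and the cycle clock.

# per-flow-rate acquisition table: z-slice count and number of 10-min cycles
flow_rate_table <- function() {
  tibble(flow_rate = c("0.1", "0.5", "1.5", "4.0"),
         z_slices  = c(12L, 14L, 14L, 16L),
         n_cycles  = c(47L, 62L, 60L, 73L))
}

#' Imaging layout of a flow-cell experiment
#'
#' Describes the grid of confocal imaging windows: 12 axial locations along
#' the channel (position 12 nearest the outlet) times 3 lateral replicate
#' areas (`a`, `b`, `c`), a square window of 212.55 um sampled at 0.42 um
#' in-plane (506 px) and 0.78 um z-steps, and an imaging cycle every 10 min
#' starting at `t_first` minutes. The z-slice count and number of cycles
#' default to the acquisition settings of the selected flow rate
#' (12/14/14/16 slices and 47/62/60/73 cycles for 0.1/0.5/1.5/4.0 ml/h).
#'
#' @param flow_rate One of `"0.1"`, `"0.5"`, `"1.5"`, `"4.0"` (ml/h per inlet).
#' @param n_x Number of axial imaging locations (default 12).
#' @param areas Lateral replicate area labels (default `c("a","b","c")`).
#' @param window_px In-plane pixel count; default `round(212.55 / 0.42) = 506`.
#'   Pass a smaller value (e.g. 128) for reduced windows in simulations.
#' @param voxel_xy,voxel_z Voxel dimensions in um.
#' @param z_slices,n_cycles Overrides for the per-flow-rate defaults.
#' @param cycle_interval Minutes between imaging cycles (default 10).
#' @param t_first Time of the first imaging cycle in minutes (default 40;
#'   with 47 cycles this spans 8 h 20 min at 0.1 ml/h).
#'
#' @return A list of class `imaging_layout`: window geometry, cycle clock and
#'   a `positions` tibble (`position` label such as `"07a"`, `x_index`, `area`).
#' @export
imaging_layout <- function(flow_rate = "0.1", n_x = 12L,
                           areas = c("a", "b", "c"),
                           window_px = 506L, voxel_xy = 0.42, voxel_z = 0.78,
                           z_slices = NULL, n_cycles = NULL,
                           cycle_interval = 10, t_first = 40) {
  flow_rate <- match.arg(as.character(flow_rate), flow_rate_table()$flow_rate)
  defaults <- flow_rate_table() |> dplyr::filter(.data$flow_rate == !!flow_rate)
  z_slices <- if (is.null(z_slices)) defaults$z_slices else as.integer(z_slices)
  n_cycles <- if (is.null(n_cycles)) defaults$n_cycles else as.integer(n_cycles)
  check_positive(voxel_xy, "voxel_xy"); check_positive(voxel_z, "voxel_z")
  check_positive(cycle_interval, "cycle_interval")
  stopifnot(n_x >= 1, window_px >= 8, z_slices >= 1, n_cycles >= 1)

  positions <- tidyr::expand_grid(x_index = seq_len(n_x), area = areas) |>
    dplyr::mutate(position = sprintf("%02d%s", .data$x_index, .data$area)) |>
    dplyr::select("position", "x_index", "area")

  structure(list(
    flow_rate = flow_rate,
    positions = positions,
    window_px = as.integer(window_px),
    window_um = window_px * voxel_xy,
    voxel_dims = c(voxel_xy, voxel_xy, voxel_z),
    z_slices = z_slices,
    n_cycles = n_cycles,
    cycle_interval = cycle_interval,
    t_first = t_first
  ), class = "imaging_layout")
}

#' Convert between imaging cycle index and experiment time
#'
#' The cycle clock is `t(n) = t_first + (n - 1) * interval` minutes; the two
#' functions are exact inverses on the cycle lattice.
#'
#' @param n Cycle index (>= 1).
#' @param t Time in minutes (>= `t_first`).
#' @param layout An `imaging_layout` (or any list with `t_first` and
#'   `cycle_interval`).
#' @return `cycle_to_time()` gives minutes; `time_to_cycle()` the nearest
#'   cycle index.
#' @export
cycle_to_time <- function(n, layout) {
  if (any(n < 1)) abort("cycle index must be >= 1", class = "bff_range_error")
  layout$t_first + (n - 1) * layout$cycle_interval
}

#' @rdname cycle_to_time
#' @export
time_to_cycle <- function(t, layout) {
  if (any(t < layout$t_first - layout$cycle_interval / 2)) {
    abort("time before the first imaging cycle", class = "bff_range_error")
  }
  as.integer(round((t - layout$t_first) / layout$cycle_interval)) + 1L
}

# times of all cycles in a layout
cycle_times <- function(layout) cycle_to_time(seq_len(layout$n_cycles), layout)
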