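# Shared fixtures for the synthetic-imaging and pipeline tests.

# reduced layout used throughout: same voxels and clock as the experiment,
# smaller field of view and shortened series
tiny_layout <- function(window_px = 64L, n_cycles = 10L, areas = "a",
                        n_x = 12L, flow_rate = "0.1") {
  imaging_layout(flow_rate, n_x = n_x, areas = areas,
                 window_px = window_px, n_cycles = n_cycles)
}

# deterministic, clean generator settings: one effective noise-free channel
clean_params <- function(...) {
  synthetic_params("0.1", noise = FALSE, blur = FALSE, ...)
}

# quantification series straight from generator truth (no imaging), for
# kinetics tests that need exact exponential input
truth_series <- function(sim, layout, position = "01a") {
  sim$truth |>
    dplyr::transmute(position = position, cycle = .data$cycle,
                     t_min = .data$t_min, n_clusters = .data$n_true,
                     biovolume_um3 = .data$v_total_true)
}
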