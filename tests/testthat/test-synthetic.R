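test_that("without shedding or dispersal the truth is a pure exponential", {
  set.seed(10)
  layout <- tiny_layout(n_cycles = 20L)
  params <- clean_params(detachment_rate = 0, doubling_time = 47,
                         dispersal_onset_t12 = 1e6)
  sim <- evolve_clusters(params, layout, x_index = 5)
  tr <- sim$truth
  v0 <- tr$v_total_true[1] / exp(log(2) / 47 * tr$t_min[1])
  expect_equal(tr$v_total_true, v0 * exp(log(2) / 47 * tr$t_min),
               tolerance = 1e-12)
  # volume doubles every 47 min: consecutive 10-min cycles grow by 2^(10/47)
  expect_equal(tr$v_total_true[-1] / tr$v_total_true[-nrow(tr)],
               rep(2^(10 / 47), nrow(tr) - 1), tolerance = 1e-12)
  expect_equal(tr$n_true, rep(nrow(sim$registry), 20L))
})

test_that("dispersal starts downstream and the onset wave needs 63 min to reach position 1", {
  params <- clean_params() # low flow: onset 370 min at position 12
  onsets <- vapply(1:12, function(x) biofilmflow:::position_onset(params, x),
                   numeric(1))
  expect_equal(onsets[12], 370)
  expect_equal(onsets[1] - onsets[12], 63)
  expect_true(all(diff(onsets) <= 0)) # non-increasing from position 1 to 12

  # truth biovolume decays after the position onset
  set.seed(21)
  layout <- tiny_layout(n_cycles = 44L)
  sim <- evolve_clusters(params, layout, x_index = 12)
  tr <- sim$truth
  before <- tr$v_total_true[tr$t_min <= 370]
  after <- tr$v_total_true[tr$t_min > 370]
  expect_true(all(diff(before) > 0))
  expect_true(all(diff(after) < 0))
})

test_that("rendering reproduces geometry: empty scenes, sphere volumes, thresholds", {
  layout <- tiny_layout(window_px = 48L, n_cycles = 1L)
  params <- clean_params()

  # no clusters, no noise: a uniform background grid
  empty <- render_stack(tibble::tibble(x_um = numeric(), y_um = numeric(),
                                       z_um = numeric(), r_um = numeric()),
                        layout, params)
  expect_true(all(empty == params$background_intensity))

  # one 3-um sphere: segmented biovolume within 10% of (4/3) pi 27
  sph <- tibble::tibble(x_um = 10, y_um = 10, z_um = 4.5, r_um = 3)
  stack <- render_stack(sph, layout, params)
  seg <- segment_stack(stack, voxel_dims = layout$voxel_dims)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$volume_um3, 4 / 3 * pi * 27, tolerance = 0.1)
  # centroid recovered at the sphere centre to sub-voxel accuracy
  expect_equal(seg$x_um, 10, tolerance = 0.42)
  expect_equal(seg$y_um, 10, tolerance = 0.42)

  # by construction, interior voxels all exceed the absolute threshold
  bright <- synthetic_params("0.1", cell_intensity = 100,
                             background_intensity = 2,
                             noise = FALSE, blur = FALSE)
  stack100 <- render_stack(sph, layout, bright)
  expect_true(all(stack100[stack100 > 2] == 100))
  expect_gte(min(stack100[stack100 > 2]), 10)
})

test_that("simulation is deterministic and follows the stack manifest contract", {
  layout <- tiny_layout(window_px = 32L, n_cycles = 3L, n_x = 2L)
  params <- synthetic_params("0.1")

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- simulate_experiment(params, layout, d1, seed = 99)
  m2 <- simulate_experiment(params, layout, d2, seed = 99)
  expect_equal(nrow(m1), 2 * 3)
  expect_true(all(file.exists(m1$path)))
  expect_identical(unname(tools::md5sum(m1$path)),
                   unname(tools::md5sum(m2$path)))
  expect_true(file.exists(file.path(d1, "truth.json")))

  # a second run into the same directory refuses to clobber files
  expect_error(simulate_experiment(params, layout, d1, seed = 99),
               class = "bff_io_error")

  # the full default experiment at the lowest flow rate plans 36 x 47 stacks
  full <- imaging_layout("0.1")
  expect_equal(nrow(stack_manifest(full)), 1692L)
  expect_equal(full$window_px, 506L)
  expect_match(stack_manifest(full)$filename[1], "^pos01a_cycle001\\.tif$")
})

test_that("written stacks read back and segment like in-memory ones", {
  set.seed(55)
  layout <- tiny_layout(window_px = 48L, n_cycles = 2L, n_x = 1L)
  params <- synthetic_params("0.1")
  dir <- withr::local_tempdir()
  simulate_experiment(params, layout, dir, seed = 7)

  set.seed(7)
  sim <- evolve_clusters(params, layout, 1)
  sph <- dplyr::filter(sim$spheres, cycle == 1)
  in_mem <- render_stack(sph, layout, params)
  on_disk <- read_stack(file.path(dir, "pos01a_cycle001.tif"))
  expect_identical(dim(on_disk), dim(in_mem))
  expect_identical(as.vector(on_disk), as.vector(in_mem))
})

test_that("invalid generator parameters are rejected", {
  expect_error(synthetic_params(growth_rate = -1),
               class = "bff_invalid_parameter")
  expect_error(synthetic_params(doubling_time = 47, growth_rate = 0.01),
               class = "bff_invalid_parameter")
  expect_error(synthetic_params(cell_intensity = 12, read_noise_sd = 2),
               class = "bff_invalid_parameter")
  expect_error(synthetic_params(detachment_rate = -0.1),
               class = "bff_invalid_parameter")
})

test_that("one hour in, attached clusters are still small; dispersal brings a count surge", {
  set.seed(31)
  layout <- tiny_layout(window_px = 128L, n_cycles = 44L)
  params <- clean_params()
  sim <- evolve_clusters(params, layout, x_index = 12)

  # early attachment stage: every cluster below 25 um^3
  early <- dplyr::filter(sim$spheres, t_min == 60)
  expect_true(all(early$v_true < 25))

  # at dispersal commencement the cluster count rises while the largest
  # cluster shrinks (break-up into drifting single cells)
  tr <- sim$truth
  peak <- which.max(tr$v_total_true)
  expect_gt(max(tr$n_true[(peak + 1):(peak + 3)]), tr$n_true[peak])
  by_cycle <- dplyr::summarise(dplyr::group_by(sim$spheres, cycle),
                               vmax = max(v_true))
  expect_lt(by_cycle$vmax[peak + 2], by_cycle$vmax[peak])
})

test_that("the initial attached cluster count is recovered at the 2-h reference", {
  set.seed(12)
  # full-size window so the surface density matches the Poisson mean of 30
  layout <- imaging_layout("0.1", areas = "a", n_cycles = 9L)
  params <- synthetic_params("0.1")
  sim <- evolve_clusters(params, layout, x_index = 3)
  sph <- dplyr::filter(sim$spheres, cycle == 9)
  stack <- render_stack(sph, layout, params)
  clusters <- segment_stack(stack, voxel_dims = layout$voxel_dims) |>
    dplyr::mutate(position = "03a", cycle = 9L)
  series <- quantify_series(clusters, layout)
  n_ap <- initial_cluster_count(series, t_ref = 120)$n_initial
  # within the 99% Poisson band of the seeding intensity
  expect_gte(n_ap, qpois(0.005, 30))
  expect_lte(n_ap, qpois(0.995, 30))
})
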