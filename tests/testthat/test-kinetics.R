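make_series <- function(t, v, position = "01a") {
  tibble::tibble(position = position, cycle = seq_along(t), t_min = t,
                 n_clusters = 1L, biovolume_um3 = v)
}

test_that("exact exponentials are fitted to machine precision at any sampling", {
  for (dt in c(5, 10, 25)) {
    t <- seq(0, 300, by = dt)
    fit <- fit_growth(make_series(t, 5 * exp(0.01 * t)))
    expect_equal(fit$g, 0.01, tolerance = 1e-12)
    expect_equal(fit$doubling_time, log(2) / 0.01, tolerance = 1e-12)
    expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)
  }
  # consistency of the doubling-time identity
  expect_equal(doubling_time(log(2)), 1.0)
  expect_equal(doubling_time(0.01), 69.31472, tolerance = 1e-6)
  expect_equal(doubling_time(0.014748), 47.0, tolerance = 1e-4)
  expect_error(doubling_time(0), class = "bff_domain_error")
  expect_error(doubling_time(-0.1), class = "bff_domain_error")
})

test_that("growth fits exclude zero cycles, stop at the peak and expose tidiers", {
  t <- seq(40, 200, by = 10)
  v <- 5 * exp(0.012 * t)
  v[3] <- 0                       # a dropped frame
  v[length(v)] <- v[length(v)] / 2 # decline after the peak is excluded
  fit <- fit_growth(make_series(t, v))
  expect_equal(fit$g, 0.012, tolerance = 1e-9)
  expect_equal(fit$n_used, length(t) - 2)

  td <- tidy(fit)
  expect_equal(td$term, c("log_v0", "g"))
  expect_equal(td$estimate[2], fit$g)
  gl <- glance(fit)
  expect_equal(gl$doubling_time, fit$doubling_time)
  expect_false(gl$non_growing)

  expect_error(fit_growth(make_series(c(40, 50, 60), c(0, 0, 1))),
               class = "bff_insufficient_data")
})

test_that("dispersal onset is the first decrease after the highest peak", {
  t <- seq(40, 100, by = 10)
  v <- c(0.5, 1, 2, 4, 3, 1, 0.2)
  out <- detect_dispersal_onset(make_series(t, v))
  expect_equal(out$onset_cycle, 5L)   # the cycle holding value 3
  expect_equal(out$t_disp, 80)
  expect_equal(out$peak_cycle, 4L)
  expect_gt(out$t_disp, out$t_peak)   # onset strictly after the peak

  # strictly increasing series: no onset, not an error
  inc <- detect_dispersal_onset(make_series(t, seq(1, 4, length.out = 7)))
  expect_true(is.na(inc$t_disp))

  # ties among equal maxima resolve to the earliest maximum
  tie <- detect_dispersal_onset(make_series(t, c(1, 5, 5, 5, 2, 1, 1)))
  expect_equal(tie$peak_cycle, 2L)
  expect_equal(tie$onset_cycle, 5L)

  # a transient dip before the true maximum is not an onset
  dip <- detect_dispersal_onset(make_series(t, c(1, 3, 2, 6, 8, 5, 1)))
  expect_equal(dip$peak_cycle, 5L)
  expect_equal(dip$onset_cycle, 6L)
})

test_that("time-shift equivariance: shifting the clock moves the onset, not the kinetics", {
  t <- seq(40, 400, by = 10)
  v <- ifelse(t <= 300, 2 * exp(0.011 * t), 2 * exp(0.011 * 300) * 0.5^((t - 300) / 20))
  base_fit <- fit_growth(make_series(t, v))
  base_onset <- detect_dispersal_onset(make_series(t, v))
  shift <- 170
  shifted_fit <- fit_growth(make_series(t + shift, v * exp(-0.011 * shift)))
  shifted_onset <- detect_dispersal_onset(make_series(t + shift, v))
  expect_equal(shifted_onset$t_disp, base_onset$t_disp + shift)
  expect_equal(shifted_fit$g, base_fit$g, tolerance = 1e-9)
  expect_equal(shifted_fit$doubling_time, base_fit$doubling_time,
               tolerance = 1e-9)
})

test_that("replicate areas aggregate with the sample standard deviation", {
  out <- aggregate_over_areas(c(364, 370, 376))
  expect_equal(out$mean, 370)
  expect_equal(out$sd, 6.0)
  expect_equal(aggregate_over_areas(c(370, 370, 370))$sd, 0)
  expect_warning(single <- aggregate_over_areas(42), "1 value")
  expect_true(is.na(single$sd))
  expect_error(suppressWarnings(aggregate_over_areas(numeric(0))),
               class = "bff_insufficient_data")
})

test_that("propagation statistic is the upstream-downstream onset difference", {
  by_loc <- tibble::tibble(x_index = 1:12,
                           t_disp_mean = seq(433, 370, length.out = 12))
  expect_equal(propagation_stat(by_loc), 63)
  flat <- tibble::tibble(x_index = 1:12, t_disp_mean = 400)
  expect_equal(propagation_stat(flat), 0)
  missing <- tibble::tibble(x_index = 1:12,
                            t_disp_mean = c(NA, rep(400, 11)))
  expect_error(propagation_stat(missing), class = "bff_insufficient_data")
})

test_that("reproducibility rows reproduce between-run statistics", {
  row <- reproducibility_table(run1 = list(mean = 370, sd = 6),
                               run2 = list(mean = 387, sd = 0),
                               flow_rate = "0.1") |>
    format_reproducibility_table()
  expect_equal(row$delta12, 17)
  expect_equal(row$delta12_pct, 4.6)
  expect_equal(row$t1_cv_pct, 1.6)
  expect_equal(row$t2_cv_pct, 0.0)

  row2 <- reproducibility_table(list(mean = 472, sd = 6),
                                list(mean = 468, sd = 0)) |>
    format_reproducibility_table()
  expect_equal(row2$t1_cv_pct, 1.3)
  expect_equal(row2$delta12, 4)
  expect_equal(row2$delta12_pct, 0.8)

  # identical runs
  same <- format_reproducibility_table(
    reproducibility_table(list(mean = 400, sd = 2), list(mean = 400, sd = 2)))
  expect_equal(same$delta12, 0)
  expect_equal(same$delta12_pct, 0.0)

  # single-run input (the highest flow rate): between-run fields stay empty
  solo <- reproducibility_table(list(mean = 539, sd = 10))
  expect_true(is.na(solo$delta12))
  expect_true(is.na(solo$t2_mean))

  # raw area onsets are accepted directly
  raw <- reproducibility_table(c(364, 370, 376), c(387, 387, 387))
  expect_equal(raw$t1_mean, 370)
  expect_equal(raw$t1_sd, 6)
  expect_equal(raw$delta12, 17)
})
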