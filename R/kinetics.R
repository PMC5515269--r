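# Growth and dispersal kinetics: exponential fits, doubling times,
# dispersal-onset detection, spatial propagation and reproducibility.

#' Fit exponential growth to one biovolume series
#'
#' Assumes `V(t) = V0 exp(g t)` during build-up and estimates `g` by ordinary
#' least squares on `log V` versus time over the cycles from the start of the
#' experiment up to and including the cycle of maximal biovolume
#' (zero-biovolume cycles are excluded from the fit). The doubling time is
#' `ln 2 / g`.
#'
#' @param series Tibble for a single position with columns `t_min` and
#'   `biovolume_um3` (and optionally `cycle`).
#' @return An object of class `growth_fit` with fields `g` (1/min),
#'   `doubling_time` (min), `n_pmax`, `t_peak`, `v_max`, `v0`, `r_squared`
#'   (log space), `n_used` and `non_growing`. Use [tidy()] / [glance()] for
#'   tibble views.
#' @export
fit_growth <- function(series) {
  if (is.data.frame(series) && "position" %in% names(series) &&
      dplyr::n_distinct(series$position) > 1) {
    abort("`series` holds several positions; use fit_growth_by_position()",
          class = "bff_input_error")
  }
  v <- series$biovolume_um3
  t <- series$t_min
  n_pmax <- which(v == max(v))[1]
  use <- seq_len(n_pmax)
  use <- use[v[use] > 0]
  if (length(use) < 3) {
    abort("need at least 3 positive-biovolume cycles up to the peak",
          class = "bff_insufficient_data")
  }
  fit <- lm(log(v[use]) ~ t[use])
  # summary() warns on exactly exponential input; that case is legitimate here
  fit_summary <- suppressWarnings(summary(fit))
  g <- unname(coef(fit)[2])
  non_growing <- !is.finite(g) || g <= 0
  structure(list(
    g = g,
    doubling_time = if (non_growing) NA_real_ else log(2) / g,
    n_pmax = n_pmax,
    t_peak = t[n_pmax],
    v_max = v[n_pmax],
    v0 = unname(exp(coef(fit)[1])),
    r_squared = fit_summary$r.squared,
    n_used = length(use),
    non_growing = non_growing,
    lm_fit = fit,
    data = tibble(t_min = t, biovolume_um3 = v,
                  used = seq_along(v) %in% use)
  ), class = "growth_fit")
}

#' @exportS3Method base::print
print.growth_fit <- function(x, ...) {
  cat("Exponential growth fit\n")
  cat(sprintf("  g = %.5f /min, doubling time = %.2f min\n", x$g,
              x$doubling_time))
  cat(sprintf("  peak V = %.1f um^3 at cycle %d (t = %g min); R^2(log) = %.4f on %d cycles\n",
              x$v_max, x$n_pmax, x$t_peak, x$r_squared, x$n_used))
  invisible(x)
}

#' @rdname fit_growth
#' @param x,object A `growth_fit`.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$lm_fit))$coefficients
  tibble(term = c("log_v0", "g"),
         estimate = unname(s[, 1]),
         std.error = unname(s[, 2]),
         statistic = unname(s[, 3]),
         p.value = unname(s[, 4]))
}

#' @rdname fit_growth
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(g = x$g, doubling_time = x$doubling_time, r.squared = x$r_squared,
         v0 = x$v0, v_max = x$v_max, n_pmax = x$n_pmax, t_peak = x$t_peak,
         n_used = x$n_used, non_growing = x$non_growing)
}

#' Growth fits for every position of a series table
#'
#' @param series Tibble from [quantify_series()] with many positions.
#' @return One [glance()] row per position.
#' @export
fit_growth_by_position <- function(series) {
  series |>
    dplyr::group_by(.data$position) |>
    dplyr::group_modify(~ glance(fit_growth(.x))) |>
    dplyr::ungroup()
}

#' Doubling time from a growth rate
#'
#' @param g Growth rate in 1/min (> 0).
#' @return `ln 2 / g` in minutes.
#' @examples
#' doubling_time(log(2)) # 1 minute
#' @export
doubling_time <- function(g) {
  if (any(!is.finite(g) | g <= 0)) {
    abort("growth rate must be positive", class = "bff_domain_error")
  }
  log(2) / g
}

#' Detect the onset of biofilm dispersal
#'
#' The onset is identified from the decrease of (normalised) biovolume
#' immediately after the highest peak: the first cycle after the global
#' maximum at which the value drops below the maximum (ties between equal
#' maxima resolve to the earliest one). A series that never decreases after
#' its peak yields a no-onset row (`NA` times) rather than an error.
#'
#' @param series Tibble for a single position with `t_min` and a value
#'   column.
#' @param value Column used for detection (default `vnorm`, falling back to
#'   `biovolume_um3`; the two are equivalent under positive normalisation).
#' @return One-row tibble: `peak_cycle`, `t_peak`, `v_peak`, `onset_cycle`,
#'   `t_disp` (`NA` if no onset).
#' @export
detect_dispersal_onset <- function(series, value = NULL) {
  if (is.null(value)) {
    value <- if ("vnorm" %in% names(series)) "vnorm" else "biovolume_um3"
  }
  v <- series[[value]]
  t <- series$t_min
  peak <- which(v == max(v))[1]
  after <- which(seq_along(v) > peak & v < v[peak])
  onset <- if (length(after)) after[1] else NA_integer_
  tibble(peak_cycle = peak, t_peak = t[peak], v_peak = v[peak],
         onset_cycle = onset,
         t_disp = if (is.na(onset)) NA_real_ else t[onset])
}

#' Dispersal onsets for every position of a series table
#'
#' @inheritParams detect_dispersal_onset
#' @return One row per position.
#' @export
detect_dispersal_by_position <- function(series, value = NULL) {
  series |>
    dplyr::group_by(.data$position) |>
    dplyr::group_modify(~ detect_dispersal_onset(.x, value = value)) |>
    dplyr::ungroup()
}

#' Mean and standard deviation over replicate areas
#'
#' Aggregates the three lateral replicate areas (a-c) of one axial location;
#' the spread is the sample standard deviation (n - 1 denominator). Fewer
#' than three values are accepted with a warning; a singleton yields an `NA`
#' standard deviation.
#'
#' @param values Numeric vector (normally length 3).
#' @return One-row tibble `mean`, `sd`, `n`.
#' @export
aggregate_over_areas <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort("no values to aggregate", class = "bff_insufficient_data")
  }
  if (length(values) != 3) {
    warn(sprintf("aggregating %d value(s) instead of 3 replicate areas",
                 length(values)))
  }
  tibble(mean = mean(values), sd = sd(values), n = length(values))
}

#' Per-location aggregates of onset, peak biovolume and doubling time
#'
#' Joins growth fits and dispersal onsets, then aggregates areas a-c at each
#' axial location into mean +- SD of the dispersal time, maximal biovolume,
#' doubling time and initial cluster count.
#'
#' @param series Normalised series tibble ([normalize_series()]).
#' @param layout The [imaging_layout()] (to map positions to locations).
#' @param t_ref Reference time for the initial cluster count, minutes.
#' @return Tibble with one row per `x_index`.
#' @export
summarize_by_location <- function(series, layout, t_ref = 120) {
  pos <- layout$positions
  fits <- fit_growth_by_position(series)
  onsets <- detect_dispersal_by_position(series)
  n0 <- initial_cluster_count(series, t_ref)
  series |>
    dplyr::distinct(.data$position) |>
    dplyr::left_join(pos, by = "position") |>
    dplyr::left_join(fits, by = "position") |>
    dplyr::left_join(onsets, by = "position") |>
    dplyr::left_join(n0, by = "position") |>
    dplyr::group_by(.data$x_index) |>
    dplyr::summarise(
      n_areas = dplyr::n(),
      t_disp_mean = mean(.data$t_disp), t_disp_sd = sd(.data$t_disp),
      v_max_mean = mean(.data$v_max), v_max_sd = sd(.data$v_max),
      t_d_mean = mean(.data$doubling_time), t_d_sd = sd(.data$doubling_time),
      n_initial_mean = mean(.data$n_initial),
      .groups = "drop")
}

#' Upstream-downstream dispersal propagation time
#'
#' The difference between the mean dispersal onset at the most upstream
#' location (position 1) and the most downstream one (position 12); positive
#' under downstream-first dispersal.
#'
#' @param by_location Tibble from [summarize_by_location()] (needs `x_index`
#'   and `t_disp_mean`).
#' @return Delta t in minutes.
#' @export
propagation_stat <- function(by_location) {
  up <- by_location$t_disp_mean[by_location$x_index == min(by_location$x_index)]
  dn <- by_location$t_disp_mean[by_location$x_index == max(by_location$x_index)]
  if (length(up) != 1 || length(dn) != 1 || is.na(up) || is.na(dn)) {
    abort("mean onset missing at an endpoint location",
          class = "bff_insufficient_data")
  }
  up - dn
}

# accept a numeric vector of area onsets, or a list/one-row frame with
# mean and sd fields
as_run_summary <- function(run) {
  if (is.null(run)) return(tibble(mean = NA_real_, sd = NA_real_, n = NA_integer_))
  if (is.numeric(run) && length(run) > 1) return(aggregate_over_areas(run))
  if (is.numeric(run) && length(run) == 1) {
    return(tibble(mean = unname(run), sd = NA_real_, n = 1L))
  }
  run <- as.list(run)
  nm <- names(run)
  mean_val <- run[[intersect(c("mean", "t_mean"), nm)[1]]]
  sd_val <- run[[intersect(c("sd", "t_sd"), nm)[1]]]
  tibble(mean = as.numeric(mean_val), sd = as.numeric(sd_val), n = 3L)
}

#' Between-run reproducibility of the dispersal time at position 12
#'
#' For two independent runs at the same flow rate, summarises the dispersal
#' times at the three downstream areas 12 a-c: mean +- SD per run, the
#' coefficient of variation in percent, the absolute between-run difference
#' `delta12 = |mean2 - mean1|` and its percentage of the run-1 mean. Full
#' precision is retained; apply [format_reproducibility_table()] for
#' report-style rounding (times to whole minutes, percentages to one
#' decimal).
#'
#' @param run1,run2 Either a numeric vector of the three area onset times
#'   (min), or a list/one-row data frame with `mean` and `sd`. `run2 = NULL`
#'   (single run) leaves the between-run fields `NA`.
#' @param flow_rate Optional label for the output row.
#' @return One-row tibble: `flow_rate`, `t1_mean`, `t1_sd`, `t1_cv_pct`,
#'   `t2_mean`, `t2_sd`, `t2_cv_pct`, `delta12`, `delta12_pct`.
#' @export
reproducibility_table <- function(run1, run2 = NULL, flow_rate = NA_character_) {
  s1 <- as_run_summary(run1)
  s2 <- as_run_summary(run2)
  tibble(
    flow_rate = flow_rate,
    t1_mean = s1$mean, t1_sd = s1$sd,
    t1_cv_pct = 100 * s1$sd / s1$mean,
    t2_mean = s2$mean, t2_sd = s2$sd,
    t2_cv_pct = 100 * s2$sd / s2$mean,
    delta12 = abs(s2$mean - s1$mean),
    delta12_pct = 100 * abs(s2$mean - s1$mean) / s1$mean
  )
}

#' @rdname reproducibility_table
#' @param tbl A tibble from [reproducibility_table()].
#' @export
format_reproducibility_table <- function(tbl) {
  tbl |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c("t1_mean", "t1_sd", "t2_mean",
                                                "t2_sd", "delta12")), round),
                  dplyr::across(dplyr::ends_with("_pct"), ~ round(.x, 1)))
}
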