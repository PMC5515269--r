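#' Design a hyperbolic channel width profile with a linear velocity ramp
#'
#' At constant volumetric flux `Q` and constant depth `h`, the depth-averaged
#' centerline speed of a shallow channel is `v(x) = Q / (h w(x))`. A width
#' profile that is the reciprocal of a linear function of `x` (a hyperbola)
#' therefore produces a linearly decreasing centerline velocity along the
#' expansion. The channel runs from the inlet junction at `x = 0` towards
#' negative `x`; the expansion spans `[x_start, x_end]` (both negative,
#' `x_end < x_start`), with straight segments of the bounding widths before
#' and after it.
#'
#' @param q_per_inlet Volumetric flow per inlet in ml/h (two inlets feed the
#'   channel, so the channel carries `2 * q_per_inlet`).
#' @param velocity_ratio Ratio `v(x_start) / v(x_end)` across the expansion
#'   (>= 1); the width grows by the same factor.
#' @param depth Channel depth in mm.
#' @param x_start,x_end Axial coordinates (mm) bounding the expansion;
#'   `x_end < x_start < 0`.
#' @param w_start Channel width (mm) upstream of the expansion. The absolute
#'   width is a free design parameter; only ratios along the profile are
#'   constrained by the velocity ramp.
#' @param outlet_length Length (mm) of the channel kept after the expansion
#'   exit.
#' @param exit_fillet Length (mm) over which the width slope is blended to
#'   zero downstream of `x_end`. A machined channel has no sharp slope
#'   discontinuity, and a kink in `w(x)` creates a corner singularity in the
#'   potential model that contaminates the centerline speed at the expansion
#'   exit; the fillet lies entirely downstream of `x_end`, so the designed
#'   ramp is untouched. Set 0 for a hard kink.
#' @param n_samples Number of sample points stored in the profile table.
#'
#' @return A tibble of class `channel_geometry` with columns `x` (mm,
#'   decreasing downstream), `w` (mm) and `v` (mm/s, centerline), carrying the
#'   exact width/velocity functions and the flow parameters as attributes.
#' @examples
#' geom <- design_width_profile(q_per_inlet = 0.1, velocity_ratio = 3)
#' centerline_velocity(geom, c(-1.49, -8.99))
#' @export
design_width_profile <- function(q_per_inlet = 0.1, velocity_ratio = 3,
                                 depth = 0.98, x_start = -1.49, x_end = -8.99,
                                 w_start = 0.5, outlet_length = 1.5,
                                 exit_fillet = 0.75, n_samples = 151) {
  check_positive(q_per_inlet, "q_per_inlet")
  check_positive(depth, "depth")
  check_positive(w_start, "w_start")
  check_positive(outlet_length, "outlet_length")
  if (!is.numeric(velocity_ratio) || length(velocity_ratio) != 1L ||
      velocity_ratio < 1) {
    abort("`velocity_ratio` must be a single number >= 1",
          class = "bff_invalid_parameter")
  }
  if (!(x_end < x_start && x_start < 0)) {
    abort("expansion must satisfy x_end < x_start < 0",
          class = "bff_invalid_parameter")
  }

  if (exit_fillet < 0 || exit_fillet >= outlet_length) {
    abort("`exit_fillet` must be in [0, outlet_length)",
          class = "bff_invalid_parameter")
  }
  q_total <- ml_h_to_mm3_s(2 * q_per_inlet)
  span <- x_end - x_start
  shrink <- 1 - 1 / velocity_ratio # fractional velocity drop across expansion
  w_end <- w_start * velocity_ratio
  # downstream width slope dw/ds at the expansion exit (s = -x)
  slope_end <- w_start * shrink * velocity_ratio^2 / abs(span)

  w_fun <- function(x) {
    xi <- pmin(pmax((x - x_start) / span, 0), 1)
    w <- w_start / (1 - shrink * xi)
    past <- x < x_end # downstream of the expansion exit
    if (any(past) && exit_fillet > 0) {
      s_past <- pmin(x_end - x[past], exit_fillet)
      w[past] <- w_end + slope_end * (s_past - s_past^2 / (2 * exit_fillet))
    }
    w
  }

  xs <- sort(unique(c(seq(0, x_end - outlet_length, length.out = n_samples),
                      x_start, x_end)), decreasing = TRUE)
  out <- tibble(x = xs, w = w_fun(xs), v = q_total / (depth * w_fun(xs)))
  structure(out,
            class = c("channel_geometry", class(out)),
            q_total = q_total, depth = depth,
            x_start = x_start, x_end = x_end,
            velocity_ratio = velocity_ratio, w_start = w_start,
            w_fun = w_fun)
}

# width at axial position x; exact for designed geometries, piecewise-linear
# interpolation of the sampled profile otherwise
channel_width <- function(geom, x) {
  rng <- range(geom$x)
  if (any(x < rng[1] - 1e-9 | x > rng[2] + 1e-9)) {
    abort("`x` outside the sampled channel profile", class = "bff_range_error")
  }
  w_fun <- attr(geom, "w_fun")
  if (is.function(w_fun)) w_fun(x) else approx(geom$x, geom$w, xout = x)$y
}

#' Centerline velocity from one-dimensional mass conservation
#'
#' `v(x) = Q_total / (w(x) h)`: the depth-averaged centerline speed implied by
#' flux conservation through the local cross-section. For a designed
#' [design_width_profile()] geometry this is exactly (piecewise) linear in `x`
#' within the expansion.
#'
#' @param geom A `channel_geometry`.
#' @param x Axial positions (mm) within the sampled profile range.
#' @return Speeds in mm/s.
#' @export
centerline_velocity <- function(geom, x) {
  attr(geom, "q_total") / (attr(geom, "depth") * channel_width(geom, x))
}

#' Depth-averaged (Hele-Shaw) solve of the channel flow field
#'
#' Solves the two-dimensional potential-flow problem for the depth-averaged
#' velocity in a shallow channel: `div(grad phi) = 0` on a regular Cartesian
#' grid masked to the channel planform, with a uniform prescribed influx
#' `Q_total` at the inlet boundary, zero potential at the outlet face, and
#' no-flux walls. In the Hele-Shaw regime (depth much smaller than width, low
#' Reynolds number) the in-plane velocity follows such a potential and the
#' volumetric flux through every cross-section is conserved exactly by the
#' finite-volume discretisation.
#'
#' @param geom A `channel_geometry`.
#' @param grid_resolution Grid spacing in mm (default 0.025 = 25 um). The
#'   narrowest cross-section must be resolved by at least 10 cells.
#' @return A tibble of class `velocity_field` with one row per open grid cell:
#'   `x`, `y` (mm), `u` (downstream component, mm/s), `v` (lateral, mm/s) and
#'   `speed`. The solved potential and grid are kept as attributes for flux
#'   checks ([cross_section_flux()]) and centerline extraction
#'   ([centerline_profile()]).
#' @export
solve_depth_averaged <- function(geom, grid_resolution = 0.025) {
  check_positive(grid_resolution, "grid_resolution")
  h <- attr(geom, "depth")
  q_total <- attr(geom, "q_total")

  s_max <- -min(geom$x)                   # downstream distance from inlet
  ns <- max(3L, as.integer(round(s_max / grid_resolution)))
  delta <- s_max / ns
  s_centers <- (seq_len(ns) - 0.5) * delta
  w_s <- channel_width(geom, -s_centers)

  half <- floor(max(geom$w) / (2 * delta))
  ny <- 2L * half + 1L                    # odd: one row centred on y = 0
  y_centers <- (seq_len(ny) - (ny + 1) / 2) * delta

  open <- outer(w_s / 2, abs(y_centers), `>=`) # ns x ny
  n_open_col <- rowSums(open)
  if (min(n_open_col) < 10L) {
    abort("grid does not resolve the narrowest width with >= 10 cells; decrease `grid_resolution`",
          class = "bff_invalid_parameter")
  }

  # cut-cell face conductances: each axial face transmits in proportion to the
  # open fraction of its length, so the effective channel width matches w(x)
  # to much better than one cell
  frac_open <- function(w_here) {
    lo <- pmax(-w_here / 2, y_centers - delta / 2)
    hi <- pmin(w_here / 2, y_centers + delta / 2)
    pmin(pmax((hi - lo) / delta, 0), 1)
  }
  w_face <- channel_width(geom, -(seq_len(ns - 1L)) * delta) # internal faces
  cond_x <- t(vapply(w_face, frac_open, numeric(ny)))        # (ns-1) x ny
  cond_x[!(open[-ns, , drop = FALSE] & open[-1L, , drop = FALSE])] <- 0
  frac_in <- frac_open(w_s[1L]) * open[1L, ]
  frac_out <- frac_open(w_s[ns]) * open[ns, ]

  id <- matrix(0L, ns, ny)
  id[open] <- seq_len(sum(open))
  n_cells <- sum(open)

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_acc <- numeric(n_cells)
  add_pairs <- function(ia, ja, ib, jb, cond) {
    a <- id[cbind(ia, ja)]; b <- id[cbind(ib, jb)]
    keep <- a > 0L & b > 0L & cond > 0
    a <- a[keep]; b <- b[keep]; cond <- cond[keep]
    ii <<- c(ii, a, b); jj <<- c(jj, b, a); vv <<- c(vv, rep(-cond, 2))
    diag_acc[a] <<- diag_acc[a] + cond
    diag_acc[b] <<- diag_acc[b] + cond
  }
  # s-direction faces (cut-cell conductance)
  gi <- which(cond_x > 0, arr.ind = TRUE)
  add_pairs(gi[, 1], gi[, 2], gi[, 1] + 1L, gi[, 2], cond_x[gi])
  # y-direction faces (unit conductance between open cells)
  gj <- which(open[, -ny, drop = FALSE] & open[, -1L, drop = FALSE],
              arr.ind = TRUE)
  add_pairs(gj[, 1], gj[, 2], gj[, 1], gj[, 2] + 1L,
            rep(1, nrow(gj)))

  # influx distributed over inlet cells in proportion to their open width
  b <- numeric(n_cells)
  inlet_ids <- id[1L, frac_in > 0]
  b[inlet_ids] <- q_total / h * frac_in[frac_in > 0] / sum(frac_in)
  # Dirichlet phi = 0 at the outlet face, half-cell distance
  outlet_ids <- id[ns, frac_out > 0]
  diag_acc[outlet_ids] <- diag_acc[outlet_ids] + 2 * frac_out[frac_out > 0]

  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n_cells)),
                            j = c(jj, seq_len(n_cells)),
                            x = c(vv, diag_acc),
                            dims = c(n_cells, n_cells))
  phi_vec <- as.numeric(Matrix::solve(A, b))
  phi <- matrix(NA_real_, ns, ny)
  phi[open] <- phi_vec

  # cell-centred velocities: central differences in the interior, one-sided at
  # the inlet (prescribed influx), outlet (phi = 0 face) and expansion steps
  # (wall on the upstream side of newly opened cells)
  u_in <- q_total / (h * delta * sum(frac_in))
  u <- matrix(NA_real_, ns, ny); v <- matrix(NA_real_, ns, ny)
  for (i in seq_len(ns)) {
    for (j in which(open[i, ])) {
      up <- i > 1L && open[i - 1L, j]
      dn <- i < ns && open[i + 1L, j]
      u[i, j] <-
        if (i == 1L) {
          if (dn) 0.5 * (u_in + (phi[1L, j] - phi[2L, j]) / delta) else u_in
        } else if (i == ns) {
          face_out <- phi[ns, j] / (delta / 2)
          if (up) 0.5 * ((phi[ns - 1L, j] - phi[ns, j]) / delta + face_out)
          else face_out
        } else if (up && dn) {
          (phi[i - 1L, j] - phi[i + 1L, j]) / (2 * delta)
        } else if (dn) {
          (phi[i, j] - phi[i + 1L, j]) / delta
        } else if (up) {
          (phi[i - 1L, j] - phi[i, j]) / delta
        } else 0
      lf <- j > 1L && open[i, j - 1L]
      rt <- j < ny && open[i, j + 1L]
      v[i, j] <-
        if (lf && rt) (phi[i, j - 1L] - phi[i, j + 1L]) / (2 * delta)
        else if (rt)  (phi[i, j] - phi[i, j + 1L]) / delta
        else if (lf)  (phi[i, j - 1L] - phi[i, j]) / delta
        else 0
    }
  }

  idx <- which(open, arr.ind = TRUE)
  u_open <- u[open]; v_open <- v[open]
  out <- tibble(x = -s_centers[idx[, 1]], y = y_centers[idx[, 2]],
                u = u_open, v = v_open,
                speed = sqrt(u_open^2 + v_open^2))
  structure(out,
            class = c("velocity_field", class(out)),
            phi = phi, open = open, cond_x = cond_x, delta = delta,
            depth = h, q_total = q_total, s_centers = s_centers,
            y_centers = y_centers)
}

#' Volumetric flux through every cross-section of a solved field
#'
#' Computed from the finite-volume face fluxes of the potential, so the value
#' should equal the prescribed `Q_total` to solver precision at every section.
#'
#' @param field A `velocity_field`.
#' @return Tibble with `x_face` (mm) and `flux_mm3_s`.
#' @export
cross_section_flux <- function(field) {
  phi <- attr(field, "phi"); cond_x <- attr(field, "cond_x")
  h <- attr(field, "depth"); s <- attr(field, "s_centers")
  delta <- attr(field, "delta")
  ns <- nrow(phi)
  flux <- vapply(seq_len(ns - 1L), function(i) {
    j <- which(cond_x[i, ] > 0)
    h * sum(cond_x[i, j] * (phi[i, j] - phi[i + 1L, j]))
  }, numeric(1))
  tibble(x_face = -(s[-ns] + delta / 2), flux_mm3_s = flux)
}

#' Centerline speed profile of a solved field
#'
#' @param field A `velocity_field`.
#' @return Tibble with `x` (mm) and `speed` (mm/s) along `y = 0`.
#' @export
centerline_profile <- function(field) {
  y0 <- attr(field, "y_centers")[(length(attr(field, "y_centers")) + 1) / 2]
  field |>
    dplyr::filter(.data$y == y0) |>
    dplyr::arrange(dplyr::desc(.data$x)) |>
    dplyr::select("x", "speed")
}

#' @export
autoplot.velocity_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$speed)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "speed (mm/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = "Depth-averaged flow field")
}
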