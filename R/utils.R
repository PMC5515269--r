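# Internal helpers shared across modules.

# ml per hour -> mm^3 per second
ml_h_to_mm3_s <- function(q) q * 1000 / 3600

# positive scalar check with a classed error
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(paste0("`", name, "` must be a single positive number"),
          class = "bff_invalid_parameter")
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(paste0("`", name, "` must be TRUE or FALSE"),
          class = "bff_invalid_parameter")
  }
  invisible(x)
}

# volume of a voxel in um^3 given voxel dims in um
voxel_volume <- function(voxel_dims) prod(voxel_dims)
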