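# 3-D segmentation of confocal stacks: absolute intensity threshold,
# connected-component labeling, minimum object size.

#' Segment a 3-D stack into biofilm clusters
#'
#' Clusters are maximal connected components of voxels with intensity at or
#' above an absolute threshold, under 6-, 18- or 26-neighbourhood
#' connectivity; components smaller than `min_voxels` are discarded. The
#' biovolume of a cluster is its voxel count times the voxel volume
#' (0.42 x 0.42 x 0.78 um = 0.137592 um^3 by default), i.e. the volume of
#' supra-threshold cell material excluding unlabelled extracellular matrix.
#'
#' @param stack 3-D numeric/integer array (x, y, z).
#' @param threshold Absolute intensity threshold (inclusive), default 10.
#' @param min_voxels Minimum component size in voxels, default 3.
#' @param connectivity 6, 18 or 26 (default 26: surface-type segmentation
#'   merges diagonal contacts).
#' @param voxel_dims Voxel edge lengths in um, `c(dx, dy, dz)`.
#' @return Tibble with one row per cluster: `id`, `voxels`, `volume_um3`,
#'   centroid `x_um`/`y_um`/`z_um`, and bounding box in voxel indices.
#' @examples
#' stack <- array(0L, c(5, 5, 3)); stack[2:3, 2:3, 1] <- 50L
#' segment_stack(stack)
#' @export
segment_stack <- function(stack, threshold = 10, min_voxels = 3,
                          connectivity = 26,
                          voxel_dims = c(0.42, 0.42, 0.78)) {
  if (!is.array(stack) || length(dim(stack)) != 3L || any(dim(stack) < 1L)) {
    abort("`stack` must be a non-empty 3-D array", class = "bff_input_error")
  }
  if (threshold < 0 || min_voxels < 1) {
    abort("`threshold` must be >= 0 and `min_voxels` >= 1",
          class = "bff_invalid_parameter")
  }
  if (!connectivity %in% c(6L, 18L, 26L)) {
    abort("`connectivity` must be one of 6, 18, 26",
          class = "bff_invalid_parameter")
  }
  dims <- dim(stack)
  mask <- as.vector(stack >= threshold)
  labels <- cpp_label3d(mask, as.integer(dims), as.integer(connectivity))

  fg <- which(labels > 0L)
  if (length(fg) == 0L) return(empty_cluster_table())
  lab <- labels[fg]
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  if (length(keep) == 0L) return(empty_cluster_table())

  sel <- lab %in% keep
  fg <- fg[sel]; lab <- lab[sel]
  # voxel indices (1-based) from linear index, column-major
  ix <- (fg - 1L) %% dims[1] + 1L
  iy <- ((fg - 1L) %/% dims[1]) %% dims[2] + 1L
  iz <- (fg - 1L) %/% (dims[1] * dims[2]) + 1L

  vox_vol <- voxel_volume(voxel_dims)
  # base-R group summaries: this is the hot path of the pipeline
  groups <- sort(keep)
  lab_f <- match(lab, groups)
  counts <- tabulate(lab_f, nbins = length(groups))
  sums <- rowsum(cbind(ix, iy, iz), lab_f)
  sp <- split(seq_along(lab_f), lab_f)
  bbox <- vapply(sp, function(ii) {
    c(min(ix[ii]), max(ix[ii]), min(iy[ii]), max(iy[ii]),
      min(iz[ii]), max(iz[ii]))
  }, integer(6))
  tibble(
    id = seq_along(groups),
    voxels = counts,
    volume_um3 = counts * vox_vol,
    x_um = (sums[, 1] / counts - 0.5) * voxel_dims[1],
    y_um = (sums[, 2] / counts - 0.5) * voxel_dims[2],
    z_um = (sums[, 3] / counts - 0.5) * voxel_dims[3],
    bbox_x0 = bbox[1, ], bbox_x1 = bbox[2, ],
    bbox_y0 = bbox[3, ], bbox_y1 = bbox[4, ],
    bbox_z0 = bbox[5, ], bbox_z1 = bbox[6, ]
  )
}

empty_cluster_table <- function() {
  tibble(id = integer(), voxels = integer(), volume_um3 = numeric(),
         x_um = numeric(), y_um = numeric(), z_um = numeric(),
         bbox_x0 = integer(), bbox_x1 = integer(),
         bbox_y0 = integer(), bbox_y1 = integer(),
         bbox_z0 = integer(), bbox_z1 = integer())
}

#' Read or write a z-stack as a multi-page TIFF
#'
#' Intensities are stored as 8-bit grey values; the round trip preserves
#' integer counts in 0..255 exactly. The array layout is (x, y, z).
#'
#' @param path TIFF file path.
#' @param stack Integer 3-D array with values in 0..255.
#' @return `read_stack()` an integer 3-D array; `write_stack()` the path,
#'   invisibly.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "bff_not_found")
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      abort(paste0("cannot read TIFF: ", conditionMessage(e)),
                            class = "bff_format_error")
                    })
  if (!is.list(pages)) pages <- list(pages)
  # readTIFF returns row-major matrices (y in rows); transpose to (x, y)
  arr <- vapply(pages, t, matrix(0L, ncol(pages[[1]]), nrow(pages[[1]])))
  array(as.integer(arr), dim = c(dim(pages[[1]])[2], dim(pages[[1]])[1],
                                 length(pages)))
}

#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  slices <- lapply(seq_len(dim(stack)[3]),
                   function(k) t(stack[, , k]) / 255)
  tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  invisible(path)
}
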