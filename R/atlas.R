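#' Load an MCA-territory mask onto a reference grid
#'
#' Accepts any NIfTI territory mask (e.g. one derived from a
#' neuroanatomical atlas) together with an affine mapping it onto the
#' patient grid, resamples it nearest-neighbour, and restricts it to the
#' requested side of the midline plane. When no file is given, a
#' synthetic hemispheric territory is generated instead (for phantoms
#' and tests).
#'
#' @param reference An [odacs_volume()] or [odacs_mask()] defining the
#'   output grid.
#' @param side `"left"` or `"right"`: the ipsilateral hemisphere.
#' @param path Optional path to a territory NIfTI mask; `NULL` selects
#'   the synthetic territory.
#' @param transform [odacs_affine()] mapping the file's physical space
#'   onto the reference space (identity by default).
#' @param plane Midline [odacs_midplane()]; grid-centre default.
#' @param margin_voxels Border margin for the synthetic territory.
#' @return Territory [odacs_mask()] on the reference grid.
#' @export
load_territory <- function(reference, side = c("left", "right"), path = NULL,
                           transform = odacs_affine(), plane = NULL,
                           margin_voxels = 2L) {
  side <- match.arg(side)
  if (is.null(plane)) plane <- default_midplane(reference)
  if (is.null(path)) {
    return(synthetic_territory(reference, plane, side, margin_voxels))
  }
  m <- read_mask(path)
  same <- identical(dim(m$data), dim(reference$data)) &&
    max(abs(m$spacing - reference$spacing)) < 1e-6 &&
    max(abs(m$origin - reference$origin)) < 1e-6 &&
    max(abs(transform$matrix - diag(3))) < 1e-12 &&
    max(abs(transform$translation)) < 1e-12
  if (!same) {
    m <- resample_to_grid(m, reference, transform, mode = "nearest")
  }
  m <- restrict_to_side(m, plane, side)
  if (voxel_count(m) == 0) {
    stop("territory mask is empty after resampling to the reference grid",
         call. = FALSE)
  }
  m
}

# Keep only voxels on the requested side of the plane (strictly, so the
# territory never touches its own mirror).
restrict_to_side <- function(mask, plane, side) {
  d <- dim(mask$data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  pts <- voxel_to_physical(mask, idx)
  sd <- as.numeric(sweep(pts, 2, plane$point, "-") %*% plane$normal)
  keep <- if (side == "right") sd > 0 else sd < 0
  mask_like(mask, mask$data & array(keep, dim = d))
}

#' Synthetic hemispheric territory mask
#'
#' A lateral slab covering one hemisphere, used as a stand-in territory
#' for phantoms: the chosen side of the midline minus a border margin
#' and a one-voxel exclusion band at the midplane, so the territory
#' never overlaps its own mirror.
#'
#' @param reference Grid-defining [odacs_volume()] or [odacs_mask()].
#' @param plane Midline [odacs_midplane()].
#' @param side `"left"` or `"right"`.
#' @param margin_voxels Non-negative border margin in voxels.
#' @return Territory [odacs_mask()].
#' @export
synthetic_territory <- function(reference, plane, side = c("left", "right"),
                                margin_voxels = 2L) {
  side <- match.arg(side)
  margin_voxels <- as.integer(margin_voxels)
  stopifnot(margin_voxels >= 0L)
  d <- dim(reference$data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  pts <- voxel_to_physical(reference, idx)
  sd <- as.numeric(sweep(pts, 2, plane$point, "-") %*% plane$normal)
  band <- reference$spacing[1]  # one-voxel exclusion band at the midplane
  lateral <- if (side == "right") sd > band else sd < -band
  inside <- idx[, 1] > margin_voxels & idx[, 1] <= d[1] - margin_voxels &
            idx[, 2] > margin_voxels & idx[, 2] <= d[2] - margin_voxels &
            idx[, 3] > margin_voxels & idx[, 3] <= d[3] - margin_voxels
  mask_like(reference, array(lateral & inside, dim = d))
}
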