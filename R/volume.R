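#' In-memory 3D image volume
#'
#' An `odacs_volume` is a 3D scalar grid with physical geometry: voxel
#' spacing in mm, the physical coordinate (mm) of the centre of the first
#' voxel, and anatomical axis codes. Volumes are kept in a canonical
#' orientation in which the first array axis runs left-right, so that
#' midline mirroring has a fixed axis.
#'
#' Voxel `(i, j, k)` (1-based) has physical centre
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3D numeric array.
#' @param spacing Voxel size in mm per axis; three positive reals.
#' @param origin Physical coordinate (mm) of the centre of voxel (1,1,1).
#' @param axis_codes Character vector of length 3 giving the anatomical
#'   direction of increasing index per axis, e.g. `c("R","A","S")`.
#' @param value_kind One of `"tmax_seconds"`, `"intensity"`,
#'   `"probability"`. Tmax volumes must be non-negative where finite.
#' @return An object of class `odacs_volume`.
#' @export
odacs_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         axis_codes = c("R", "A", "S"),
                         value_kind = c("intensity", "tmax_seconds", "probability")) {
  value_kind <- match.arg(value_kind)
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("volume data must have exactly 3 axes, got ", length(dim(data)),
         call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive finite reals", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("origin must be three finite reals", call. = FALSE)
  }
  if (value_kind == "tmax_seconds") {
    v <- data[is.finite(data)]
    if (length(v) && any(v < 0)) {
      stop("tmax_seconds volumes must be non-negative where finite",
           call. = FALSE)
    }
  }
  structure(
    list(data = data, spacing = spacing, origin = origin,
         axis_codes = axis_codes, value_kind = value_kind),
    class = "odacs_volume"
  )
}

#' In-memory 3D binary mask
#'
#' An `odacs_mask` shares the geometry model of [odacs_volume()] but holds
#' logical data (vessel segmentations, hypoperfusion masks, territory
#' masks, mirrored regions).
#'
#' @inheritParams odacs_volume
#' @param data 3D logical (or coercible 0/1) array.
#' @return An object of class `odacs_mask`.
#' @export
odacs_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       axis_codes = c("R", "A", "S")) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("mask data must have exactly 3 axes", call. = FALSE)
  }
  if (!is.logical(data)) {
    storage.mode(data) <- "logical"
  }
  data[is.na(data)] <- FALSE
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive finite reals", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, origin = origin,
         axis_codes = axis_codes),
    class = "odacs_mask"
  )
}

#' @export
print.odacs_volume <- function(x, ...) {
  cat("<odacs_volume> ", paste(dim(x$data), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm, kind: ", x$value_kind, "\n", sep = "")
  invisible(x)
}

#' @export
print.odacs_mask <- function(x, ...) {
  cat("<odacs_mask> ", paste(dim(x$data), collapse = "x"),
      " voxels, ", voxel_count(x), " true (",
      signif(mask_volume_ml(x), 4), " mL)\n", sep = "")
  invisible(x)
}

#' Number of true voxels in a mask
#' @param mask An [odacs_mask()].
#' @return Integer count of true voxels.
#' @export
voxel_count <- function(mask) {
  stopifnot(inherits(mask, "odacs_mask"))
  sum(mask$data)
}

#' Physical volume of a mask in millilitres
#'
#' The true-voxel count times the voxel volume (product of spacings,
#' mm^3), converted to mL.
#'
#' @param mask An [odacs_mask()].
#' @return Volume in mL (non-negative).
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "odacs_mask"))
  sum(mask$data) * prod(mask$spacing) / 1000
}

#' @rdname odacs_volume
#' @param x Object to test.
#' @export
is_odacs_volume <- function(x) inherits(x, "odacs_volume")

#' @rdname odacs_mask
#' @param x Object to test.
#' @export
is_odacs_mask <- function(x) inherits(x, "odacs_mask")

# Physical coordinates (mm) of voxel centres given 1-based index matrix.
voxel_to_physical <- function(geom, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx - 1, 2, geom$spacing, "*"), 2, geom$origin, "+")
}

# Continuous (fractional) 1-based voxel index for physical points.
physical_to_voxel <- function(geom, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, geom$origin, "-"), 2, geom$spacing, "/") + 1
}

# Coordinates (N x 3 integer matrix) of true voxels of a mask.
mask_coords <- function(mask) {
  which(mask$data, arr.ind = TRUE)
}

# Shared geometry as a plain list (used by constructors of derived objects).
geometry_of <- function(x) {
  list(spacing = x$spacing, origin = x$origin, axis_codes = x$axis_codes)
}

# Build a mask on the same grid as `like` from a logical array.
mask_like <- function(like, data) {
  odacs_mask(data, spacing = like$spacing, origin = like$origin,
             axis_codes = like$axis_codes)
}

#' Check that two objects live on the same voxel grid
#'
#' Compares array shape, spacing and origin of two geometry-bearing
#' objects (volumes or masks). Intended as the precondition for any
#' voxelwise combination, e.g. intersecting a vessel mask with a region.
#'
#' @param a,b Volumes or masks.
#' @param tol_mm Tolerance in mm for spacing and origin agreement.
#' @return Invisibly `TRUE`; errors on mismatch naming the offending
#'   component.
#' @export
assert_same_grid <- function(a, b, tol_mm = 1e-3) {
  da <- dim(a$data); db <- dim(b$data)
  if (!identical(da, db)) {
    stop("grid mismatch: shapes ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"), call. = FALSE)
  }
  if (any(abs(a$spacing - b$spacing) > tol_mm)) {
    stop("grid mismatch: spacing (", paste(signif(a$spacing, 6), collapse = ", "),
         ") vs (", paste(signif(b$spacing, 6), collapse = ", "), ") mm",
         call. = FALSE)
  }
  if (any(abs(a$origin - b$origin) > tol_mm)) {
    stop("grid mismatch: origin (", paste(signif(a$origin, 6), collapse = ", "),
         ") vs (", paste(signif(b$origin, 6), collapse = ", "), ") mm",
         call. = FALSE)
  }
  invisible(TRUE)
}
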