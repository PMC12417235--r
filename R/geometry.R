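#' Midline plane of the brain
#'
#' A physical-space plane (point on the plane plus unit normal, both in
#' mm) separating the two hemispheres. Supplied by an external midline
#' extraction via a JSON sidecar ([read_midplane()]) or constructed as
#' the grid-centre fallback ([default_midplane()]).
#'
#' @param point Numeric length-3, a point on the plane (mm).
#' @param normal Numeric length-3; normalized internally, must be nonzero.
#' @return An object of class `odacs_midplane`.
#' @export
odacs_midplane <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  if (length(point) != 3L || length(normal) != 3L ||
      any(!is.finite(point)) || any(!is.finite(normal))) {
    stop("midplane point and normal must be finite length-3 vectors",
         call. = FALSE)
  }
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("midplane normal must be nonzero", call. = FALSE)
  structure(list(point = point, normal = normal / nn),
            class = "odacs_midplane")
}

#' @export
print.odacs_midplane <- function(x, ...) {
  cat("<odacs_midplane> point (", paste(signif(x$point, 5), collapse = ", "),
      ") mm, normal (", paste(signif(x$normal, 5), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Affine transform between physical spaces
#'
#' Maps physical points `p` of a moving image into a fixed space as
#' `matrix %*% p + translation`. Used to apply a given co-registration;
#' estimating transforms is outside this package's scope.
#'
#' @param matrix 3x3 invertible matrix.
#' @param translation Length-3 translation in mm.
#' @return An object of class `odacs_affine`.
#' @export
odacs_affine <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L) {
    stop("translation must have length 3", call. = FALSE)
  }
  if (!all(is.finite(matrix)) || abs(det(matrix)) < 1e-12 ||
      !is.finite(rcond(matrix)) || rcond(matrix) < 1e-12) {
    stop("affine matrix must be finite and invertible", call. = FALSE)
  }
  structure(list(matrix = matrix, translation = translation),
            class = "odacs_affine")
}

apply_affine <- function(affine, pts) {
  pts <- rbind(pts)
  sweep(pts %*% t(affine$matrix), 2, affine$translation, "+")
}

invert_affine <- function(affine) {
  minv <- solve(affine$matrix)
  odacs_affine(matrix = minv, translation = -as.numeric(minv %*% affine$translation))
}

#' Grid-centre midline plane
#'
#' Fallback midline when no externally extracted plane is supplied: the
#' plane through the physical centre of the grid with normal along the
#' left-right (first) axis.
#'
#' @param volume An [odacs_volume()] or [odacs_mask()] in canonical
#'   orientation.
#' @return An [odacs_midplane()].
#' @export
default_midplane <- function(volume) {
  d <- dim(volume$data)
  centre <- volume$origin + (d - 1) / 2 * volume$spacing
  odacs_midplane(point = centre, normal = c(1, 0, 0))
}

#' Reflect physical points through a plane
#'
#' @param pts N x 3 matrix of physical coordinates (mm).
#' @param plane An [odacs_midplane()].
#' @return N x 3 matrix of reflected coordinates.
#' @export
reflect_points <- function(pts, plane) {
  pts <- rbind(pts)
  sd <- sweep(pts, 2, plane$point, "-") %*% plane$normal  # signed distances
  pts - 2 * as.numeric(sd) %o% plane$normal
}

# Deterministic nearest-voxel rounding: exact half-voxel ties go to the
# lower index.
round_half_down <- function(x) ceiling(x - 0.5)

#' Mirror a binary mask across the midline plane
#'
#' Each true voxel centre is reflected through the plane in physical
#' coordinates and assigned to the nearest voxel centre of the same grid
#' (ties at exact half-voxel distances round toward the lower index).
#' Reflections landing outside the grid are dropped; their fraction is
#' recorded in the `off_grid_fraction` attribute and raised as a warning
#' when nonzero.
#'
#' @param mask An [odacs_mask()].
#' @param plane An [odacs_midplane()].
#' @return The mirrored [odacs_mask()] on the same grid.
#' @export
mirror_mask <- function(mask, plane) {
  stopifnot(is_odacs_mask(mask), inherits(plane, "odacs_midplane"))
  d <- dim(mask$data)
  out <- array(FALSE, dim = d)
  idx <- mask_coords(mask)
  frac_off <- 0
  if (nrow(idx) > 0) {
    pts <- voxel_to_physical(mask, idx)
    refl <- reflect_points(pts, plane)
    ci <- physical_to_voxel(mask, refl)
    ri <- round_half_down(ci)
    ok <- ri[, 1] >= 1 & ri[, 1] <= d[1] &
          ri[, 2] >= 1 & ri[, 2] <= d[2] &
          ri[, 3] >= 1 & ri[, 3] <= d[3]
    frac_off <- 1 - mean(ok)
    if (any(ok)) out[ri[ok, , drop = FALSE]] <- TRUE
    if (frac_off > 0) {
      warning(sprintf("%.1f%% of mirrored voxels fell outside the grid and were dropped",
                      100 * frac_off), call. = FALSE)
    }
  }
  res <- mask_like(mask, out)
  attr(res, "off_grid_fraction") <- frac_off
  res
}

# Minimal rotation taking unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    stop("cannot construct rotation between antiparallel vectors", call. = FALSE)
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

# Trilinear / nearest sampling of a 3D array at continuous 1-based voxel
# indices; outside the grid returns `fill`.
sample_array <- function(arr, ci, mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  d <- dim(arr)
  n <- nrow(ci)
  if (mode == "nearest") {
    ri <- round_half_down(ci)
    ok <- ri[, 1] >= 1 & ri[, 1] <= d[1] &
          ri[, 2] >= 1 & ri[, 2] <= d[2] &
          ri[, 3] >= 1 & ri[, 3] <= d[3]
    out <- rep(fill, n)
    if (any(ok)) out[ok] <- arr[ri[ok, , drop = FALSE]]
    return(out)
  }
  i0 <- floor(ci)
  f <- ci - i0
  out <- numeric(n)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    ii <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
    ok <- ii[, 1] >= 1 & ii[, 1] <= d[1] &
          ii[, 2] >= 1 & ii[, 2] <= d[2] &
          ii[, 3] >= 1 & ii[, 3] <= d[3]
    vals <- rep(fill, n)
    if (any(ok)) vals[ok] <- arr[ii[ok, , drop = FALSE]]
    out <- out + w * vals
  }
  out
}

# Resample a volume/mask onto its own grid under a rigid map `fwd`
# (point in input space -> point in output space), i.e. sample the input
# at fwd^{-1}(output voxel centres).
resample_rigid <- function(x, rot, centre_from, centre_to, mode) {
  d <- dim(x$data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  q <- voxel_to_physical(x, idx)
  # inverse map: p = R^T (q - centre_to) + centre_from
  p <- sweep(sweep(q, 2, centre_to, "-") %*% rot, 2, centre_from, "+")
  ci <- physical_to_voxel(x, p)
  vals <- sample_array(x$data + 0, ci, mode = mode, fill = 0)
  array(vals, dim = d)
}

#' Rigidly align a volume so a supplied midline coincides with the grid-centre plane
#'
#' Resamples the volume under the rigid transform that rotates the
#' supplied plane's normal onto the left-right axis and moves the
#' plane's point to the grid centre, emulating vendor-style midline
#' alignment to a standard coordinate system. Scalar volumes are
#' interpolated linearly, masks with nearest-neighbour.
#'
#' @param x An [odacs_volume()] or [odacs_mask()].
#' @param plane An [odacs_midplane()]; its normal must be within 45
#'   degrees of the left-right axis.
#' @return A list with `image` (the resampled object) and `plane` (the
#'   new grid-centre [odacs_midplane()]).
#' @export
align_to_midplane <- function(x, plane) {
  stopifnot(inherits(plane, "odacs_midplane"))
  n <- plane$normal
  if (n[1] < 0) n <- -n  # plane orientation sign is arbitrary
  if (n[1] < cos(pi / 4)) {
    stop("degenerate midline plane: normal more than 45 degrees from the left-right axis",
         call. = FALSE)
  }
  target <- default_midplane(x)
  rot <- rotation_between(n, c(1, 0, 0))
  # forward map: q = rot (p - plane$point) + target$point
  identity_map <- max(abs(rot - diag(3))) < 1e-12 &&
    max(abs(plane$point - target$point)) < 1e-12
  if (identity_map) {
    return(list(image = x, plane = target))
  }
  mode <- if (is_odacs_mask(x)) "nearest" else "linear"
  arr <- resample_rigid(x, rot, plane$point, target$point, mode)
  out <- if (is_odacs_mask(x)) {
    mask_like(x, arr > 0.5)
  } else {
    odacs_volume(arr, spacing = x$spacing, origin = x$origin,
                 axis_codes = x$axis_codes, value_kind = x$value_kind)
  }
  list(image = out, plane = target)
}

#' Resample a volume onto a reference grid under a given affine
#'
#' Applies a known co-registration: `transform` maps physical points of
#' `x` into the reference space; the output carries the reference
#' geometry. With the identity transform and equal grids this is the
#' identity map.
#'
#' @param x An [odacs_volume()] or [odacs_mask()] (the moving image).
#' @param reference An [odacs_volume()] or [odacs_mask()] supplying the
#'   output grid.
#' @param transform An [odacs_affine()] (moving to fixed); default
#'   identity.
#' @param mode Interpolation: `"nearest"` or `"linear"`. Masks are
#'   always resampled nearest-neighbour.
#' @return Object of the same class as `x` on the reference grid.
#' @export
resample_to_grid <- function(x, reference, transform = odacs_affine(),
                             mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (is_odacs_mask(x)) mode <- "nearest"
  inv <- invert_affine(transform)
  d <- dim(reference$data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  q <- voxel_to_physical(reference, idx)
  p <- apply_affine(inv, q)
  ci <- physical_to_voxel(x, p)
  vals <- sample_array(x$data + 0, ci, mode = mode, fill = 0)
  arr <- array(vals, dim = d)
  if (is_odacs_mask(x)) {
    odacs_mask(arr > 0.5, spacing = reference$spacing,
               origin = reference$origin, axis_codes = reference$axis_codes)
  } else {
    odacs_volume(arr, spacing = reference$spacing, origin = reference$origin,
                 axis_codes = reference$axis_codes, value_kind = x$value_kind)
  }
}
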