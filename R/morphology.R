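#' Ellipsoidal structuring element
#'
#' Integer voxel offsets `(dx, dy, dz)` satisfying
#' `(dx/a)^2 + (dy/b)^2 + (dz/c)^2 <= 1` for semi-axes `(a, b, c)` in
#' voxel units. A zero semi-axis admits only offset 0 along that axis.
#' The default `(10, 10, 1)` is the element used to recover vessels
#' carved out of vendor perfusion maps: an in-plane disc of radius 10
#' voxels plus single voxels one slice above and below.
#'
#' @param semi_axes Three non-negative numbers (voxel units).
#' @return Integer matrix with columns `dx`, `dy`, `dz`; contains the
#'   origin and is symmetric under negation.
#' @export
ellipsoid_element <- function(semi_axes = c(10, 10, 1)) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) || any(semi_axes < 0)) {
    stop("semi_axes must be three non-negative finite numbers", call. = FALSE)
  }
  ext <- floor(semi_axes)
  g <- as.matrix(expand.grid(dx = -ext[1]:ext[1], dy = -ext[2]:ext[2],
                             dz = -ext[3]:ext[3]))
  # zero semi-axis: only a zero offset is admissible along that axis
  term <- function(d, a) if (a > 0) (d / a)^2 else ifelse(d == 0, 0, Inf)
  r2 <- term(g[, 1], semi_axes[1]) + term(g[, 2], semi_axes[2]) +
        term(g[, 3], semi_axes[3])
  el <- g[r2 <= 1 + 1e-12, , drop = FALSE]
  storage.mode(el) <- "integer"
  el
}

element_extent <- function(element) {
  unname(apply(abs(element), 2, max))
}

# Binary convolution count via FFT on a zero-padded domain: out[v] =
# number of element offsets o with arr[v - o] true. Exact for voxel
# counts up to rounding noise far below 0.5.
conv_count <- function(arr, element) {
  d <- dim(arr)
  kern <- array(0, dim = d)
  # place offset o at wrapped linear position
  pos <- sweep(element, 2, d, function(o, n) (o %% n) + 1L)
  kern[pos] <- kern[pos] + 1
  re <- Re(fft(fft(arr + 0) * fft(kern), inverse = TRUE)) / prod(d)
  array(re, dim = d)
}

pad_array <- function(arr, ext, value = FALSE) {
  d <- dim(arr)
  out <- array(value, dim = d + 2 * ext)
  out[(ext[1] + 1):(ext[1] + d[1]),
      (ext[2] + 1):(ext[2] + d[2]),
      (ext[3] + 1):(ext[3] + d[3])] <- arr
  out
}

crop_array <- function(arr, ext, d) {
  arr[(ext[1] + 1):(ext[1] + d[1]),
      (ext[2] + 1):(ext[2] + d[2]),
      (ext[3] + 1):(ext[3] + d[3])]
}

#' Binary dilation, erosion and closing
#'
#' Morphological operators on binary masks with an arbitrary structuring
#' element (a matrix of integer offsets, typically from
#' [ellipsoid_element()]). The grid boundary is treated as background:
#' for [close_mask()] the volume is padded by the element extent with
#' false voxels before dilation and cropped after erosion, so the border
#' never closes gaps spuriously.
#'
#' @param mask An [odacs_mask()].
#' @param element Integer offset matrix (columns dx, dy, dz).
#' @return An [odacs_mask()] on the same grid.
#' @export
dilate_mask <- function(mask, element = ellipsoid_element()) {
  stopifnot(is_odacs_mask(mask))
  d <- dim(mask$data)
  ext <- element_extent(element)
  p <- pad_array(mask$data, ext)
  out <- crop_array(conv_count(p, element) > 0.5, ext, d)
  mask_like(mask, out)
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, element = ellipsoid_element()) {
  stopifnot(is_odacs_mask(mask))
  d <- dim(mask$data)
  ext <- element_extent(element)
  p <- pad_array(mask$data, ext)
  out <- crop_array(conv_count(p, element) > nrow(element) - 0.5, ext, d)
  mask_like(mask, out)
}

#' @rdname dilate_mask
#' @export
close_mask <- function(mask, element = ellipsoid_element()) {
  stopifnot(is_odacs_mask(mask))
  d <- dim(mask$data)
  ext <- element_extent(element)
  if (all(ext == 0) && nrow(element) == 1L) return(mask)
  p <- pad_array(mask$data, ext)
  dil <- conv_count(p, element) > 0.5
  ero <- conv_count(dil, element) > nrow(element) - 0.5
  mask_like(mask, crop_array(ero, ext, d))
}
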