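#' Hypoperfusion mask from a Tmax map
#'
#' The occlusion-downstream area proxy: voxels with Tmax strictly
#' greater than the threshold (default 6 s, the common definition of
#' hypoperfused tissue). Non-finite voxels are excluded.
#'
#' @param tmax An [odacs_volume()] with `value_kind = "tmax_seconds"`.
#' @param threshold_s Threshold in seconds; strictly-greater comparison.
#' @return An [odacs_mask()].
#' @export
threshold_hypoperfusion <- function(tmax, threshold_s = 6.0) {
  stopifnot(is_odacs_volume(tmax))
  if (!identical(tmax$value_kind, "tmax_seconds")) {
    stop("threshold_hypoperfusion expects a volume with value_kind 'tmax_seconds', got '",
         tmax$value_kind, "'", call. = FALSE)
  }
  if (!is.finite(threshold_s) || threshold_s <= 0) {
    stop("threshold_s must be a positive number", call. = FALSE)
  }
  d <- tmax$data
  m <- is.finite(d) & d > threshold_s
  mask_like(tmax, m)
}

#' Refine the downstream area by morphological closing
#'
#' Vendor CTP software removes vessels from its perfusion analysis, so
#' vessels traversing the hypoperfused area appear as tubular holes in
#' the thresholded mask. Closing with an ellipsoidal element (default
#' semi-axes 10, 10, 1 voxels along x, y, z) fills these holes, making
#' penetrating vessels part of the refined downstream mask. The result
#' is always a superset of the input.
#'
#' @param hypo Hypoperfusion [odacs_mask()].
#' @param semi_axes Ellipsoid semi-axes in voxels; see
#'   [ellipsoid_element()]. `c(0, 0, 0)` disables refinement.
#' @return Refined [odacs_mask()].
#' @export
refine_downstream <- function(hypo, semi_axes = c(10, 10, 1)) {
  stopifnot(is_odacs_mask(hypo))
  close_mask(hypo, ellipsoid_element(semi_axes))
}

#' Ipsilateral/contralateral region pair
#'
#' Determines the occlusion side as the hemisphere holding the majority
#' of the refined downstream mask, mirrors the mask across the midline
#' plane to obtain the contralateral counterpart, and records quality
#' indicators: the fraction of the ipsilateral mask overlapped by its
#' own mirror (large values mean the lesion straddles the midline) and
#' the number of axial slices covered.
#'
#' @param refined Refined downstream [odacs_mask()]; must be nonempty.
#' @param plane An [odacs_midplane()].
#' @param majority_warn Warn when the majority-hemisphere fraction falls
#'   below this value (default 0.9).
#' @param overlap_warn Warn when the mirror-overlap fraction exceeds
#'   this value (default 0.05).
#' @return An `odacs_region_pair`: list with `ipsilateral`,
#'   `contralateral` masks, `side` (`"left"`/`"right"`),
#'   `overlap_fraction`, `coverage_slices`, `warnings`.
#' @export
build_region_pair <- function(refined, plane, majority_warn = 0.9,
                              overlap_warn = 0.05) {
  stopifnot(is_odacs_mask(refined), inherits(plane, "odacs_midplane"))
  n_ipsi <- voxel_count(refined)
  if (n_ipsi == 0) {
    stop("no hypoperfusion: the refined downstream mask is empty",
         call. = FALSE)
  }
  warnings <- character()
  idx <- mask_coords(refined)
  pts <- voxel_to_physical(refined, idx)
  sd <- as.numeric(sweep(pts, 2, plane$point, "-") %*% plane$normal)
  # canonical orientation: +x (and hence positive signed distance for a
  # right-pointing normal) is the patient's right
  n_right <- sum(sd > 0)
  frac_major <- max(n_right, n_ipsi - n_right) / n_ipsi
  side <- if (n_right > n_ipsi - n_right) "right" else "left"
  if (frac_major < majority_warn) {
    warnings <- c(warnings, sprintf(
      "only %.0f%% of the downstream mask lies in the %s hemisphere",
      100 * frac_major, side))
  }
  contra <- suppressWarnings(mirror_mask(refined, plane))
  off_grid <- attr(contra, "off_grid_fraction")
  if (isTRUE(off_grid > 0)) {
    warnings <- c(warnings, sprintf(
      "%.1f%% of mirrored voxels fell outside the grid", 100 * off_grid))
  }
  overlap <- sum(refined$data & contra$data) / n_ipsi
  if (overlap > overlap_warn) {
    warnings <- c(warnings, sprintf(
      "downstream mask overlaps its own mirror by %.1f%%; lesion may straddle the midline",
      100 * overlap))
  }
  coverage <- sum(apply(refined$data, 3, any))
  structure(
    list(ipsilateral = refined, contralateral = contra, side = side,
         overlap_fraction = overlap, coverage_slices = coverage,
         warnings = warnings),
    class = "odacs_region_pair"
  )
}

#' @export
print.odacs_region_pair <- function(x, ...) {
  cat("<odacs_region_pair> side: ", x$side,
      ", ipsi ", signif(mask_volume_ml(x$ipsilateral), 4), " mL",
      ", contra ", signif(mask_volume_ml(x$contralateral), 4), " mL",
      ", overlap ", signif(x$overlap_fraction, 3),
      ", slices ", x$coverage_slices, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}
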