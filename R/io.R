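#' Read a 3D NIfTI volume
#'
#' Loads a `.nii`/`.nii.gz` file and reorients it to the package's
#' canonical anatomical convention (first axis left-right, i.e. "RAS"
#' axis codes) using the file's qform/sform metadata, so that midline
#' mirroring always acts along the first array axis. The original
#' orientation string is recorded in the result's `provenance` attribute.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param value_kind Declared meaning of the voxel values; see
#'   [odacs_volume()].
#' @return An [odacs_volume()].
#' @export
read_volume <- function(path, value_kind = c("intensity", "tmax_seconds", "probability")) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) {
    stop("cannot read volume: file not found: ", path, call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d)) d <- length(img)
  # NIfTI drops trailing singleton dimensions; restore them
  if (length(d) < 3L) {
    img <- RNifti::asNifti(array(as.array(img), dim = c(d, rep(1L, 3 - length(d)))),
                           reference = img)
    d <- dim(img)
  }
  if (length(d) == 4L && d[4] == 1L) {
    img <- RNifti::asNifti(array(as.array(img), dim = d[1:3]), reference = img)
    d <- dim(img)
  }
  if (length(d) != 3L) {
    stop("expected a 3D image, got ", length(d), " dimensions in ", path,
         call. = FALSE)
  }
  orig_orient <- RNifti::orientation(img)
  if (!identical(orig_orient, "RAS")) {
    RNifti::orientation(img) <- "RAS"
  }
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("non-finite or non-positive voxel spacing in ", path, call. = FALSE)
  }
  # off-axis rotation is not applied; the pipeline assumes near-axis-aligned
  # grids (inputs are expected pre-aligned to a standard coordinate system)
  axis_dev <- max(abs(rot / rep(spacing, each = 3) - diag(3)))
  if (axis_dev > 0.01) {
    warning("image axes deviate from the canonical frame by up to ",
            signif(axis_dev, 3), "; treating the grid as axis-aligned",
            call. = FALSE)
  }
  vol <- odacs_volume(as.array(img), spacing = spacing, origin = aff[1:3, 4],
                      axis_codes = c("R", "A", "S"), value_kind = value_kind)
  attr(vol, "provenance") <- list(path = path, original_orientation = orig_orient)
  vol
}

#' Write a volume or mask as NIfTI
#'
#' Masks are stored as unsigned 8-bit 0/1 volumes; scalar volumes as
#' 32-bit float. Geometry is written into both qform and sform.
#'
#' @param x An [odacs_volume()] or [odacs_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly `path`.
#' @export
write_volume <- function(x, path) {
  stopifnot(is_odacs_volume(x) || is_odacs_mask(x))
  if (is_odacs_mask(x)) {
    arr <- array(as.integer(x$data), dim = dim(x$data))
    datatype <- "uint8"
  } else {
    arr <- x$data
    datatype <- "float"
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  aff <- rbind(cbind(diag(x$spacing), x$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI file as a binary mask
#'
#' Voxels with value strictly greater than `threshold` become true.
#'
#' @inheritParams read_volume
#' @param threshold Binarization threshold (default 0.5, so 0/1 files
#'   pass through and probability maps are cut at one half).
#' @return An [odacs_mask()].
#' @export
read_mask <- function(path, threshold = 0.5) {
  vol <- read_volume(path, value_kind = "intensity")
  m <- odacs_mask(vol$data > threshold, spacing = vol$spacing,
                  origin = vol$origin, axis_codes = vol$axis_codes)
  attr(m, "provenance") <- attr(vol, "provenance")
  m
}

#' @rdname write_volume
#' @export
write_mask <- function(x, path) {
  stopifnot(is_odacs_mask(x))
  write_volume(x, path)
}

#' Read and write midline-plane sidecar files
#'
#' The midline plane is exchanged as a small JSON document
#' `{"point_mm": [x,y,z], "normal": [nx,ny,nz]}`, the format a vendor
#' midline extraction would hand over.
#'
#' @param path Path to the JSON sidecar.
#' @return [read_midplane()] returns an [odacs_midplane()];
#'   [write_midplane()] invisibly returns `path`.
#' @export
read_midplane <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read midplane: file not found: ", path, call. = FALSE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$point_mm) || is.null(obj$normal)) {
    stop("midplane sidecar must contain 'point_mm' and 'normal'", call. = FALSE)
  }
  odacs_midplane(point = obj$point_mm, normal = obj$normal)
}

#' @rdname read_midplane
#' @param plane An [odacs_midplane()].
#' @export
write_midplane <- function(plane, path) {
  stopifnot(inherits(plane, "odacs_midplane"))
  jsonlite::write_json(
    list(point_mm = plane$point, normal = plane$normal),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' Read an affine transform file
#'
#' A plain-text file of 12 whitespace-separated numbers: the 3x3 matrix
#' in row-major order followed by the translation (mm). The transform
#' maps physical points of the moving image into the fixed (reference)
#' space.
#'
#' @param path Path to the text file.
#' @return An [odacs_affine()].
#' @export
read_affine <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read affine: file not found: ", path, call. = FALSE)
  }
  v <- scan(path, what = numeric(), quiet = TRUE)
  if (length(v) != 12L) {
    stop("affine file must contain exactly 12 numbers, got ", length(v),
         call. = FALSE)
  }
  odacs_affine(matrix = matrix(v[1:9], 3, 3, byrow = TRUE),
               translation = v[10:12])
}

report_schema_version <- "1.0"

#' Write a per-patient score report as JSON
#'
#' Serializes a score report (see [score_patient()]) to a versioned JSON
#' document. Undefined numeric fields (e.g. a ratio with zero
#' contralateral volume) are emitted as explicit JSON `null`.
#'
#' @param report An `odacs_report`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "odacs_report"))
  obj <- unclass(report)
  obj$schema_version <- report_schema_version
  res <- try(jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null", pretty = TRUE),
             silent = TRUE)
  if (inherits(res, "try-error")) {
    stop("cannot write report to ", path, ": ", attr(res, "condition")$message,
         call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read report: file not found: ", path, call. = FALSE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$schema_version <- NULL
  structure(obj, class = "odacs_report")
}
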