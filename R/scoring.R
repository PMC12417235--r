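#' Vessel volume inside a region
#'
#' Physical volume (mL) of the intersection of a vessel segmentation
#' with a region mask on the same grid.
#'
#' @param vessels Binary vessel [odacs_mask()].
#' @param region Region [odacs_mask()] on the same grid.
#' @return Volume in mL.
#' @export
vessel_volume_in_region <- function(vessels, region) {
  stopifnot(is_odacs_mask(vessels), is_odacs_mask(region))
  assert_same_grid(vessels, region)
  sum(vessels$data & region$data) * prod(vessels$spacing) / 1000
}

#' Quantitative collateral score
#'
#' The ratio of ipsilateral to contralateral vessel volume. Undefined
#' (returned as `NA` with a `reason` attribute) when the contralateral
#' volume is zero; values above 1 are permitted and not capped.
#'
#' @param ipsi_ml,contra_ml Vessel volumes in mL, both non-negative.
#' @return The ratio, or `NA` with attribute `reason`.
#' @export
quantitative_score <- function(ipsi_ml, contra_ml) {
  if (!is.finite(ipsi_ml) || !is.finite(contra_ml) || ipsi_ml < 0 || contra_ml < 0) {
    stop("vessel volumes must be finite and non-negative", call. = FALSE)
  }
  if (contra_ml == 0) {
    return(structure(NA_real_, reason = "zero contralateral vessel volume"))
  }
  ipsi_ml / contra_ml
}

#' Categorize a quantitative score on the Tan ordinal scale
#'
#' Four-level Tan grading with relaxed boundary criteria guarding
#' against minor false-positive segmentations: category 0 (absent)
#' below `low_relax` filling, 1 (poor) up to 50%, 2 (moderate) up to
#' `high_relax`, 3 (good) above. Boundary points belong to the inner
#' categories: 0 iff r < 0.05, 1 iff 0.05 <= r <= 0.50,
#' 2 iff 0.50 < r <= 0.95, 3 iff r > 0.95 (defaults). Ratios above 1
#' map to category 3.
#'
#' @param ratio Quantitative score(s); non-negative, `NA` passed through.
#' @param low_relax Relaxed lower criterion (default 0.05, i.e. 5%
#'   filling relative to the contralateral side).
#' @param high_relax Relaxed upper criterion (default 0.95).
#' @return Integer vector of categories in `0:3` (`NA` where ratio is
#'   `NA`).
#' @export
categorize <- function(ratio, low_relax = 0.05, high_relax = 0.95) {
  check_relax(low_relax, high_relax)
  ratio <- as.numeric(ratio)
  if (any(ratio < 0, na.rm = TRUE)) {
    stop("ratio must be non-negative", call. = FALSE)
  }
  out <- rep(NA_integer_, length(ratio))
  ok <- !is.na(ratio)
  r <- ratio[ok]
  out[ok] <- ifelse(r < low_relax, 0L,
             ifelse(r <= 0.5, 1L,
             ifelse(r <= high_relax, 2L, 3L)))
  out
}

#' Categorize on the extended six-level Tan scale
#'
#' Refines [categorize()] by splitting category 1 into 1a (<= 25%
#' filling) and 1b, and category 2 into 2a (<= 75%) and 2b. The
#' relaxation criteria act only on the outer boundaries, so 1a spans
#' `[low_relax, 0.25]` and 2b spans `(0.75, high_relax]`.
#'
#' @inheritParams categorize
#' @return Character vector with levels `"0"`, `"1a"`, `"1b"`, `"2a"`,
#'   `"2b"`, `"3"`.
#' @export
categorize_extended <- function(ratio, low_relax = 0.05, high_relax = 0.95) {
  base <- categorize(ratio, low_relax, high_relax)
  ratio <- as.numeric(ratio)
  out <- rep(NA_character_, length(ratio))
  ok <- !is.na(base)
  out[ok] <- as.character(base[ok])
  sel <- ok & base == 1L
  out[sel] <- ifelse(ratio[sel] <= 0.25, "1a", "1b")
  sel <- ok & base == 2L
  out[sel] <- ifelse(ratio[sel] <= 0.75, "2a", "2b")
  out
}

#' Dichotomize a Tan category
#'
#' The clinically used split: poor collaterals (categories 0-1) versus
#' good collaterals (categories 2-3).
#'
#' @param category Integer categories in `0:3` (`NA` allowed).
#' @return Character vector `"poor"`/`"good"` (`NA` preserved).
#' @export
dichotomize <- function(category) {
  category <- as.integer(category)
  if (any(!category %in% c(0:3, NA))) {
    stop("categories must lie in 0:3", call. = FALSE)
  }
  ifelse(is.na(category), NA_character_,
         ifelse(category >= 2L, "good", "poor"))
}

check_relax <- function(low_relax, high_relax) {
  if (!(is.finite(low_relax) && is.finite(high_relax) &&
        low_relax > 0 && low_relax < 0.5 &&
        high_relax > 0.5 && high_relax < 1)) {
    stop("relaxation criteria must satisfy 0 < low_relax < 0.5 < high_relax < 1",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Assemble a collateral result from regional vessel volumes
#'
#' @param method `"ODACS"` (occlusion-downstream area) or `"MCA_CS"`
#'   (MCA-territory reference).
#' @param ipsi_ml,contra_ml Regional vessel volumes in mL.
#' @param low_relax,high_relax Categorization criteria; see
#'   [categorize()].
#' @return An `odacs_collateral_result`: method, volumes, ratio,
#'   category, extended category, dichotomy, and `undefined_reason` when
#'   the ratio is undefined.
#' @export
collateral_result <- function(method = c("ODACS", "MCA_CS"), ipsi_ml, contra_ml,
                              low_relax = 0.05, high_relax = 0.95) {
  method <- match.arg(method)
  ratio <- quantitative_score(ipsi_ml, contra_ml)
  reason <- attr(ratio, "reason")
  ratio <- as.numeric(ratio)
  structure(
    list(method = method,
         ipsi_vessel_ml = ipsi_ml,
         contra_vessel_ml = contra_ml,
         ratio = ratio,
         category = categorize(ratio, low_relax, high_relax),
         extended_category = categorize_extended(ratio, low_relax, high_relax),
         dichotomy = dichotomize(categorize(ratio, low_relax, high_relax)),
         undefined_reason = if (is.null(reason)) NA_character_ else reason),
    class = "odacs_collateral_result"
  )
}

#' @export
print.odacs_collateral_result <- function(x, ...) {
  cat("<", x$method, "> ipsi ", signif(x$ipsi_vessel_ml, 4), " mL, contra ",
      signif(x$contra_vessel_ml, 4), " mL", sep = "")
  if (is.na(x$ratio)) {
    cat(" -> ratio undefined (", x$undefined_reason, ")\n", sep = "")
  } else {
    cat(" -> ratio ", signif(x$ratio, 4), ", category ", x$category,
        " (", x$extended_category, ", ", x$dichotomy, ")\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a collateral result into a one-row tibble
#'
#' @param x An `odacs_collateral_result`.
#' @param ... Unused.
#' @method tidy odacs_collateral_result
#' @export
tidy.odacs_collateral_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    ipsi_vessel_ml = x$ipsi_vessel_ml,
    contra_vessel_ml = x$contra_vessel_ml,
    ratio = x$ratio,
    category = x$category,
    extended_category = x$extended_category,
    dichotomy = x$dichotomy
  )
}

#' Occlusion-downstream area collateral score (full pipeline)
#'
#' Orchestrates the scoring pipeline: threshold the Tmax map at the
#' hypoperfusion criterion, refine the downstream area by morphological
#' closing (recovering carved-out vessels), mirror it across the midline
#' to the contralateral hemisphere, and score the ipsilateral to
#' contralateral vessel-volume ratio. Deterministic for fixed inputs and
#' configuration.
#'
#' @param vessels Binary vessel segmentation [odacs_mask()].
#' @param tmax Tmax [odacs_volume()] (`value_kind = "tmax_seconds"`) on
#'   the same grid.
#' @param plane Midline [odacs_midplane()]; defaults to the grid-centre
#'   plane.
#' @param config An [odacs_config()].
#' @return List of class `odacs_score` with `result` (an
#'   `odacs_collateral_result`), `region_pair`, and the intermediate
#'   `hypoperfusion` mask.
#' @export
compute_odacs <- function(vessels, tmax, plane = NULL, config = odacs_config()) {
  stopifnot(is_odacs_mask(vessels), is_odacs_volume(tmax))
  assert_same_grid(vessels, tmax)
  if (is.null(plane)) plane <- default_midplane(tmax)
  hypo <- threshold_hypoperfusion(tmax, config$tmax_threshold_s)
  if (voxel_count(hypo) == 0) {
    stop("no hypoperfusion: no voxels exceed Tmax ", config$tmax_threshold_s,
         " s", call. = FALSE)
  }
  refined <- refine_downstream(hypo, config$closing_semi_axes)
  pair <- build_region_pair(refined, plane,
                            overlap_warn = config$overlap_warning_fraction)
  ipsi_ml <- vessel_volume_in_region(vessels, pair$ipsilateral)
  contra_ml <- vessel_volume_in_region(vessels, pair$contralateral)
  res <- collateral_result("ODACS", ipsi_ml, contra_ml,
                           config$low_relax, config$high_relax)
  structure(list(result = res, region_pair = pair, hypoperfusion = hypo),
            class = "odacs_score")
}

#' MCA-territory reference collateral score
#'
#' The conventional reference: the same vessel-volume ratio computed
#' over the middle cerebral artery territory instead of the
#' occlusion-downstream area. The contralateral territory is the mirror
#' of the supplied ipsilateral territory mask.
#'
#' @param vessels Binary vessel segmentation [odacs_mask()].
#' @param territory_ipsi Ipsilateral MCA-territory [odacs_mask()] on the
#'   vessel grid.
#' @param plane Midline [odacs_midplane()].
#' @param config An [odacs_config()].
#' @return List of class `odacs_score` with `result` and `region_pair`.
#' @export
compute_mca_cs <- function(vessels, territory_ipsi, plane = NULL,
                           config = odacs_config()) {
  stopifnot(is_odacs_mask(vessels), is_odacs_mask(territory_ipsi))
  assert_same_grid(vessels, territory_ipsi)
  if (voxel_count(territory_ipsi) == 0) {
    stop("territory mask is empty", call. = FALSE)
  }
  if (is.null(plane)) plane <- default_midplane(vessels)
  pair <- build_region_pair(territory_ipsi, plane,
                            overlap_warn = config$overlap_warning_fraction)
  ipsi_ml <- vessel_volume_in_region(vessels, pair$ipsilateral)
  contra_ml <- vessel_volume_in_region(vessels, pair$contralateral)
  res <- collateral_result("MCA_CS", ipsi_ml, contra_ml,
                           config$low_relax, config$high_relax)
  structure(list(result = res, region_pair = pair), class = "odacs_score")
}

#' @export
print.odacs_score <- function(x, ...) {
  print(x$result)
  print(x$region_pair)
  invisible(x)
}

#' Region-wise vessel overlays for external visualization
#'
#' The two labelled masks behind the usual red/green rendering:
#' vessels restricted to the ipsilateral region and to the
#' contralateral mirrored region.
#'
#' @param vessels Binary vessel [odacs_mask()].
#' @param pair An `odacs_region_pair`.
#' @return List with `ipsilateral` and `contralateral` vessel masks.
#' @export
overlay_masks <- function(vessels, pair) {
  stopifnot(is_odacs_mask(vessels), inherits(pair, "odacs_region_pair"))
  assert_same_grid(vessels, pair$ipsilateral)
  list(
    ipsilateral = mask_like(vessels, vessels$data & pair$ipsilateral$data),
    contralateral = mask_like(vessels, vessels$data & pair$contralateral$data)
  )
}

#' Score one patient and assemble a report
#'
#' Runs the downstream-area score, optionally the MCA-territory
#' reference score, and collects everything with warnings and
#' provenance (configuration and content hashes of the inputs) into a
#' JSON-serializable report.
#'
#' @param patient_id Identifier string.
#' @param vessels Vessel segmentation [odacs_mask()].
#' @param tmax Tmax [odacs_volume()].
#' @param plane Optional [odacs_midplane()] (grid-centre default).
#' @param territory_ipsi Optional ipsilateral territory [odacs_mask()]
#'   for the reference score.
#' @param config An [odacs_config()].
#' @return An `odacs_report`; see [write_report()].
#' @export
score_patient <- function(patient_id, vessels, tmax, plane = NULL,
                          territory_ipsi = NULL, config = odacs_config()) {
  if (is.null(plane)) plane <- default_midplane(tmax)
  sc <- compute_odacs(vessels, tmax, plane, config)
  warnings <- sc$region_pair$warnings
  mca <- NULL
  if (!is.null(territory_ipsi)) {
    msc <- compute_mca_cs(vessels, territory_ipsi, plane, config)
    mca <- result_as_list(msc$result)
    warnings <- c(warnings, msc$region_pair$warnings)
  }
  structure(
    list(
      patient_id = patient_id,
      odacs = result_as_list(sc$result),
      mca_cs = mca,
      side = sc$region_pair$side,
      overlap_fraction = sc$region_pair$overlap_fraction,
      coverage_slices = sc$region_pair$coverage_slices,
      warnings = as.list(warnings),
      provenance = list(
        config = unclass(config),
        vessels_hash = rlang::hash(vessels$data),
        tmax_hash = rlang::hash(tmax$data),
        midplane = list(point_mm = plane$point, normal = plane$normal)
      )
    ),
    class = "odacs_report"
  )
}

result_as_list <- function(res) {
  list(
    method = res$method,
    ipsi_vessel_ml = res$ipsi_vessel_ml,
    contra_vessel_ml = res$contra_vessel_ml,
    ratio = if (is.na(res$ratio)) NULL else res$ratio,
    category = if (is.na(res$category)) NULL else res$category,
    extended_category = if (is.na(res$extended_category)) NULL else res$extended_category,
    dichotomy = if (is.na(res$dichotomy)) NULL else res$dichotomy,
    undefined_reason = if (is.na(res$undefined_reason)) NULL else res$undefined_reason
  )
}
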