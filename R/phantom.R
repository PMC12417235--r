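#' Specification of a synthetic stroke phantom
#'
#' Describes a paired CTA/CTP phantom with known ground truth: tubular
#' vessels placed mirror-symmetrically about the midline except for a
#' controllable volume deficit inside a one-sided hypoperfusion lesion,
#' a Tmax map with the lesion above the hypoperfusion threshold, and
#' optional carving of vessel voxels out of the lesion (emulating
#' vendor CTP software, which removes vessels from its analysis — the
#' artifact the morphological-closing refinement exists to undo).
#'
#' Defaults emulate the study's data regime at desk scale: strongly
#' anisotropic 5 mm slices, a unilateral MCA-like lesion of a few
#' hundred mL-scale voxels, and vessel radii of large-vessel calibre.
#'
#' @param grid_shape Grid size (voxels), default `c(64, 64, 16)`.
#' @param spacing_mm Voxel spacing, default `c(2, 2, 5)` mm.
#' @param n_vessels_per_side Number of tubular vessels inside the
#'   lesion per hemisphere (before the deficit is applied).
#' @param vessel_radius_mm Capsule radius in mm.
#' @param target_ratio Desired ipsilateral/contralateral vessel-volume
#'   ratio inside the downstream region, in `[0, 1.5]`.
#' @param lesion_center_frac Lesion centre as fractions of the grid
#'   extent (first component < 0.5 places the lesion in the left
#'   hemisphere).
#' @param lesion_semi_axes_mm Ellipsoidal lesion semi-axes in mm.
#' @param tmax_background_s,tmax_lesion_s Tmax values (s) outside and
#'   inside the lesion; the lesion must exceed 6 s and the background
#'   stay below it.
#' @param carve_vessels_from_tmax If true, vessel voxels inside the
#'   lesion are reset to background Tmax, so only the closing
#'   refinement can return them to the downstream region.
#' @param n_background_vessels Mirror-symmetric vessels outside the
#'   lesion (inside the hemispheric territory), identical on both
#'   sides; these separate the territory-wide score from the
#'   downstream-area score.
#' @param noise_sd Additive Gaussian noise SD on the CTA-like intensity
#'   volume (vessel contrast is 1).
#' @param seed Integer seed; generation is deterministic given the
#'   spec.
#' @return An `odacs_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 16),
                         spacing_mm = c(2, 2, 5),
                         n_vessels_per_side = 8L,
                         vessel_radius_mm = 2.0,
                         target_ratio = 0.5,
                         lesion_center_frac = c(0.28, 0.5, 0.5),
                         lesion_semi_axes_mm = c(24, 30, 18),
                         tmax_background_s = 0.5,
                         tmax_lesion_s = 10,
                         carve_vessels_from_tmax = TRUE,
                         n_background_vessels = 6L,
                         noise_sd = 0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            n_vessels_per_side >= 1L, vessel_radius_mm > 0,
            is.finite(target_ratio), target_ratio >= 0, target_ratio <= 1.5,
            all(lesion_center_frac > 0), all(lesion_center_frac < 1),
            all(lesion_semi_axes_mm > 0),
            noise_sd >= 0)
  if (!(tmax_lesion_s > 6.0 && tmax_background_s < 6.0)) {
    stop("phantom lesion Tmax must exceed 6 s and background stay below it",
         call. = FALSE)
  }
  structure(
    list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
         n_vessels_per_side = as.integer(n_vessels_per_side),
         vessel_radius_mm = vessel_radius_mm, target_ratio = target_ratio,
         lesion_center_frac = as.numeric(lesion_center_frac),
         lesion_semi_axes_mm = as.numeric(lesion_semi_axes_mm),
         tmax_background_s = tmax_background_s, tmax_lesion_s = tmax_lesion_s,
         carve_vessels_from_tmax = isTRUE(carve_vessels_from_tmax),
         n_background_vessels = as.integer(n_background_vessels),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "odacs_phantom_spec"
  )
}

# Linear voxel indices of a capsule (line segment with radius) clipped
# to the grid, plus the axial parameter t of each voxel for ordered
# truncation.
rasterize_capsule <- function(d, spacing, origin, p1, p2, radius_mm) {
  lo <- pmin(p1, p2) - radius_mm
  hi <- pmax(p1, p2) + radius_mm
  i_lo <- pmax(1L, floor((lo - origin) / spacing + 1))
  i_hi <- pmin(d, ceiling((hi - origin) / spacing + 1))
  if (any(i_lo > i_hi)) {
    return(list(lin = integer(), t = numeric()))
  }
  idx <- as.matrix(expand.grid(i = i_lo[1]:i_hi[1], j = i_lo[2]:i_hi[2],
                               k = i_lo[3]:i_hi[3]))
  pts <- sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
  u <- p2 - p1
  uu <- sum(u^2)
  w <- sweep(pts, 2, p1, "-")
  t <- if (uu > 0) pmin(1, pmax(0, as.numeric(w %*% u) / uu)) else
    rep(0, nrow(pts))
  proj <- sweep(t %o% u, 2, p1, "+") + 0  # closest points on the segment
  dist2 <- rowSums((pts - proj)^2)
  keep <- dist2 <= radius_mm^2
  lin <- (idx[keep, 3] - 1L) * d[1] * d[2] + (idx[keep, 2] - 1L) * d[1] +
    idx[keep, 1]
  list(lin = as.integer(lin), t = t[keep])
}

# Mirror linear indices across the grid-symmetric default plane
# (first-axis index flip).
mirror_linear <- function(lin, d) {
  i <- (lin - 1L) %% d[1] + 1L
  rest <- lin - i
  rest + (d[1] + 1L - i)
}

#' Generate a synthetic stroke phantom with known ground truth
#'
#' Builds the phantom described by a [phantom_spec()]: a one-sided
#' ellipsoidal Tmax lesion, mirror-symmetric tubular vessels with the
#' ipsilateral set reduced (or the contralateral set, for target ratios
#' above 1) so that the brute-force vessel-volume ratio inside the
#' refined downstream region equals `target_ratio` to within one voxel,
#' symmetric background vessels outside the lesion, a hemispheric
#' territory mask, and a CTA-like intensity volume. The calibration
#' counts voxels directly rather than trusting analytic capsule
#' volumes, so the recorded truth absorbs all rasterization error.
#'
#' @param spec An [phantom_spec()].
#' @return An `odacs_phantom`: list with `vessel_mask`, `tmax`, `cta`,
#'   `plane`, `territory_ipsi`, `region_ipsi` (the truth downstream
#'   region), `truth_ipsi_ml`, `truth_contra_ml`, `truth_ratio`,
#'   `side`, and the `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "odacs_phantom_spec"))
  set.seed(spec$seed)
  d <- spec$grid_shape
  spacing <- spec$spacing_mm
  origin <- c(0, 0, 0)
  voxvol_ml <- prod(spacing) / 1000
  extent <- (d - 1) * spacing

  geom_ref <- odacs_mask(array(FALSE, dim = d), spacing = spacing,
                         origin = origin)
  plane <- default_midplane(geom_ref)

  # lesion (hypoperfusion) ellipsoid, one-sided: shift the centre
  # laterally if needed so the lesion clears the midplane (clipping at
  # the outer grid border is acceptable, crossing the midline is not)
  centre <- origin + spec$lesion_center_frac * extent
  clearance <- 3 * spacing[1]
  if (centre[1] <= plane$point[1]) {
    limit <- plane$point[1] - clearance - spec$lesion_semi_axes_mm[1]
    centre[1] <- min(centre[1], limit)
  } else {
    limit <- plane$point[1] + clearance + spec$lesion_semi_axes_mm[1]
    centre[1] <- max(centre[1], limit)
  }
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  pts <- sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
  r2 <- rowSums(sweep(sweep(pts, 2, centre, "-"), 2,
                      spec$lesion_semi_axes_mm, "/")^2)
  lesion <- array(r2 <= 1, dim = d)
  side <- if (centre[1] < plane$point[1]) "left" else "right"

  # truth downstream region: lesion closed with the default element,
  # and its exact mirror
  lesion_mask <- mask_like(geom_ref, lesion)
  region_ipsi <- close_mask(lesion_mask, ellipsoid_element(c(10, 10, 1)))
  region_lin <- which(region_ipsi$data)
  region_contra_lin <- mirror_linear(region_lin, d)

  # base vessels: capsules inside the lesion (sampled well inside so
  # rasterized tubes stay within the region), mostly in-plane
  sample_capsule_in_lesion <- function() {
    repeat {
      c1 <- centre + stats::runif(3, -0.55, 0.55) * spec$lesion_semi_axes_mm
      dir <- c(stats::rnorm(2), stats::rnorm(1) * 0.15)
      dir <- dir / sqrt(sum(dir^2))
      len <- stats::runif(1, 0.5, 1.2) * spec$lesion_semi_axes_mm[1]
      c2 <- c1 + dir * len
      # keep both endpoints inside the shrunken lesion
      ok <- function(p) sum(((p - centre) / (spec$lesion_semi_axes_mm - spec$vessel_radius_mm))^2) <= 0.8
      if (ok(c1) && ok(c2)) return(list(p1 = c1, p2 = c2))
    }
  }
  tubes <- lapply(seq_len(spec$n_vessels_per_side), function(i) {
    seg <- sample_capsule_in_lesion()
    rasterize_capsule(d, spacing, origin, seg$p1, seg$p2,
                      spec$vessel_radius_mm)
  })
  tubes <- Filter(function(t) length(t$lin) > 0, tubes)
  if (!length(tubes)) stop("phantom generation failed: no vessel voxels rasterized",
                           call. = FALSE)

  # restrict tubes to the truth region (they are constructed inside it)
  in_region <- array(FALSE, dim = d); in_region[region_lin] <- TRUE
  tubes <- lapply(tubes, function(t) {
    keep <- in_region[t$lin]
    list(lin = t$lin[keep], t = t$t[keep])
  })
  base_union <- unique(unlist(lapply(tubes, `[[`, "lin")))
  U <- length(base_union)
  if (U == 0) stop("phantom generation failed: vessels fell outside the region",
                   call. = FALSE)

  # greedy union-based selection of a voxel subset of the tubes whose
  # size hits `target`; partial tubes are truncated along their axis
  select_subset <- function(target_n) {
    selected <- logical(prod(d))
    count <- 0L
    for (tb in tubes) {
      if (count >= target_n) break
      novel <- tb$lin[!selected[tb$lin]]
      novel_t <- tb$t[!selected[tb$lin]]
      if (!length(novel)) next
      if (count + length(novel) <= target_n) {
        selected[novel] <- TRUE
        count <- count + length(novel)
      } else {
        ord <- order(novel_t, novel)
        take <- novel[ord][seq_len(target_n - count)]
        selected[take] <- TRUE
        count <- target_n
      }
    }
    which(selected)
  }

  if (spec$target_ratio <= 1) {
    ipsi_lin <- select_subset(round(spec$target_ratio * U))
    contra_lin <- mirror_linear(base_union, d)
  } else {
    ipsi_lin <- base_union
    n_contra <- round(U / spec$target_ratio)
    if (n_contra < 1) {
      stop("infeasible target_ratio for this phantom geometry", call. = FALSE)
    }
    contra_lin <- mirror_linear(select_subset(n_contra), d)
  }

  # symmetric background vessels outside the lesion, inside the
  # hemispheric territory; excluded from both downstream regions so the
  # truth ratio stays exact
  territory_ipsi <- synthetic_territory(geom_ref, plane, side,
                                        margin_voxels = 2L)
  bg_lin <- integer()
  if (spec$n_background_vessels > 0) {
    terr_lin_set <- array(FALSE, dim = d)
    terr_lin_set[which(territory_ipsi$data)] <- TRUE
    hemi_lo <- origin[1] + 0.05 * extent[1]
    hemi_hi <- plane$point[1] - 0.15 * extent[1]
    if (side == "right") {
      hemi_lo <- plane$point[1] + 0.15 * extent[1]
      hemi_hi <- origin[1] + 0.95 * extent[1]
    }
    for (i in seq_len(spec$n_background_vessels)) {
      p1 <- c(stats::runif(1, hemi_lo, hemi_hi),
              stats::runif(1, 0.1, 0.9) * extent[2],
              stats::runif(1, 0.15, 0.85) * extent[3])
      dir <- c(stats::rnorm(2), stats::rnorm(1) * 0.2)
      dir <- dir / sqrt(sum(dir^2))
      p2 <- p1 + dir * stats::runif(1, 15, 40)
      cap <- rasterize_capsule(d, spacing, origin, p1, p2,
                               spec$vessel_radius_mm)
      bg_lin <- c(bg_lin, cap$lin)
    }
    bg_lin <- unique(bg_lin)
    # keep only voxels in the territory and outside both regions
    keep <- terr_lin_set[bg_lin]
    bg_lin <- bg_lin[keep]
    off_region <- array(TRUE, dim = d)
    off_region[region_lin] <- FALSE
    off_region[region_contra_lin] <- FALSE
    bg_lin <- bg_lin[off_region[bg_lin]]
    bg_lin <- unique(c(bg_lin, mirror_linear(bg_lin, d)))
  }

  vessels <- array(FALSE, dim = d)
  vessels[ipsi_lin] <- TRUE
  vessels[contra_lin] <- TRUE
  vessels[bg_lin] <- TRUE
  vessel_mask <- mask_like(geom_ref, vessels)

  # truth by brute-force intersection counting
  in_contra <- array(FALSE, dim = d); in_contra[region_contra_lin] <- TRUE
  truth_ipsi <- sum(vessels & in_region) * voxvol_ml
  truth_contra <- sum(vessels & in_contra) * voxvol_ml
  truth_ratio <- if (truth_contra > 0) truth_ipsi / truth_contra else NA_real_
  if (!is.na(truth_ratio) && abs(truth_ratio - spec$target_ratio) > 0.02) {
    stop(sprintf("phantom calibration failed: truth ratio %.3f vs target %.3f",
                 truth_ratio, spec$target_ratio), call. = FALSE)
  }

  # Tmax map, with optional vessel carving inside the lesion
  tmax_arr <- array(spec$tmax_background_s, dim = d)
  tmax_arr[lesion] <- spec$tmax_lesion_s
  if (spec$carve_vessels_from_tmax) {
    tmax_arr[vessels & lesion] <- spec$tmax_background_s
  }
  tmax <- odacs_volume(tmax_arr, spacing = spacing, origin = origin,
                       value_kind = "tmax_seconds")

  # CTA-like intensity volume (vessel contrast 1 plus optional noise)
  cta_arr <- array(0, dim = d)
  cta_arr[vessels] <- 1
  if (spec$noise_sd > 0) {
    cta_arr <- cta_arr + stats::rnorm(length(cta_arr), sd = spec$noise_sd)
  }
  cta <- odacs_volume(cta_arr, spacing = spacing, origin = origin,
                      value_kind = "intensity")

  structure(
    list(vessel_mask = vessel_mask, tmax = tmax, cta = cta, plane = plane,
         territory_ipsi = territory_ipsi, region_ipsi = region_ipsi,
         truth_ipsi_ml = truth_ipsi, truth_contra_ml = truth_contra,
         truth_ratio = truth_ratio, side = side, spec = spec),
    class = "odacs_phantom"
  )
}

#' @export
print.odacs_phantom <- function(x, ...) {
  cat("<odacs_phantom> ", paste(dim(x$tmax$data), collapse = "x"),
      " grid, side ", x$side, ", truth ratio ",
      signif(x$truth_ratio, 4), " (ipsi ", signif(x$truth_ipsi_ml, 4),
      " mL / contra ", signif(x$truth_contra_ml, 4), " mL)\n", sep = "")
  invisible(x)
}

#' Write a phantom's volumes and truth to a directory
#'
#' Emits `vessels.nii.gz`, `tmax.nii.gz`, `cta.nii.gz`,
#' `territory.nii.gz`, `midplane.json` and `truth.json`.
#'
#' @param phantom An `odacs_phantom`.
#' @param dir Output directory (created if absent).
#' @return Invisibly `dir`.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "odacs_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mask(phantom$vessel_mask, file.path(dir, "vessels.nii.gz"))
  write_volume(phantom$tmax, file.path(dir, "tmax.nii.gz"))
  write_volume(phantom$cta, file.path(dir, "cta.nii.gz"))
  write_mask(phantom$territory_ipsi, file.path(dir, "territory.nii.gz"))
  write_midplane(phantom$plane, file.path(dir, "midplane.json"))
  jsonlite::write_json(
    list(truth_ipsi_ml = phantom$truth_ipsi_ml,
         truth_contra_ml = phantom$truth_contra_ml,
         truth_ratio = phantom$truth_ratio,
         side = phantom$side,
         seed = phantom$spec$seed,
         target_ratio = phantom$spec$target_ratio),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(dir)
}

#' Threshold-based fallback vessel segmenter
#'
#' A deliberately simple stand-in for a learned CTA vessel
#' segmentation, sufficient for phantoms: intensity thresholding with
#' optional removal of small connected components (6-connectivity).
#'
#' @param cta_like An intensity [odacs_volume()].
#' @param intensity_threshold Voxels strictly above this become vessel.
#' @param min_component_voxels Components smaller than this are
#'   removed; 0 disables cleaning.
#' @return Vessel [odacs_mask()].
#' @export
fallback_segment <- function(cta_like, intensity_threshold = 0.5,
                             min_component_voxels = 0L) {
  stopifnot(is_odacs_volume(cta_like))
  m <- cta_like$data > intensity_threshold
  if (min_component_voxels > 0 && any(m)) {
    lab <- label_components_6(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component_voxels)
    m <- array(lab %in% keep, dim = dim(m))
  }
  mask_like(cta_like, m)
}

# 6-connectivity component labelling by repeated label propagation
# (minimum-label flooding); adequate for sparse vessel masks.
label_components_6 <- function(m) {
  d <- dim(m)
  lab <- array(0L, dim = d)
  lab[m] <- seq_len(sum(m))
  shift_min <- function(l) {
    out <- l
    # propagate the minimum positive label from the 6 neighbours
    nb <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
    for (o in nb) {
      src_i <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
      dst_i <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
      src_j <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
      dst_j <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
      src_k <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
      dst_k <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
      nbr <- array(0L, dim = d)
      nbr[dst_i, dst_j, dst_k] <- l[src_i, src_j, src_k]
      upd <- m & nbr > 0 & (out == 0 | nbr < out)
      out[upd] <- nbr[upd]
    }
    out
  }
  repeat {
    new_lab <- shift_min(lab)
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  # renumber to consecutive labels
  u <- sort(unique(lab[lab > 0]))
  if (length(u)) lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

#' Generate a synthetic scored cohort
#'
#' Draws `n` phantom patients stratified over occlusion locations with
#' the study-like prevalence (52% proximal M1, 32% distal M1, 16% M2)
#' and location-dependent lesion sizes (more distal occlusions give
#' smaller hypoperfused volumes), scores each with the full pipeline
#' (downstream-area and territory scores, using the truth vessel
#' segmentation), and adds two synthetic raters who grade a noisy
#' version of the truth ratio on the Tan scale.
#'
#' @param n Number of patients.
#' @param seed Integer seed.
#' @param ratio_range Range of the uniform target-ratio distribution
#'   (default `c(0.1, 1.1)`).
#' @param grid_shape,spacing_mm Forwarded to [phantom_spec()].
#' @param carve Whether vessels are carved out of the Tmax maps.
#' @param config Pipeline [odacs_config()].
#' @param keep_phantoms Whether to return the phantom objects.
#' @return List with `table` (cohort tibble, see [read_cohort_csv()]
#'   for the schema, plus `truth_ratio` and `lesion_ml` columns) and
#'   `phantoms` (list, empty unless `keep_phantoms`).
#' @export
generate_cohort <- function(n, seed = 1L, ratio_range = c(0.1, 1.1),
                            grid_shape = c(64, 64, 16),
                            spacing_mm = c(2, 2, 5),
                            carve = TRUE, config = odacs_config(),
                            keep_phantoms = FALSE) {
  stopifnot(n >= 1)
  set.seed(seed)
  locations <- sample(c("proximal_M1", "distal_M1", "M2"), n, replace = TRUE,
                      prob = c(0.52, 0.32, 0.16))
  # lesion size gradient: distal occlusions hypoperfuse smaller volumes
  lesion_axes <- list(
    proximal_M1 = c(28, 34, 22),
    distal_M1 = c(22, 26, 16),
    M2 = c(14, 18, 11)
  )
  target_ratios <- stats::runif(n, ratio_range[1], ratio_range[2])
  seeds <- sample.int(1e6, n)
  rater_noise <- matrix(stats::rnorm(2 * n, sd = 0.12), ncol = 2)
  rows <- vector("list", n)
  phantoms <- if (keep_phantoms) vector("list", n) else list()
  for (i in seq_len(n)) {
    sp <- phantom_spec(grid_shape = grid_shape, spacing_mm = spacing_mm,
                       target_ratio = target_ratios[i],
                       lesion_semi_axes_mm = lesion_axes[[locations[i]]],
                       carve_vessels_from_tmax = carve,
                       seed = seeds[i])
    ph <- generate_phantom(sp)
    sc <- compute_odacs(ph$vessel_mask, ph$tmax, ph$plane, config)
    mc <- compute_mca_cs(ph$vessel_mask, ph$territory_ipsi, ph$plane, config)
    r1 <- categorize(max(0, ph$truth_ratio + rater_noise[i, 1]))
    r2 <- categorize(max(0, ph$truth_ratio + rater_noise[i, 2]))
    rows[[i]] <- tibble::tibble(
      patient_id = sprintf("P%03d", i),
      occlusion_location = locations[i],
      odacs_ratio = sc$result$ratio,
      mca_ratio = mc$result$ratio,
      odacs_category = sc$result$category,
      mca_category = mc$result$category,
      rater_R1 = r1,
      rater_R2 = r2,
      truth_ratio = ph$truth_ratio,
      lesion_ml = mask_volume_ml(sc$region_pair$ipsilateral)
    )
    if (keep_phantoms) phantoms[[i]] <- ph
  }
  list(table = dplyr::bind_rows(rows), phantoms = phantoms)
}
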