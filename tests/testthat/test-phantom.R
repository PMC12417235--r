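test_that("phantom generation is deterministic for a fixed seed", {
  s <- phantom_spec(target_ratio = 0.7, seed = 9)
  p1 <- generate_phantom(s)
  p2 <- generate_phantom(s)
  expect_identical(p1$vessel_mask$data, p2$vessel_mask$data)
  expect_identical(p1$tmax$data, p2$tmax$data)
  expect_identical(p1$truth_ratio, p2$truth_ratio)
  # different seeds vary the anatomy
  p3 <- generate_phantom(phantom_spec(target_ratio = 0.7, seed = 10))
  expect_false(identical(p1$vessel_mask$data, p3$vessel_mask$data))
})

test_that("calibrated truth ratios are verified by direct voxel counting", {
  for (target in c(0.3, 0.5, 0.9)) {
    ph <- generate_phantom(phantom_spec(target_ratio = target, seed = 31))
    # brute-force recount from the stored truth masks
    region <- ph$region_ipsi$data
    contra <- mirror_mask(ph$region_ipsi, ph$plane)$data
    n_ipsi <- sum(ph$vessel_mask$data & region)
    n_contra <- sum(ph$vessel_mask$data & contra)
    vox_ml <- prod(ph$vessel_mask$spacing) / 1000
    expect_equal(ph$truth_ipsi_ml, n_ipsi * vox_ml, tolerance = 1e-12)
    expect_equal(ph$truth_contra_ml, n_contra * vox_ml, tolerance = 1e-12)
    expect_equal(ph$truth_ratio, n_ipsi / n_contra, tolerance = 1e-12)
    expect_lt(abs(ph$truth_ratio - target), 0.02)
  }
})

test_that("phantom specs reject unphysical Tmax configurations", {
  expect_error(phantom_spec(tmax_lesion_s = 5), "exceed 6")
  expect_error(phantom_spec(tmax_background_s = 7), "exceed 6")
  expect_error(phantom_spec(target_ratio = 2), "target_ratio")
})

test_that("vessel carving removes lesion vessels from the Tmax map only", {
  sp <- phantom_spec(target_ratio = 0.5, seed = 41, carve_vessels_from_tmax = TRUE)
  ph <- generate_phantom(sp)
  sp0 <- phantom_spec(target_ratio = 0.5, seed = 41, carve_vessels_from_tmax = FALSE)
  ph0 <- generate_phantom(sp0)
  expect_identical(ph$vessel_mask$data, ph0$vessel_mask$data)
  carved <- ph0$tmax$data > 6 & !(ph$tmax$data > 6)
  expect_true(all(ph$vessel_mask$data[carved]))
  expect_gt(sum(carved), 0)
})

test_that("ratios above one swap the deficit to the contralateral side", {
  ph <- generate_phantom(phantom_spec(target_ratio = 1.4, seed = 51))
  expect_equal(ph$truth_ratio, 1.4, tolerance = 0.02)
  sc <- compute_odacs(ph$vessel_mask, ph$tmax, ph$plane)
  expect_equal(sc$result$ratio, ph$truth_ratio, tolerance = 0.05)
  expect_equal(sc$result$category, 3L)
})

test_that("the fallback segmenter recovers the truth mask from a clean phantom", {
  ph <- generate_phantom(phantom_spec(target_ratio = 0.5, seed = 61, noise_sd = 0))
  seg <- fallback_segment(ph$cta, 0.5)
  expect_identical(seg$data, ph$vessel_mask$data)
  # threshold above all intensities gives an empty mask
  expect_equal(voxel_count(fallback_segment(ph$cta, 2)), 0)
})

test_that("the fallback segmenter stays accurate under additive noise", {
  ph <- generate_phantom(phantom_spec(target_ratio = 0.5, seed = 62,
                                      noise_sd = 0.1))
  seg <- fallback_segment(ph$cta, 0.5)
  truth <- ph$vessel_mask$data
  dice <- 2 * sum(seg$data & truth) / (sum(seg$data) + sum(truth))
  expect_gt(dice, 0.9)
  # component cleaning keeps accuracy while dropping isolated specks
  seg_clean <- fallback_segment(ph$cta, 0.5, min_component_voxels = 3)
  dice_clean <- 2 * sum(seg_clean$data & truth) /
    (sum(seg_clean$data) + sum(truth))
  expect_gt(dice_clean, 0.9)
  expect_lte(sum(seg_clean$data & !truth), sum(seg$data & !truth))
})

test_that("connected component labelling separates disjoint blobs", {
  arr <- array(FALSE, dim = c(12, 12, 3))
  arr[2:3, 2:3, 1] <- TRUE
  arr[8:10, 8:10, 2] <- TRUE
  arr[6, 1, 3] <- TRUE
  v <- odacs_volume(arr + 0)
  seg <- fallback_segment(v, 0.5, min_component_voxels = 2)
  expect_equal(sum(seg$data), sum(arr) - 1)  # the singleton is removed
  expect_false(seg$data[6, 1, 3])
})

test_that("synthetic cohorts are reproducible and carry the expected schema", {
  co <- generate_cohort(6, seed = 5, grid_shape = c(48, 48, 12))
  co2 <- generate_cohort(6, seed = 5, grid_shape = c(48, 48, 12))
  expect_identical(co$table, co2$table)
  expect_equal(nrow(co$table), 6)
  expect_true(all(c("patient_id", "occlusion_location", "odacs_ratio",
                    "mca_ratio", "odacs_category", "mca_category",
                    "rater_R1", "rater_R2", "truth_ratio", "lesion_ml") %in%
                  names(co$table)))
  expect_true(all(co$table$occlusion_location %in%
                  c("proximal_M1", "distal_M1", "M2")))
  # pipeline recovers the truth ratio on every cohort member
  expect_true(all(abs(co$table$odacs_ratio - co$table$truth_ratio) <= 0.05))
})

test_that("phantom directories round-trip through the NIfTI pipeline", {
  ph <- generate_phantom(phantom_spec(target_ratio = 0.5, seed = 71))
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  vessels <- read_mask(file.path(dir, "vessels.nii.gz"))
  tmax <- read_volume(file.path(dir, "tmax.nii.gz"), value_kind = "tmax_seconds")
  plane <- read_midplane(file.path(dir, "midplane.json"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  sc <- compute_odacs(vessels, tmax, plane)
  expect_equal(sc$result$ratio, truth$truth_ratio, tolerance = 0.02)
})
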