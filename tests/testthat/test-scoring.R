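test_that("regional vessel volume converts intersection counts to mL", {
  d <- c(20, 20, 10)
  vessels <- odacs_mask(array(FALSE, dim = d))
  region <- odacs_mask(array(FALSE, dim = d))
  vessels$data[1:10, 1:10, 1:10] <- TRUE
  region$data[1:10, 1:10, 1:10] <- TRUE
  expect_equal(vessel_volume_in_region(vessels, region), 1.0)  # 1000 voxels at 1 mm^3
  # disjoint masks
  region2 <- odacs_mask(array(FALSE, dim = d))
  region2$data[11:20, 11:20, 1:10] <- TRUE
  expect_equal(vessel_volume_in_region(vessels, region2), 0.0)
  # anisotropic voxels: 200 voxels at 5 mm^3
  va <- odacs_mask(array(FALSE, dim = d), spacing = c(1, 1, 5))
  ra <- odacs_mask(array(FALSE, dim = d), spacing = c(1, 1, 5))
  va$data[1:10, 1:10, 1:2] <- TRUE
  ra$data[1:10, 1:10, 1:2] <- TRUE
  expect_equal(vessel_volume_in_region(va, ra), 1.0)
  # grid mismatch propagates
  expect_error(vessel_volume_in_region(vessels, ra), "grid mismatch")
})

test_that("quantitative score is the uncapped ipsi/contra ratio", {
  expect_equal(quantitative_score(10, 20), 0.5)
  expect_equal(quantitative_score(20, 10), 2.0)
  u <- quantitative_score(5, 0)
  expect_true(is.na(u))
  expect_match(attr(u, "reason"), "contralateral")
  expect_error(quantitative_score(-1, 5), "non-negative")
})

test_that("Tan categorization applies the relaxed boundary rules", {
  expect_equal(categorize(0.04), 0L)
  expect_equal(categorize(0.50), 1L)
  expect_equal(categorize(0.75), 2L)
  expect_equal(categorize(0.97), 3L)
  # boundary semantics: boundary points join the inner categories
  expect_equal(categorize(c(0, 0.05, 0.95, 1.2)), c(0L, 1L, 2L, 3L))
  expect_error(categorize(-0.1), "non-negative")
  expect_error(categorize(0.5, low_relax = 0.6), "relax")
  expect_true(is.na(categorize(NA_real_)))
})

test_that("extended categorization refines the base scale", {
  expect_equal(categorize_extended(0.20), "1a")
  expect_equal(categorize_extended(0.25), "1a")
  expect_equal(categorize_extended(0.40), "1b")
  expect_equal(categorize_extended(0.60), "2a")
  expect_equal(categorize_extended(0.90), "2b")
  expect_equal(categorize_extended(c(0.02, 0.98)), c("0", "3"))
  # refinement property on a dense ratio grid
  r <- seq(0, 10, by = 1e-3)
  base <- categorize(r)
  ext <- categorize_extended(r)
  expect_true(all(substr(ext, 1, 1) == as.character(base)))
  # monotone non-decreasing in the ratio
  expect_true(all(diff(base) >= 0))
})

test_that("dichotomy splits poor (0-1) from good (2-3)", {
  expect_equal(dichotomize(c(0, 1, 2, 3)), c("poor", "poor", "good", "good"))
  expect_true(is.na(dichotomize(NA)))
  expect_error(dichotomize(5), "0:3")
})

test_that("collateral results are scale invariant in the vessel volumes", {
  set.seed(2)
  for (rep in 1:20) {
    ipsi <- runif(1, 0, 5); contra <- runif(1, 0.1, 5); k <- runif(1, 0.1, 10)
    r1 <- collateral_result("ODACS", ipsi, contra)
    r2 <- collateral_result("ODACS", k * ipsi, k * contra)
    expect_equal(r2$ratio, r1$ratio, tolerance = 1e-12)
    expect_equal(r2$category, r1$category)
    expect_equal(r2$extended_category, r1$extended_category)
  }
  u <- collateral_result("ODACS", 1, 0)
  expect_true(is.na(u$ratio) && is.na(u$category))
  expect_match(u$undefined_reason, "contralateral")
  td <- tidy(collateral_result("MCA_CS", 1, 2))
  expect_s3_class(td, "tbl_df")
  expect_equal(td$ratio, 0.5)
})

test_that("the full pipeline recovers phantom ground truth", {
  ph <- generate_phantom(phantom_spec(target_ratio = 0.45, seed = 101))
  sc <- compute_odacs(ph$vessel_mask, ph$tmax, ph$plane)
  expect_equal(sc$result$ratio, 0.45, tolerance = 0.02)
  expect_equal(sc$result$category, 1L)
  # symmetric phantom: identical vessels both sides
  ph1 <- generate_phantom(phantom_spec(target_ratio = 1.0, seed = 102))
  sc1 <- compute_odacs(ph1$vessel_mask, ph1$tmax, ph1$plane)
  expect_equal(sc1$result$ratio, 1.0, tolerance = 0.02)
  expect_equal(sc1$result$category, 3L)
  # vessels only contralateral
  ph0 <- generate_phantom(phantom_spec(target_ratio = 0, seed = 103))
  sc0 <- compute_odacs(ph0$vessel_mask, ph0$tmax, ph0$plane)
  expect_equal(sc0$result$ratio, 0)
  expect_equal(sc0$result$category, 0L)
})

test_that("scoring a Tmax map without hypoperfusion is an explicit error", {
  d <- c(16, 16, 4)
  vessels <- odacs_mask(array(FALSE, dim = d)); vessels$data[3, 3, 2] <- TRUE
  tmax <- odacs_volume(array(1, dim = d), value_kind = "tmax_seconds")
  expect_error(compute_odacs(vessels, tmax), "no hypoperfusion")
})

test_that("territory score uses the mirrored territory as reference", {
  ph <- generate_phantom(phantom_spec(target_ratio = 1.0, seed = 104))
  mc <- compute_mca_cs(ph$vessel_mask, ph$territory_ipsi, ph$plane)
  expect_equal(mc$result$ratio, 1.0, tolerance = 0.02)
  expect_equal(mc$result$category, 3L)
  empty_terr <- odacs_mask(array(FALSE, dim = dim(ph$vessel_mask$data)),
                           spacing = ph$vessel_mask$spacing)
  expect_error(compute_mca_cs(ph$vessel_mask, empty_terr, ph$plane), "empty")
})

test_that("deficits confined to the downstream region depress its score below the territory score", {
  for (seed in c(11, 12, 13)) {
    ph <- generate_phantom(phantom_spec(target_ratio = 0.4, seed = seed))
    sc <- compute_odacs(ph$vessel_mask, ph$tmax, ph$plane)
    mc <- compute_mca_cs(ph$vessel_mask, ph$territory_ipsi, ph$plane)
    expect_lte(sc$result$ratio, mc$result$ratio)
  }
})

test_that("repeated runs yield byte-identical reports", {
  ph <- generate_phantom(phantom_spec(target_ratio = 0.6, seed = 105))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(score_patient("x", ph$vessel_mask, ph$tmax, ph$plane,
                             ph$territory_ipsi), p1)
  write_report(score_patient("x", ph$vessel_mask, ph$tmax, ph$plane,
                             ph$territory_ipsi), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("overlay masks split vessels by region", {
  ph <- generate_phantom(phantom_spec(target_ratio = 0.5, seed = 106))
  sc <- compute_odacs(ph$vessel_mask, ph$tmax, ph$plane)
  ov <- overlay_masks(ph$vessel_mask, sc$region_pair)
  expect_equal(mask_volume_ml(ov$ipsilateral), sc$result$ipsi_vessel_ml)
  expect_equal(mask_volume_ml(ov$contralateral), sc$result$contra_vessel_ml)
  expect_equal(sum(ov$ipsilateral$data & ov$contralateral$data), 0)
})
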