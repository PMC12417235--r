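test_that("weighted kappa is 1 for identical labels and <= 0 against a constant rater", {
  a <- c(0, 1, 2, 3, 2, 1, 0, 3)
  expect_equal(as.numeric(weighted_kappa(a, a)), 1.0)
  b <- rep(2, 6)
  a6 <- c(0, 1, 2, 3, 0, 1)
  k <- weighted_kappa(a6, b)
  expect_lte(as.numeric(k), 0)
  expect_equal(as.numeric(k), brute_weighted_kappa(a6, b), tolerance = 1e-12)
})

test_that("weighted kappa matches the from-definition oracle on random label pairs", {
  set.seed(61)
  for (rep in 1:25) {
    a <- sample(0:3, 50, replace = TRUE)
    b <- ifelse(runif(50) < 0.6, a, sample(0:3, 50, replace = TRUE))
    expect_equal(as.numeric(weighted_kappa(a, b)),
                 brute_weighted_kappa(a, b), tolerance = 1e-12)
    # symmetry in the arguments
    expect_equal(as.numeric(weighted_kappa(a, b)),
                 as.numeric(weighted_kappa(b, a)), tolerance = 1e-12)
  }
})

test_that("weighted kappa drops incomplete pairs and flags degenerate agreement", {
  a <- c(0, 1, NA, 2); b <- c(0, 1, 2, NA)
  k <- weighted_kappa(a, b)
  expect_equal(attr(k, "n"), 2)
  expect_equal(attr(k, "n_dropped"), 2)
  # a constant rater facing any disagreement earns zero chance-corrected credit
  expect_equal(as.numeric(weighted_kappa(c(2, 2, 2, 2), c(2, 2, 2, 3))), 0)
  expect_equal(as.numeric(weighted_kappa(c(1, 1, 1), c(1, 1, 1))), 1)
  expect_error(weighted_kappa(0:2, 0:3), "equal length")
})

test_that("confusion matrices count pairs over the fixed category set", {
  a <- c(0, 1, 2, 3, 3); b <- c(0, 2, 2, 3, 1)
  m <- confusion_matrix(a, b)
  expect_equal(dim(m), c(4, 4))
  expect_equal(sum(m), 5)
  expect_equal(m["1", "2"], 1L, ignore_attr = TRUE)
  expect_equal(m["3", "1"], 1L, ignore_attr = TRUE)
  # marginals reproduce each rater's histogram
  expect_equal(unname(rowSums(m)), unname(table(factor(a, levels = 0:3))),
               ignore_attr = TRUE)
  expect_equal(unname(colSums(m)), unname(table(factor(b, levels = 0:3))),
               ignore_attr = TRUE)
  # identical labels give a diagonal matrix
  md <- confusion_matrix(a, a)
  expect_equal(sum(md) - sum(diag(md)), 0)
})

test_that("one-sided signed-rank p is 1/256 for eight uniformly smaller values", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- x + c(0.5, 1.1, 0.7, 2.2, 1.6, 0.9, 3.1, 1.4)
  res <- wilcoxon_one_sided(x, y, "less")
  expect_true(res$exact)
  expect_equal(res$p_value, 1 / 256)
  expect_equal(res$statistic, 0)
})

test_that("exact signed-rank p matches full enumeration for tie-free samples", {
  set.seed(71)
  for (n in c(5, 8, 10, 12)) {
    for (rep in 1:3) {
      d <- round(rnorm(n, sd = 3), 3)
      d <- d[d != 0]
      while (any(duplicated(abs(d))) || length(d) < n) {
        d <- round(rnorm(n, sd = 3), 3); d <- d[d != 0]
      }
      x <- seq_along(d); y <- x - d
      for (alt in c("less", "greater")) {
        res <- wilcoxon_one_sided(x, y, alt)
        expect_true(res$exact)
        expect_equal(res$p_value, enumerate_signed_rank_p(d, alt),
                     tolerance = 1e-12)
        expect_gte(res$p_value, 2^-length(d))
        expect_lte(res$p_value, 1)
      }
    }
  }
})

test_that("degenerate and tied signed-rank inputs are handled explicitly", {
  expect_warning(res <- wilcoxon_one_sided(1:4, 1:4, "less"), "zero")
  expect_true(is.na(res$p_value))
  expect_equal(res$n_zero_dropped, 4)
  # ties fall back to the corrected normal approximation
  x <- c(1, 2, 3, 4, 5, 6); y <- x - c(1, 1, 2, 2, 3, 3)
  res2 <- wilcoxon_one_sided(x, y, "greater")
  expect_false(res2$exact)
  expect_true(res2$p_value > 0 && res2$p_value < 0.1)
})

test_that("Bland-Altman reproduces the hand-computed example and its antisymmetry", {
  # d = {0.1, 0.2, 0.3}: mean 0.2, sd 0.1, limits 0.2 -+ 1.96 * 0.1
  x <- c(1.1, 2.2, 3.3); y <- c(1.0, 2.0, 3.0)
  ba <- bland_altman(x, y)
  expect_equal(ba$mean_difference, 0.2)
  expect_equal(ba$loa_low, 0.004)
  expect_equal(ba$loa_high, 0.396)
  # swapping negates all three summaries
  ba2 <- bland_altman(y, x)
  expect_equal(ba2$mean_difference, -ba$mean_difference)
  expect_equal(ba2$loa_low, -ba$loa_high)
  expect_equal(ba2$loa_high, -ba$loa_low)
  # identical inputs give zero-width limits
  ba0 <- bland_altman(y, y)
  expect_equal(ba0$mean_difference, 0)
  expect_equal(ba0$loa_high - ba0$loa_low, 0)
  expect_error(bland_altman(1, 2), "at least 2")
  expect_true(ba$loa_low <= ba$mean_difference &&
              ba$mean_difference <= ba$loa_high)
})

test_that("good-to-poor shift proportions count dichotomy crossings", {
  expect_equal(shift_proportion(rep(2, 10), rep(1, 10)),
               list(fraction = 1, numerator = 10L, denominator = 10L))
  expect_equal(shift_proportion(c(0, 1, 1), c(0, 0, 1))$numerator, 0L)
  # mixed hand-counted example
  ref <- c(2, 3, 2, 1, 3, 0)
  new <- c(1, 3, 0, 0, 2, 0)
  sp <- shift_proportion(ref, new)
  expect_equal(sp$numerator, 2L)
  expect_equal(sp$denominator, 6L)
  expect_equal(sp$fraction, 2 / 6)
  expect_error(shift_proportion(NA, NA), "no complete")
})

test_that("cohort analysis summarizes by location with sorted-list medians", {
  tbl <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:12),
    occlusion_location = rep(c("proximal_M1", "distal_M1", "M2"), each = 4),
    odacs_ratio = c(0.2, 0.4, 0.5, 0.6, 0.3, 0.45, 0.5, 0.7, 0.1, 0.3, 0.4, 0.5),
    mca_ratio = c(0.5, 0.6, 0.7, 0.8, 0.6, 0.7, 0.8, 0.9, 0.6, 0.7, 0.9, 1.0),
    odacs_category = c(1, 1, 1, 2, 1, 1, 1, 2, 1, 1, 1, 1),
    mca_category = c(1, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 3),
    rater_R1 = c(1, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 3),
    rater_R2 = c(1, 1, 2, 2, 2, 2, 1, 2, 2, 3, 2, 3)
  )
  an <- cohort_analysis(tbl)
  overall <- dplyr::filter(an$by_location, location == "overall")
  v <- sort(tbl$odacs_ratio)
  expect_equal(overall$odacs_median, stats::median(v))
  expect_equal(overall$odacs_q1, unname(stats::quantile(v, 0.25)))
  expect_equal(overall$n, 12)
  expect_equal(nrow(an$by_location), 4)
  # identical score pairs shift nobody
  tbl0 <- tbl
  tbl0$odacs_ratio <- tbl0$mca_ratio
  tbl0$odacs_category <- tbl0$mca_category
  an0 <- cohort_analysis(tbl0)
  expect_true(all(an0$by_location$shift_good_to_poor == 0))
  # agreement table covers odacs-rater and rater-rater pairs
  expect_equal(nrow(an$agreement), 3)
  expect_true(all(is.finite(an$agreement$kappa)))
  # tidy/glance accessors
  expect_identical(tidy(an), an$by_location)
  expect_equal(glance(an)$location, "overall")
})

test_that("cohort analysis flags subsets that are too small for inference", {
  tbl <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    occlusion_location = c("M2", "proximal_M1", "proximal_M1"),
    odacs_ratio = c(0.2, 0.4, 0.3),
    mca_ratio = c(0.5, 0.6, NA),
    odacs_category = c(1, 1, 1),
    mca_category = c(2, 2, NA)
  )
  an <- cohort_analysis(tbl)
  m2 <- dplyr::filter(an$by_location, location == "M2")
  expect_true(is.na(m2$wilcoxon_p))
  expect_true(is.na(m2$ba_mean_difference))
  expect_equal(m2$shift_numerator, 1L)
})

test_that("cohort CSV round-trips through the reader with validation", {
  tbl <- tibble::tibble(
    patient_id = c("a", "b"), occlusion_location = c("M2", "distal_M1"),
    odacs_ratio = c(0.2, NA), mca_ratio = c(0.5, 0.6),
    odacs_category = c(1, NA), mca_category = c(2, 2)
  )
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tbl, p, row.names = FALSE)
  back <- read_cohort_csv(p)
  expect_equal(back$odacs_ratio, tbl$odacs_ratio)
  expect_true(is.na(back$odacs_category[2]))
  bad <- tbl; bad$occlusion_location[1] <- "basilar"
  pb <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, pb, row.names = FALSE)
  expect_error(read_cohort_csv(pb), "occlusion_location")
})

test_that("agreement plots and confusion heatmaps build without error", {
  ba <- bland_altman(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  expect_s3_class(ggplot2::autoplot(ba), "ggplot")
  m <- confusion_matrix(c(0, 1, 2, 3), c(0, 1, 1, 3))
  expect_s3_class(plot_confusion(m), "ggplot")
})
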