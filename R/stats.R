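#' Quadratically weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordinal labels with squared-distance
#' disagreement weights `w_ij = (i - j)^2 / (K - 1)^2`:
#' `kappa = 1 - sum(w * O) / sum(w * E)`, with observed table `O` and
#' chance expectation `E` from the marginals. The category set is fixed
#' (default `0:3`) rather than taken from the data, so weights are
#' stable across cohort subsets even when some categories are
#' unobserved. Pairs with any missing label are dropped (count reported
#' in the `n_dropped` attribute).
#'
#' @param labels_a,labels_b Equal-length ordinal label vectors.
#' @param categories Ordered category set (default `0:3`).
#' @return Kappa in `[-1, 1]` with attributes `n` (pairs used) and
#'   `n_dropped`; `NA` (flagged by a warning) when expected
#'   disagreement is zero but observed disagreement is not.
#' @export
weighted_kappa <- function(labels_a, labels_b, categories = 0:3) {
  if (length(labels_a) != length(labels_b)) {
    stop("label sequences must have equal length", call. = FALSE)
  }
  keep <- !is.na(labels_a) & !is.na(labels_b)
  a <- labels_a[keep]; b <- labels_b[keep]
  if (length(a) < 2) {
    stop("need at least 2 complete label pairs", call. = FALSE)
  }
  if (!all(a %in% categories) || !all(b %in% categories)) {
    stop("labels outside the declared category set", call. = FALSE)
  }
  K <- length(categories)
  O <- confusion_matrix(a, b, categories)
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  ij <- seq_len(K)
  w <- outer(ij, ij, function(i, j) (i - j)^2) / (K - 1)^2
  num <- sum(w * O); den <- sum(w * E)
  if (den == 0) {
    if (num == 0) {
      kappa <- 1
    } else {
      warning("zero expected disagreement with nonzero observed disagreement; kappa undefined",
              call. = FALSE)
      kappa <- NA_real_
    }
  } else {
    kappa <- 1 - num / den
  }
  structure(kappa, n = n, n_dropped = sum(!keep))
}

#' Confusion matrix over a fixed category set
#'
#' Entry `(i, j)` counts pairs labelled category `i` by the first rater
#' and `j` by the second. Pairs with missing labels are dropped.
#'
#' @inheritParams weighted_kappa
#' @return K x K integer matrix with category dimnames; entries sum to
#'   the number of complete pairs.
#' @export
confusion_matrix <- function(labels_a, labels_b, categories = 0:3) {
  if (length(labels_a) != length(labels_b)) {
    stop("label sequences must have equal length", call. = FALSE)
  }
  keep <- !is.na(labels_a) & !is.na(labels_b)
  a <- labels_a[keep]; b <- labels_b[keep]
  if (length(a) && (!all(a %in% categories) || !all(b %in% categories))) {
    stop("labels outside the declared category set", call. = FALSE)
  }
  fa <- factor(a, levels = categories)
  fb <- factor(b, levels = categories)
  m <- table(fa, fb)
  m <- matrix(as.integer(m), nrow = length(categories),
              dimnames = list(as.character(categories), as.character(categories)))
  m
}

#' One-sided paired Wilcoxon signed-rank test
#'
#' Tests whether `x` is stochastically smaller (or greater) than its
#' paired `y`. Zero differences are dropped (count reported); the p
#' value is exact (full enumeration of sign assignments, via the
#' signed-rank distribution) for n <= 25 without ties in the absolute
#' differences, and a tie-corrected normal approximation otherwise.
#'
#' @param x,y Equal-length paired numeric vectors (NA pairs dropped).
#' @param alternative `"less"` (x below y) or `"greater"`.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List: `statistic` (signed-rank V), `p_value`, `n_used`,
#'   `n_zero_dropped`, `exact`. All differences zero yields `NA`
#'   statistic and p with a warning.
#' @export
wilcoxon_one_sided <- function(x, y, alternative = c("less", "greater"),
                               exact_max = 25L) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; signed-rank test undefined",
            call. = FALSE)
    return(list(statistic = NA_real_, p_value = NA_real_, n_used = 0L,
                n_zero_dropped = n_zero, exact = NA))
  }
  ties <- any(duplicated(abs(d)))
  use_exact <- n <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = alternative,
                       exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_used = n, n_zero_dropped = n_zero, exact = use_exact)
}

#' Bland-Altman agreement summary
#'
#' Differences `d = x - y` between paired measurements: mean difference
#' (bias) and 1.96 SD limits of agreement, with the per-pair means and
#' differences for plotting. Swapping the arguments negates all three
#' summaries.
#'
#' @param x,y Equal-length paired numeric vectors; pairs with missing
#'   values are dropped, at least 2 complete pairs required.
#' @return An `odacs_bland_altman`: list with `mean_difference`,
#'   `loa_low`, `loa_high`, `sd_difference`, `n`, and a `pairs` tibble
#'   (`mean`, `difference`).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) {
    stop("need at least 2 complete pairs for Bland-Altman analysis",
         call. = FALSE)
  }
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(mean_difference = m,
         loa_low = m - 1.96 * s,
         loa_high = m + 1.96 * s,
         sd_difference = s,
         n = length(d),
         pairs = tibble::tibble(mean = (x + y) / 2, difference = d)),
    class = "odacs_bland_altman"
  )
}

#' @export
print.odacs_bland_altman <- function(x, ...) {
  cat("<odacs_bland_altman> n = ", x$n,
      ", mean difference ", signif(x$mean_difference, 4),
      ", limits of agreement [", signif(x$loa_low, 4), ", ",
      signif(x$loa_high, 4), "]\n", sep = "")
  invisible(x)
}

#' Proportion shifting from good to poor collaterals
#'
#' Fraction of patients graded good (categories 2-3) by the reference
#' method but poor (categories 0-1) by the new method. Pairs with a
#' missing category are excluded from both counts.
#'
#' @param reference_cats,new_cats Equal-length category vectors in
#'   `0:3`.
#' @return List: `fraction`, `numerator`, `denominator`.
#' @export
shift_proportion <- function(reference_cats, new_cats) {
  if (length(reference_cats) != length(new_cats)) {
    stop("paired category vectors must have equal length", call. = FALSE)
  }
  keep <- !is.na(reference_cats) & !is.na(new_cats)
  ref <- reference_cats[keep]; new <- new_cats[keep]
  if (length(ref) == 0) {
    stop("no complete category pairs", call. = FALSE)
  }
  if (!all(ref %in% 0:3) || !all(new %in% 0:3)) {
    stop("categories must lie in 0:3", call. = FALSE)
  }
  num <- sum(ref >= 2 & new <= 1)
  list(fraction = num / length(ref), numerator = as.integer(num),
       denominator = length(ref))
}

median_iqr <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    return(list(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Read a cohort table from CSV
#'
#' One row per patient with columns `patient_id`, `occlusion_location`
#' (`proximal_M1`, `distal_M1`, `M2`), `odacs_ratio`, `mca_ratio`,
#' `odacs_category`, `mca_category`, and optionally rater label columns
#' named `rater_<id>`. Empty cells become `NA` (undefined scores).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop("cohort table not found: ", path, call. = FALSE)
  }
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_cohort(df)
  df
}

validate_cohort <- function(df) {
  required <- c("patient_id", "occlusion_location", "odacs_ratio",
                "mca_ratio", "odacs_category", "mca_category")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$patient_id)) {
    stop("patient_id values must be unique", call. = FALSE)
  }
  bad_loc <- setdiff(unique(df$occlusion_location),
                     c("proximal_M1", "distal_M1", "M2"))
  if (length(bad_loc)) {
    stop("unknown occlusion_location value(s): ",
         paste(bad_loc, collapse = ", "), call. = FALSE)
  }
  for (col in c("odacs_ratio", "mca_ratio")) {
    v <- df[[col]]
    if (any(v < 0, na.rm = TRUE)) {
      stop(col, " must be non-negative where defined", call. = FALSE)
    }
  }
  for (col in c("odacs_category", "mca_category")) {
    v <- df[[col]]
    if (!all(v %in% c(0:3, NA))) {
      stop(col, " must lie in 0:3 where defined", call. = FALSE)
    }
  }
  invisible(df)
}

summarize_subset <- function(df) {
  qo <- median_iqr(df$odacs_ratio)
  qm <- median_iqr(df$mca_ratio)
  co <- median_iqr(df$odacs_category)
  cm <- median_iqr(df$mca_category)
  pairs_ok <- !is.na(df$odacs_ratio) & !is.na(df$mca_ratio)
  n_pairs <- sum(pairs_ok)
  ba <- if (n_pairs >= 2) bland_altman(df$mca_ratio, df$odacs_ratio) else NULL
  wt <- if (n_pairs >= 2) {
    # an NA p value is already the flag for degenerate (all-tied) pairs
    suppressWarnings(
      wilcoxon_one_sided(df$odacs_ratio, df$mca_ratio, alternative = "less"))
  } else NULL
  cat_ok <- !is.na(df$odacs_category) & !is.na(df$mca_category)
  shift <- if (any(cat_ok)) {
    shift_proportion(df$mca_category, df$odacs_category)
  } else list(fraction = NA_real_, numerator = NA_integer_,
              denominator = 0L)
  tibble::tibble(
    n = nrow(df),
    n_score_pairs = n_pairs,
    odacs_median = qo$median, odacs_q1 = qo$q1, odacs_q3 = qo$q3,
    mca_median = qm$median, mca_q1 = qm$q1, mca_q3 = qm$q3,
    odacs_cat_median = co$median, odacs_cat_q1 = co$q1, odacs_cat_q3 = co$q3,
    mca_cat_median = cm$median, mca_cat_q1 = cm$q1, mca_cat_q3 = cm$q3,
    ba_mean_difference = if (is.null(ba)) NA_real_ else ba$mean_difference,
    ba_loa_low = if (is.null(ba)) NA_real_ else ba$loa_low,
    ba_loa_high = if (is.null(ba)) NA_real_ else ba$loa_high,
    wilcoxon_statistic = if (is.null(wt)) NA_real_ else wt$statistic,
    wilcoxon_p = if (is.null(wt)) NA_real_ else wt$p_value,
    shift_good_to_poor = shift$fraction,
    shift_numerator = shift$numerator,
    shift_denominator = shift$denominator
  )
}

#' Cohort comparison of downstream-area and MCA-territory scores
#'
#' For each occlusion location (proximal M1, distal M1, M2) and for the
#' whole cohort: median (IQR) of the quantitative and categorized
#' scores, Bland-Altman summary of the difference
#' (MCA-CS minus downstream-area score), a one-sided Wilcoxon
#' signed-rank test of the hypothesis that the downstream-area score is
#' lower, the proportion of patients shifting from good to poor
#' collaterals, and confusion matrices of the categorized scores.
#' Rater columns (`rater_<id>`) additionally yield quadratically
#' weighted kappa agreements between the automated categories and each
#' rater and between rater pairs. Undefined scores are excluded
#' pairwise; locations with fewer than 2 complete pairs get `NA`
#' inferential statistics.
#'
#' @param table Cohort tibble as from [read_cohort_csv()] or
#'   [generate_cohort()].
#' @return An `odacs_cohort_analysis`: list with `by_location` tibble
#'   (one row per location plus `"overall"`), `confusion` (list of
#'   matrices), `agreement` tibble, `bland_altman` (list of
#'   `odacs_bland_altman` objects), and `n_patients`.
#' @export
cohort_analysis <- function(table) {
  df <- tibble::as_tibble(table)
  validate_cohort(df)
  locations <- c("proximal_M1", "distal_M1", "M2")
  subsets <- c(
    stats::setNames(
      lapply(locations, function(l) dplyr::filter(df, .data$occlusion_location == l)),
      locations),
    list(overall = df)
  )
  subsets <- subsets[vapply(subsets, nrow, 0L) > 0]
  by_location <- dplyr::bind_rows(
    lapply(names(subsets), function(nm) {
      dplyr::bind_cols(tibble::tibble(location = nm),
                       summarize_subset(subsets[[nm]]))
    })
  )
  confusion <- lapply(subsets, function(s) {
    confusion_matrix(s$mca_category, s$odacs_category, categories = 0:3)
  })
  ba <- lapply(subsets, function(s) {
    ok <- !is.na(s$odacs_ratio) & !is.na(s$mca_ratio)
    if (sum(ok) >= 2) bland_altman(s$mca_ratio, s$odacs_ratio) else NULL
  })
  rater_cols <- grep("^rater_", names(df), value = TRUE)
  agreement <- agreement_table(df, rater_cols)
  structure(
    list(by_location = by_location, confusion = confusion,
         agreement = agreement, bland_altman = ba, n_patients = nrow(df)),
    class = "odacs_cohort_analysis"
  )
}

agreement_table <- function(df, rater_cols) {
  rows <- list()
  for (rc in rater_cols) {
    k <- tryCatch(weighted_kappa(df$odacs_category, df[[rc]]),
                  error = function(e) NA_real_)
    rows[[length(rows) + 1]] <- tibble::tibble(
      rater_a = "odacs", rater_b = sub("^rater_", "", rc),
      kappa = as.numeric(k), n = attr(k, "n") %||% NA_integer_)
  }
  if (length(rater_cols) >= 2) {
    combs <- utils::combn(rater_cols, 2)
    for (i in seq_len(ncol(combs))) {
      a <- combs[1, i]; b <- combs[2, i]
      k <- tryCatch(weighted_kappa(df[[a]], df[[b]]),
                    error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- tibble::tibble(
        rater_a = sub("^rater_", "", a), rater_b = sub("^rater_", "", b),
        kappa = as.numeric(k), n = attr(k, "n") %||% NA_integer_)
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(rater_a = character(), rater_b = character(),
                   kappa = numeric(), n = integer())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.odacs_cohort_analysis <- function(x, ...) {
  cat("<odacs_cohort_analysis> ", x$n_patients, " patients\n", sep = "")
  print(x$by_location)
  if (nrow(x$agreement)) {
    cat("rater agreement (quadratically weighted kappa):\n")
    print(x$agreement)
  }
  invisible(x)
}

#' @rdname cohort_analysis
#' @param x An `odacs_cohort_analysis`.
#' @param ... Unused.
#' @method tidy odacs_cohort_analysis
#' @export
tidy.odacs_cohort_analysis <- function(x, ...) {
  x$by_location
}

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname cohort_analysis
#' @method glance odacs_cohort_analysis
#' @export
glance.odacs_cohort_analysis <- function(x, ...) {
  dplyr::filter(x$by_location, .data$location == "overall")
}

#' Write a cohort analysis to disk
#'
#' Emits `summary.json` (the by-location summaries and agreements),
#' `by_location.csv`, and one `confusion_<location>.csv` per subset.
#'
#' @param analysis An `odacs_cohort_analysis`.
#' @param dir Output directory (created if absent).
#' @return Invisibly `dir`.
#' @export
write_cohort_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "odacs_cohort_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(n_patients = analysis$n_patients,
         by_location = analysis$by_location,
         agreement = analysis$agreement),
    file.path(dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE
  )
  utils::write.csv(analysis$by_location, file.path(dir, "by_location.csv"),
                   row.names = FALSE)
  for (nm in names(analysis$confusion)) {
    utils::write.csv(analysis$confusion[[nm]],
                     file.path(dir, paste0("confusion_", nm, ".csv")))
  }
  invisible(dir)
}
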