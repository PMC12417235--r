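#' Pipeline configuration
#'
#' Collects the tunable parameters of the scoring pipeline with their
#' defaults: the hypoperfusion threshold (Tmax > 6 s), the closing
#' element semi-axes (10, 10, 1 voxels), the relaxed categorization
#' criteria (5% and 95% filling), and the mirror-overlap warning level.
#'
#' @param tmax_threshold_s Hypoperfusion threshold in seconds (> 0).
#' @param closing_semi_axes Three non-negative semi-axes in voxels.
#' @param low_relax,high_relax Categorization criteria,
#'   `0 < low_relax < 0.5 < high_relax < 1`.
#' @param overlap_warning_fraction Warn when the downstream mask
#'   overlaps its own mirror by more than this fraction.
#' @param save_intermediates Whether pipeline entry points should write
#'   intermediate masks.
#' @param seed Optional integer seed echoed into provenance.
#' @return An `odacs_config`.
#' @export
odacs_config <- function(tmax_threshold_s = 6.0,
                         closing_semi_axes = c(10, 10, 1),
                         low_relax = 0.05,
                         high_relax = 0.95,
                         overlap_warning_fraction = 0.05,
                         save_intermediates = FALSE,
                         seed = NULL) {
  if (!is.finite(tmax_threshold_s) || tmax_threshold_s <= 0) {
    stop("invalid config: tmax_threshold_s must be > 0", call. = FALSE)
  }
  closing_semi_axes <- as.numeric(closing_semi_axes)
  if (length(closing_semi_axes) != 3L || any(!is.finite(closing_semi_axes)) ||
      any(closing_semi_axes < 0)) {
    stop("invalid config: closing_semi_axes must be three non-negative numbers",
         call. = FALSE)
  }
  if (!(is.finite(low_relax) && low_relax > 0 && low_relax < 0.5)) {
    stop("invalid config: low_relax must satisfy 0 < low_relax < 0.5",
         call. = FALSE)
  }
  if (!(is.finite(high_relax) && high_relax > 0.5 && high_relax < 1)) {
    stop("invalid config: high_relax must satisfy 0.5 < high_relax < 1",
         call. = FALSE)
  }
  if (!(is.finite(overlap_warning_fraction) && overlap_warning_fraction >= 0 &&
        overlap_warning_fraction <= 1)) {
    stop("invalid config: overlap_warning_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(tmax_threshold_s = tmax_threshold_s,
         closing_semi_axes = closing_semi_axes,
         low_relax = low_relax,
         high_relax = high_relax,
         overlap_warning_fraction = overlap_warning_fraction,
         save_intermediates = isTRUE(save_intermediates),
         seed = seed),
    class = "odacs_config"
  )
}

#' Load a configuration from YAML
#'
#' Absent keys take their defaults; unknown keys are rejected by name,
#' as are values violating the parameter invariants.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return An [odacs_config()].
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(odacs_config())
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  obj <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed YAML in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(obj)) obj <- list()
  known <- names(formals(odacs_config))
  extra <- setdiff(names(obj), known)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(odacs_config, obj)
}

#' @export
print.odacs_config <- function(x, ...) {
  cat("<odacs_config>\n")
  cat("  tmax_threshold_s: ", x$tmax_threshold_s, "\n", sep = "")
  cat("  closing_semi_axes: [", paste(x$closing_semi_axes, collapse = ", "),
      "]\n", sep = "")
  cat("  low_relax / high_relax: ", x$low_relax, " / ", x$high_relax,
      "\n", sep = "")
  cat("  overlap_warning_fraction: ", x$overlap_warning_fraction, "\n",
      sep = "")
  invisible(x)
}
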