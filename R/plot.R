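#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Per-pair means against differences with the bias and 1.96 SD limits
#' of agreement as horizontal lines.
#'
#' @param object An `odacs_bland_altman` from [bland_altman()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot odacs_bland_altman
#' @export
autoplot.odacs_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_difference, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Mean of paired scores", y = "Difference",
                  title = sprintf("Bland-Altman (n = %d): bias %.3f, LoA [%.3f, %.3f]",
                                  object$n, object$mean_difference,
                                  object$loa_low, object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman panels per occlusion location
#'
#' @param object An `odacs_cohort_analysis` from [cohort_analysis()].
#' @param ... Unused.
#' @return A ggplot object faceted by location, showing the
#'   MCA-territory minus downstream-area score differences.
#' @method autoplot odacs_cohort_analysis
#' @export
autoplot.odacs_cohort_analysis <- function(object, ...) {
  keep <- !vapply(object$bland_altman, is.null, logical(1))
  dfs <- purrr::imap(object$bland_altman[keep], function(ba, nm) {
    dplyr::mutate(ba$pairs, location = nm)
  })
  df <- dplyr::bind_rows(dfs)
  lines <- dplyr::bind_rows(purrr::imap(object$bland_altman[keep], function(ba, nm) {
    tibble::tibble(location = nm, bias = ba$mean_difference,
                   lo = ba$loa_low, hi = ba$loa_high)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(data = lines, ggplot2::aes(yintercept = .data$bias),
                        colour = "steelblue") +
    ggplot2::geom_hline(data = lines, ggplot2::aes(yintercept = .data$lo),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(data = lines, ggplot2::aes(yintercept = .data$hi),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~location) +
    ggplot2::labs(x = "Mean of territory and downstream-area scores",
                  y = "Territory score - downstream-area score") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap for categorized scores
#'
#' @param confusion K x K matrix from [confusion_matrix()].
#' @param xlab,ylab Axis labels.
#' @return A ggplot tile plot with counts.
#' @export
plot_confusion <- function(confusion, xlab = "Method B category",
                           ylab = "Method A category") {
  df <- as.data.frame(as.table(confusion))
  names(df) <- c("a", "b", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$a, fill = .data$count)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = xlab, y = ylab, fill = "n") +
    ggplot2::theme_minimal()
}
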