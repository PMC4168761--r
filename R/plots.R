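#' Plot variance-partition fractions
#'
#' Stacked bar of the partner, shared, purely spatial and unexplained
#' fractions (clamped at zero for display; raw values are in
#' [tidy()]).
#'
#' @param object A [variance_partition()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot varpart_fractions
#' @export
autoplot.varpart_fractions <- function(object, ...) {
  df <- tidy(object)
  df$fraction <- factor(df$fraction,
                        levels = c("partner", "shared", "space", "unexplained"))
  ggplot2::ggplot(df, ggplot2::aes(x = "response",
                                   y = .data$value_clamped,
                                   fill = .data$fraction)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::scale_fill_manual(values = c(partner = "#c0392b", shared = "#8e44ad",
                                          space = "#2980b9", unexplained = "grey70")) +
    ggplot2::labs(x = NULL, y = "fraction of genetic variation",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-specimen Procrustes residuals
#'
#' Bar chart of the squared residual of every specimen, in input order,
#' with a dashed line at the overall median: specimens above the line
#' contribute most to the lack of congruence. An optional trait colours
#' the bars.
#'
#' @param object A [paco_test()] result.
#' @param traits Optional named character vector or tibble
#'   (`specimen_id`, `trait`) colouring the bars.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot paco_result
#' @export
autoplot.paco_result <- function(object, traits = NULL, ...) {
  df <- tidy(object)
  df$specimen_id <- factor(df$specimen_id, levels = df$specimen_id)
  if (!is.null(traits)) {
    if (is.data.frame(traits)) {
      traits <- stats::setNames(as.character(traits$trait), traits$specimen_id)
    }
    df$trait <- unname(traits[as.character(df$specimen_id)])
    df$trait[is.na(df$trait)] <- "unlabelled"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$specimen_id,
                                        y = .data$residual)) +
    ggplot2::geom_hline(yintercept = median(df$residual), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "squared Procrustes residual") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
  if (is.null(traits)) {
    p + ggplot2::geom_col()
  } else {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$trait))
  }
}

#' Plot a congruence report
#'
#' Variance-partition fractions per dependent-matrix direction, the
#' standard side-by-side presentation of the two analysis directions.
#'
#' @param object A [run_congruence_analysis()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot congruence_report
#' @export
autoplot.congruence_report <- function(object, ...) {
  df <- purrr::map_dfr(object$results, function(r) {
    dplyr::mutate(tidy(r$varpart), dependent = r$direction, .before = 1)
  })
  df$fraction <- factor(df$fraction,
                        levels = c("partner", "shared", "space", "unexplained"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dependent,
                                   y = .data$value_clamped,
                                   fill = .data$fraction)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::scale_fill_manual(values = c(partner = "#c0392b", shared = "#8e44ad",
                                          space = "#2980b9", unexplained = "grey70")) +
    ggplot2::labs(x = "dependent matrix", y = "fraction of genetic variation",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
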