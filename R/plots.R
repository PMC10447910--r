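# Plotting and broom-style verbs for the result objects. Rendering is a
# thin layer: every plot has a tabular export next to it.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
tidy.sweep_curve <- function(x, ...) {
  tibble::tibble(n_pcs = x$n_pcs, auc = x$auc,
                 selected = x$n_pcs == best_n_pcs(x))
}

#' Plot a LOOCV PC-count sweep
#'
#' AUC against the number of principal components fed to LDA, with the
#' selected (argmax) count highlighted.
#'
#' @param object a `sweep_curve` from [loocv_sweep()].
#' @param ... ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sweep_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_pcs, y = .data$auc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 1.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "number of principal components",
                  y = "LOOCV pooled AUC",
                  title = sprintf("PC sweep (selected: %d PCs)",
                                  best_n_pcs(object))) +
    ggplot2::theme_minimal()
}

#' Scree plot of a shape space
#'
#' @param object a `shape_space`.
#' @param n_components components to display.
#' @param ... ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.shape_space <- function(object, n_components = 30L, ...) {
  df <- dplyr::slice_head(tidy(object), n = n_components)
  df_long <- tidyr::pivot_longer(df, c("variance_fraction", "cumulative"),
                                 names_to = "measure", values_to = "value")
  ggplot2::ggplot(df_long,
                  ggplot2::aes(x = .data$component, y = .data$value,
                               colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "principal component", y = "fraction of variance") +
    ggplot2::theme_minimal()
}

#' Forest-style plot of a classifier bank report
#'
#' AUC with its confidence interval per algorithm, sorted by AUC.
#'
#' @param object a `cv_bank` (or the combined model/DIFFMASK comparison).
#' @param ... ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_bank <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$auc)
  df$algorithm <- factor(df$algorithm, levels = df$algorithm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc, y = .data$algorithm)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$auc_ci_low,
                                         xmax = .data$auc_ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "cross-validated AUC (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a per-vertex distance map
#'
#' Frontal (x, y) projection of a shape with vertices coloured by the
#' distance field, the tabular stand-in for a rendered heat map on the
#' surface.
#'
#' @param shape K x 3 matrix (e.g. a mean shape).
#' @param distances numeric vector of K distances ([distance_map()]).
#' @return A ggplot.
#' @export
plot_distance_map <- function(shape, distances) {
  shape <- as.matrix(shape)
  stopifnot(nrow(shape) == length(distances))
  df <- tibble::tibble(x = shape[, 1L], y = shape[, 2L],
                       distance = distances)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$distance)) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_colour_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "distance (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
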