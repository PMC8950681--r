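#' @export
autoplot.idpred_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "mean package loss (BCE)",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Plot per-residue disorder probability tracks
#'
#' @param predictions Prediction tibble from [predict_corpus()].
#' @param threshold Call threshold drawn as a horizontal line
#'   (default 0.5).
#' @return A ggplot object, one facet per protein.
#' @export
plot_predictions <- function(predictions, threshold = 0.5) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$pos, y = .data$probability)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_point(data = function(d) d[d$call == 1L, ],
                        colour = "firebrick", size = 0.5) +
    ggplot2::facet_wrap(~id, scales = "free_x") +
    ggplot2::labs(x = "residue", y = "P(disordered)") +
    ggplot2::theme_minimal()
}

#' Plot selected rows of a feature matrix along the sequence
#'
#' @param feature_matrix `35 x L` matrix from
#'   [assemble_feature_matrix()].
#' @param features Character vector of row names to show (default: the
#'   three entropy tracks and the two PCAA tracks).
#' @return A ggplot object with one facet per feature.
#' @export
plot_feature_tracks <- function(feature_matrix,
                                features = c("shannon_entropy",
                                             "topological_entropy",
                                             "persistent_entropy",
                                             "pcaa2", "pcaa3")) {
  d <- tidy_feature_matrix(feature_matrix)
  d <- d[d$feature %in% features, ]
  d$feature <- factor(d$feature, levels = features)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~feature, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "residue", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a persistence diagram
#'
#' @param diagram Tibble from [rips_persistence()].
#' @return A ggplot object (birth/death scatter, diagonal dashed).
#' @export
plot_persistence_diagram <- function(diagram) {
  ggplot2::ggplot(diagram,
                  ggplot2::aes(x = .data$birth, y = .data$death,
                               colour = factor(.data$dimension))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(colour = "dim", x = "birth", y = "death") +
    ggplot2::theme_minimal()
}
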