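#' Score plot of a PCA with optional cluster colouring
#'
#' PC1-PC2 scatter of the responses; marker shape shows the true tissue
#' state and, when a cluster assignment is supplied, colour shows the
#' unsupervised assignment so misassigned responses stand out.
#'
#' @param object A `state_pca`.
#' @param clusters Optional `cluster_assignment` from [cluster_states()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.state_pca <- function(object, clusters = NULL, ...) {
  df <- object$scores
  ev <- round(100 * object$explained_variance[1:2], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(clusters)) {
    df$assigned <- clusters$assignments$assigned_state
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          colour = .data$assigned))
  }
  if ("state" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$state), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = paste0("PC1 (", ev[1], "%)"),
                    y = paste0("PC2 (", ev[2], "%)"),
                    colour = "assigned", shape = "tissue state") +
    ggplot2::theme_minimal()
}

#' Scatter of the best discriminative pair with its decision boundary
#'
#' Plots the two normalized protein responses of the top-ranked pair, one
#' point per stimulus and state, with the fitted linear decision boundary.
#'
#' @param object A `pair_search`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pair_search <- function(object, ...) {
  b <- object$best_pair
  df <- object$best_data
  w <- object$boundary$weights
  c0 <- object$boundary$offset
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[b[1]]],
                                        y = .data[[b[2]]],
                                        colour = .data$state,
                                        shape = .data$state)) +
    ggplot2::geom_point(size = 2)
  if (abs(w[2]) > 1e-12) {
    p <- p + ggplot2::geom_abline(slope = -w[1] / w[2],
                                  intercept = c0 / w[2],
                                  linetype = "dashed")
  } else {
    p <- p + ggplot2::geom_vline(xintercept = c0 / w[1],
                                 linetype = "dashed")
  }
  p + ggplot2::labs(x = paste(b[1], "(normalized response)"),
                    y = paste(b[2], "(normalized response)")) +
    ggplot2::theme_minimal()
}

#' Bar chart of retained effect sizes
#'
#' @param object An `effect_size_tbl` from [rank_baseline_releases()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.effect_size_tbl <- function(object, ...) {
  df <- as.data.frame(object)
  df$protein <- factor(df$protein, levels = rev(df$protein))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cohens_d, y = .data$protein)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "Cohen's d (treated - control)", y = NULL) +
    ggplot2::theme_minimal()
}
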