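#' Plot predicted versus actual trait scores
#'
#' Scatter of actual against predicted scores with the identity-free least
#' squares trend, annotated with the Pearson correlation.
#'
#' @param predictions Tibble with `actual` and `predicted` columns (e.g.
#'   `predictions_discovery` from [run_ls_study()]).
#' @return A ggplot object.
#' @export
plot_predictions <- function(predictions) {
  r <- evaluate_predictions(predictions$predicted, predictions$actual)$r
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$actual, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "firebrick") +
    ggplot2::labs(x = "Actual LS score", y = "Predicted LS score",
                  subtitle = sprintf("Pearson r = %.3f (n = %d)", r,
                                     nrow(predictions))) +
    ggplot2::theme_minimal()
}

#' Histogram of a permutation null distribution
#'
#' Shows the null correlations from trait-shuffled refits with the observed
#' correlation marked.
#'
#' @param object A `permutation_result` (see [permute_discovery()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$observed_r,
                        color = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "Null correlation (trait-shuffled refits)", y = "Count",
      subtitle = sprintf("%s: observed r = %.3f, p = %.4g (%d permutations)",
                         object$stage, object$observed_r, object$p_value,
                         object$n_perm)) +
    ggplot2::theme_minimal()
}

#' Heatmap of edge-contribution t-statistics
#'
#' Reconstructs the symmetric ROI x ROI matrix of per-edge contribution
#' t-statistics and renders it as a tile heatmap (red positive, blue
#' negative).
#'
#' @param object An `edge_contribution` tibble (see [contribution_test()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edge_contribution <- function(object, ...) {
  t_clean <- ifelse(is.finite(object$t_stat), object$t_stat, 0)
  mat <- inverse_vectorize(t_clean)
  df <- tibble::as_tibble(expand.grid(roi_i = seq_len(nrow(mat)),
                                      roi_j = seq_len(ncol(mat))))
  df$t_stat <- mat[cbind(df$roi_i, df$roi_j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_j, y = .data$roi_i,
                                   fill = .data$t_stat)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "ROI", y = "ROI", fill = "t") +
    ggplot2::theme_minimal()
}

#' Network-pair enrichment heatmap
#'
#' Renders the 9 x 9 network matrix of enrichment likelihoods (1 - p) for
#' one significance set, with significant pairs starred.
#'
#' @param object An `edge_enrichment` tibble (possibly both sets bound
#'   together, as returned in `enrichment` by [contribution_analysis()]).
#' @param ... Unused.
#' @return A ggplot object (faceted by set when both are present).
#' @export
autoplot.edge_enrichment <- function(object, ...) {
  df <- tidyr::separate(tibble::as_tibble(object), "pair",
                        into = c("net_a", "net_b"), sep = "-",
                        remove = FALSE)
  levels <- intersect(rsn_labels, unique(c(df$net_a, df$net_b)))
  both <- dplyr::bind_rows(df,
                           dplyr::rename(dplyr::filter(df,
                                                       .data$net_a != .data$net_b),
                                         net_a = "net_b", net_b = "net_a"))
  both$net_a <- factor(both$net_a, levels = levels)
  both$net_b <- factor(both$net_b, levels = levels)
  p <- ggplot2::ggplot(both, ggplot2::aes(x = .data$net_a, y = .data$net_b,
                                          fill = .data$likelihood)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", "")), size = 5) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - p") +
    ggplot2::theme_minimal()
  if (length(unique(stats::na.omit(both$set))) > 1) {
    p <- p + ggplot2::facet_wrap(~set)
  }
  p
}

#' @export
tidy.ls_pipeline <- function(x, ...) {
  purrr::map_dfr(seq_along(x$cv$folds), function(f) {
    fm <- x$cv$folds[[f]]
    tibble::tibble(fold = f, lambda = fm$lambda,
                   intercept = fm$intercept,
                   coef_norm = sqrt(sum(fm$coefficients^2)),
                   n_train = length(fm$train_idx),
                   n_test = length(fm$test_idx))
  })
}

#' @export
glance.ls_pipeline <- function(x, ...) {
  tibble::tibble(n = x$cv$n, n_components = x$pca$n_components,
                 k = x$cv$k, inner_k = x$cv$inner_k,
                 r_discovery = x$r_discovery,
                 explained_variance_total = sum(x$pca$explained_variance))
}
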