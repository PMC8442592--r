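new_permutation_result <- function(stage, observed_r, null_r, n_perm, seed,
                                   two_sided = FALSE) {
  exceed <- if (two_sided) sum(abs(null_r) >= abs(observed_r))
            else sum(null_r >= observed_r)
  structure(
    list(stage = stage, observed_r = observed_r, null_r = null_r,
         p_value = (1 + exceed) / (1 + n_perm), n_perm = n_perm,
         seed = seed, two_sided = two_sided),
    class = "permutation_result"
  )
}

#' Permutation test for discovery prediction performance
#'
#' Shuffles the trait scores and reruns the full supervised stage
#' (fold assignment, inner-loop penalty selection, fold refits,
#' out-of-fold prediction, Pearson r) at every iteration, building the
#' null distribution of the out-of-fold correlation. PCA scores are fixed
#' across iterations: the dimensionality reduction is unsupervised, so a
#' trait shuffle cannot change it — reusing it is exact, not an
#' approximation. By default the fold assignment is redrawn each
#' iteration.
#'
#' The p-value uses the add-one estimator
#' `p = (1 + #\{null r >= observed r\}) / (1 + n_perm)`, one-sided in the
#' upper tail (the hypothesis is positive predictability); a two-sided
#' version compares `|r|`.
#'
#' @param scores n x K PC score matrix.
#' @param y Numeric trait vector.
#' @param k,inner_k,lambda_grid Cross-validation configuration (see
#'   [fit_cv_ridge()]).
#' @param n_perm Number of permutations (default 5000, the headline
#'   setting; use far fewer for exploration).
#' @param seed Master seed; per-iteration seeds are derived from it so
#'   results do not depend on execution order.
#' @param two_sided Compare `|r|` instead of upper-tail r.
#' @param refit_folds Redraw the outer/inner fold assignment each
#'   iteration (default `TRUE`); if `FALSE` the observed fit's seed is
#'   reused so folds are fixed.
#' @return Object of class `permutation_result` with fields `observed_r`,
#'   `null_r`, `p_value`, `n_perm`, `seed`.
#' @export
permute_discovery <- function(scores, y, k = 10, inner_k = 5,
                              lambda_grid = default_lambda_grid(),
                              n_perm = 5000, seed = 1, two_sided = FALSE,
                              refit_folds = TRUE) {
  if (n_perm < 1) abort_param("n_perm must be >= 1")
  scores <- as.matrix(scores)
  fit <- fit_cv_ridge(scores, y, k, inner_k, lambda_grid, seed = seed)
  observed <- evaluate_predictions(predict_discovery(fit, scores)$predicted,
                                   y)$r
  seeds <- matrix(derive_seeds(seed, 2L * n_perm), nrow = 2)
  null_r <- vapply(seq_len(n_perm), function(it) {
    set.seed(seeds[1, it])
    y_perm <- sample(y)
    cv_seed <- if (refit_folds) seeds[2, it] else seed
    f <- fit_cv_ridge(scores, y_perm, k, inner_k, lambda_grid,
                      seed = cv_seed)
    evaluate_predictions(predict_discovery(f, scores)$predicted, y_perm)$r
  }, numeric(1))
  new_permutation_result("discovery", observed, null_r, n_perm, seed,
                         two_sided)
}

#' Permutation test for validation (external) prediction performance
#'
#' At each iteration the discovery trait scores are shuffled, the k fold
#' models are refit on the permuted discovery data, applied to the
#' validation scores and averaged; the correlation of that averaged null
#' prediction with the actual validation scores gives one null r. The
#' observed r comes from the unpermuted discovery fit applied the same
#' way. Same p-value estimator as [permute_discovery()].
#'
#' @param scores_disc Discovery PC scores (n x K).
#' @param y_disc Discovery trait vector.
#' @param scores_val Validation PC scores (m x K), projected with the
#'   *discovery* PCA.
#' @param y_val Validation trait vector.
#' @inheritParams permute_discovery
#' @return A `permutation_result` (stage "validation").
#' @export
permute_validation <- function(scores_disc, y_disc, scores_val, y_val,
                               k = 10, inner_k = 5,
                               lambda_grid = default_lambda_grid(),
                               n_perm = 5000, seed = 1, two_sided = FALSE,
                               refit_folds = TRUE) {
  if (n_perm < 1) abort_param("n_perm must be >= 1")
  scores_disc <- as.matrix(scores_disc)
  scores_val <- as.matrix(scores_val)
  fit <- fit_cv_ridge(scores_disc, y_disc, k, inner_k, lambda_grid,
                      seed = seed)
  observed <- evaluate_predictions(predict_external(fit, scores_val), y_val)$r
  seeds <- matrix(derive_seeds(seed, 2L * n_perm), nrow = 2)
  null_r <- vapply(seq_len(n_perm), function(it) {
    set.seed(seeds[1, it])
    y_perm <- sample(y_disc)
    cv_seed <- if (refit_folds) seeds[2, it] else seed
    f <- fit_cv_ridge(scores_disc, y_perm, k, inner_k, lambda_grid,
                      seed = cv_seed)
    evaluate_predictions(predict_external(f, scores_val), y_val)$r
  }, numeric(1))
  new_permutation_result("validation", observed, null_r, n_perm, seed,
                         two_sided)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result [%s]: observed r = %.3f, p = %.4g (%d permutations%s)>\n",
    x$stage, x$observed_r, x$p_value, x$n_perm,
    if (x$two_sided) ", two-sided" else ""))
  invisible(x)
}

#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(iteration = seq_len(x$n_perm), null_r = x$null_r)
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(stage = x$stage, observed_r = x$observed_r,
                 p_value = x$p_value, n_perm = x$n_perm,
                 null_mean = mean(x$null_r), null_sd = sd(x$null_r),
                 seed = x$seed)
}
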