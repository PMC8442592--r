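#' Fit PCA on a discovery feature matrix
#'
#' Centered (unscaled) principal component analysis of the n x E edge
#' feature matrix. With E >> n, at most n - 1 components carry variance;
#' `n_components = "max"` resolves to `min(n - 1, E)`. Components are
#' ordered by decreasing explained variance and each loading column's sign
#' is fixed so its largest-magnitude entry is positive. Asking for more
#' components than the data's rank truncates with a warning.
#'
#' @param x n x E numeric matrix (rows = subjects).
#' @param n_components Number of components to keep, or `"max"`.
#' @return Object of class `pca_model`: list with `center` (length E),
#'   `transform` (E x K orthonormal loadings), `explained_variance`
#'   (length K), `n_components`.
#' @export
fit_pca <- function(x, n_components = "max") {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) abort_param("PCA needs at least 2 subjects")
  k_max <- min(n - 1L, ncol(x))
  k <- if (identical(n_components, "max")) k_max else as.integer(n_components)
  if (k < 1) abort_param("n_components must be >= 1")
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = min(k, k_max))
  ev <- pc$sdev[seq_len(min(k, k_max))]^2
  nz <- ev > max(ev[1], 0) * 1e-12
  k_eff <- sum(nz)
  if (k > k_eff) {
    warning(sprintf(
      "requested %d components but rank supports %d; truncating", k, k_eff),
      call. = FALSE)
    k <- k_eff
  }
  transform <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading in each component is positive
  flip <- vapply(seq_len(k), function(c) {
    col <- transform[, c]
    sign(col[which.max(abs(col))])
  }, numeric(1))
  transform <- sweep(transform, 2, flip, `*`)
  structure(
    list(center = pc$center, transform = transform,
         explained_variance = ev[seq_len(k)], n_components = k),
    class = "pca_model"
  )
}

#' Project feature vectors onto a fitted PCA basis
#'
#' Scores are `(x - center) %*% transform`. The center and loadings always
#' come from the discovery fit — projecting a validation cohort never
#' refits or re-centers on the validation data.
#'
#' @param pca A [fit_pca()] model.
#' @param x n x E matrix with the same E (and edge ordering) as the fit.
#' @return n x K score matrix.
#' @export
project_pca <- function(pca, x) {
  stopifnot(inherits(pca, "pca_model"))
  x <- as.matrix(x)
  if (ncol(x) != length(pca$center)) {
    abort_param(sprintf("x has %d columns; PCA was fit on %d features",
                        ncol(x), length(pca$center)))
  }
  sweep(x, 2, pca$center) %*% pca$transform
}

# Ridge path via SVD of the centered design: minimizes
# sum (y_i - b - beta' s_i)^2 + lambda ||beta||^2 with unpenalized
# intercept. Returns coefficients for every lambda at once.
ridge_path <- function(s, y, lambdas) {
  s <- as.matrix(s)
  s_mean <- colMeans(s)
  y_mean <- mean(y)
  sc <- sweep(s, 2, s_mean)
  yc <- y - y_mean
  sv <- svd(sc)
  uty <- crossprod(sv$u, yc)
  tol <- max(dim(sc)) * .Machine$double.eps * max(sv$d, 0)
  beta <- vapply(lambdas, function(lam) {
    shrink <- if (lam > 0) sv$d / (sv$d^2 + lam) else
      ifelse(sv$d > tol, 1 / sv$d, 0)
    as.numeric(sv$v %*% (shrink * uty))
  }, numeric(ncol(s)))
  beta <- matrix(beta, ncol = length(lambdas))
  intercept <- y_mean - as.numeric(crossprod(beta, s_mean))
  list(beta = beta, intercept = intercept)
}

#' Default ridge penalty grid
#'
#' Thirteen log-spaced values from 1e-3 to 1e3. Ties in inner-loop error
#' break toward the larger (more regularized) penalty.
#'
#' @return Numeric vector of length 13.
#' @export
default_lambda_grid <- function() 10^seq(-3, 3, by = 0.5)

#' Ridge regression on PC scores with nested k-fold cross-validation
#'
#' The discovery cohort is split into `k` outer folds by a seeded shuffle
#' (fold sizes differ by at most one). For each outer fold, the penalty is
#' chosen by `inner_k`-fold cross-validation *within the training folds
#' only* (minimizing mean squared error; ties go to the larger penalty),
#' and the fold model is then refit on all training folds at the chosen
#' penalty. Outer test folds never touch hyperparameter selection. The
#' ridge objective is `sum (y_i - b - beta' s_i)^2 + lambda ||beta||^2`
#' with an unpenalized intercept.
#'
#' @param scores n x K matrix of PC scores (see [project_pca()]).
#' @param y Numeric response of length n.
#' @param k Number of outer folds (default 10).
#' @param inner_k Number of inner folds for penalty selection (default 5).
#' @param lambda_grid Candidate penalties (default [default_lambda_grid()]).
#' @param seed Integer seed for the fold shuffles.
#' @return Object of class `cv_ridge`: list with `folds` (list of length
#'   `k`, each with `coefficients`, `intercept`, `lambda`, `train_idx`,
#'   `test_idx`), `fold_id` (length n), `k`, `lambda_grid`, `seed`.
#' @export
fit_cv_ridge <- function(scores, y, k = 10, inner_k = 5,
                         lambda_grid = default_lambda_grid(), seed = 1) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (length(y) != n) abort_param("length(y) must match nrow(scores)")
  if (anyNA(y)) abort_param("y contains missing values")
  if (n < 2 * k) abort_param(sprintf("need n >= 2k subjects (n=%d, k=%d)", n, k))
  if (length(lambda_grid) == 0 || any(lambda_grid < 0)) {
    abort_param("lambda_grid must be nonempty and nonnegative")
  }
  lambda_grid <- sort(lambda_grid)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(k), length.out = n))
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- which(fold_id != f)
    inner_id <- sample(rep(seq_len(inner_k), length.out = length(train)))
    sse <- numeric(length(lambda_grid))
    for (g in seq_len(inner_k)) {
      tr <- train[inner_id != g]
      te <- train[inner_id == g]
      path <- ridge_path(scores[tr, , drop = FALSE], y[tr], lambda_grid)
      pred <- scores[te, , drop = FALSE] %*% path$beta
      pred <- sweep(pred, 2, path$intercept, `+`)
      sse <- sse + colSums((pred - y[te])^2)
    }
    best <- max(which(sse == min(sse)))   # ties -> larger lambda
    lam <- lambda_grid[best]
    fit <- ridge_path(scores[train, , drop = FALSE], y[train], lam)
    folds[[f]] <- list(coefficients = as.numeric(fit$beta),
                       intercept = fit$intercept[1], lambda = lam,
                       train_idx = train, test_idx = which(fold_id == f))
  }
  structure(
    list(folds = folds, fold_id = fold_id, k = k, inner_k = inner_k,
         lambda_grid = lambda_grid, seed = seed, n = n),
    class = "cv_ridge"
  )
}

#' Out-of-fold discovery predictions
#'
#' Each subject is predicted by the single fold model that was not trained
#' on it.
#'
#' @param fit A [fit_cv_ridge()] object.
#' @param scores The n x K score matrix the model was fit on.
#' @return Tibble with columns `row`, `fold`, `predicted`.
#' @export
predict_discovery <- function(fit, scores) {
  stopifnot(inherits(fit, "cv_ridge"))
  scores <- as.matrix(scores)
  pred <- numeric(fit$n)
  for (f in seq_len(fit$k)) {
    fold <- fit$folds[[f]]
    pred[fold$test_idx] <- fold$intercept +
      scores[fold$test_idx, , drop = FALSE] %*% fold$coefficients
  }
  tibble::tibble(row = seq_len(fit$n), fold = fit$fold_id, predicted = pred)
}

#' Averaged external (validation) predictions
#'
#' Applies each of the k fold models to external score rows and averages:
#' `pred(x) = mean_f (b_f + beta_f' s(x))`. By linearity this equals the
#' prediction under the averaged coefficients.
#'
#' @param fit A [fit_cv_ridge()] object.
#' @param scores m x K matrix of external PC scores (projected with the
#'   discovery PCA; see [project_pca()]).
#' @return Numeric vector of length m.
#' @export
predict_external <- function(fit, scores) {
  stopifnot(inherits(fit, "cv_ridge"))
  scores <- as.matrix(scores)
  preds <- vapply(fit$folds, function(fold) {
    as.numeric(fold$intercept + scores %*% fold$coefficients)
  }, numeric(nrow(scores)))
  rowMeans(matrix(preds, nrow = nrow(scores)))
}

#' Pearson correlation between predicted and actual scores
#'
#' @param predicted,actual Numeric vectors of equal length (>= 3), neither
#'   constant.
#' @return List with `r` (Pearson correlation) and `n`.
#' @export
evaluate_predictions <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    abort_param("predicted and actual must have equal length")
  }
  if (length(actual) < 3) abort_param("need at least 3 observations")
  if (sd(predicted) == 0 || sd(actual) == 0) {
    abort_param("correlation undefined for a constant vector")
  }
  list(r = cor(predicted, actual), n = length(actual))
}

#' Fit the full PCA + cross-validated ridge pipeline
#'
#' Convenience wrapper for the discovery stage: fits PCA on the feature
#' matrix, projects it, runs [fit_cv_ridge()] on the scores and computes
#' out-of-fold predictions. PCA is fit once on the full discovery set
#' before the supervised cross-validation (the dimensionality reduction is
#' unsupervised; see the methods vignette for the leakage discussion and
#' the strictly nested variant).
#'
#' @param features n x E feature matrix or a `feature_matrix` object.
#' @param y Numeric response (defaults to the `ls_score` column of a
#'   `feature_matrix`'s subject table).
#' @param n_components Passed to [fit_pca()].
#' @param nested_pca If `TRUE`, out-of-fold predictions instead come from a
#'   strictly nested variant in which PCA is refit on each outer-fold
#'   training set (slower; the stored single PCA/fold models are unchanged
#'   and external prediction still uses the full-discovery PCA).
#' @param k,inner_k,lambda_grid,seed Passed to [fit_cv_ridge()].
#' @return Object of class `ls_pipeline`: list with `pca`, `cv`,
#'   `scores`, `y`, `oof` (out-of-fold prediction tibble), `r_discovery`,
#'   `config`.
#' @export
fit_ls_pipeline <- function(features, y = NULL, n_components = "max",
                            k = 10, inner_k = 5,
                            lambda_grid = default_lambda_grid(), seed = 1,
                            nested_pca = FALSE) {
  if (inherits(features, "feature_matrix")) {
    if (is.null(y)) {
      y <- features$subjects$ls_score[!features$subjects$excluded]
    }
    features <- features$features
  }
  features <- as.matrix(features)
  if (is.null(y)) abort_param("y is required when features is a bare matrix")
  pca <- fit_pca(features, n_components)
  scores <- project_pca(pca, features)
  cv <- fit_cv_ridge(scores, y, k = k, inner_k = inner_k,
                     lambda_grid = lambda_grid, seed = seed)
  if (nested_pca) {
    oof_pred <- numeric(cv$n)
    for (f in seq_len(cv$k)) {
      fold <- cv$folds[[f]]
      pca_f <- fit_pca(features[fold$train_idx, , drop = FALSE], n_components)
      s_tr <- project_pca(pca_f, features[fold$train_idx, , drop = FALSE])
      fit_f <- ridge_path(s_tr, y[fold$train_idx], fold$lambda)
      s_te <- project_pca(pca_f, features[fold$test_idx, , drop = FALSE])
      oof_pred[fold$test_idx] <- fit_f$intercept[1] + s_te %*% fit_f$beta
    }
    oof <- tibble::tibble(row = seq_len(cv$n), fold = cv$fold_id,
                          predicted = oof_pred)
  } else {
    oof <- predict_discovery(cv, scores)
  }
  r <- evaluate_predictions(oof$predicted, y)$r
  structure(
    list(pca = pca, cv = cv, scores = scores, y = y, oof = oof,
         r_discovery = r,
         config = list(n_components = pca$n_components, k = k,
                       inner_k = inner_k, lambda_grid = lambda_grid,
                       seed = seed, nested_pca = nested_pca)),
    class = "ls_pipeline"
  )
}

#' Predict an external cohort with a fitted pipeline
#'
#' Projects the validation feature matrix with the discovery PCA (its
#' center and transformation matrix, never refit) and averages the k fold
#' models' predictions.
#'
#' @param pipeline A [fit_ls_pipeline()] object.
#' @param features m x E validation feature matrix (same edge ordering as
#'   discovery) or a `feature_matrix`.
#' @return Numeric vector of averaged predictions, length m.
#' @export
predict_ls <- function(pipeline, features) {
  stopifnot(inherits(pipeline, "ls_pipeline"))
  if (inherits(features, "feature_matrix")) features <- features$features
  predict_external(pipeline$cv, project_pca(pipeline$pca, features))
}

#' @export
print.ls_pipeline <- function(x, ...) {
  cat(sprintf(
    "<ls_pipeline: %d subjects, %d PCs, %d-fold CV; out-of-fold r = %.3f>\n",
    x$cv$n, x$pca$n_components, x$cv$k, x$r_discovery))
  invisible(x)
}

#' @export
print.cv_ridge <- function(x, ...) {
  lams <- vapply(x$folds, `[[`, numeric(1), "lambda")
  cat(sprintf("<cv_ridge: %d folds on %d subjects; lambda in [%g, %g]>\n",
              x$k, x$n, min(lams), max(lams)))
  invisible(x)
}
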