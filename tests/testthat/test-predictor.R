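test_that("PCA keeps min(n-1, E) components with orthonormal signed loadings", {
  set.seed(15)
  x <- matrix(rnorm(20 * 50), 20, 50)
  pca <- fit_pca(x)
  expect_equal(pca$n_components, 19)
  gram <- crossprod(pca$transform)
  expect_lt(max(abs(gram - diag(19))), 1e-8)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  # sign convention: largest-magnitude loading positive
  for (c in 1:19) {
    col <- pca$transform[, c]
    expect_gt(col[which.max(abs(col))], 0)
  }
  # training scores are centered with diagonal covariance
  s <- project_pca(pca, x)
  expect_lt(max(abs(colMeans(s))), 1e-10)
  cv <- cov(s)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-8)
})

test_that("degenerate feature matrices truncate with a warning", {
  x <- matrix(1, 10, 6)    # identical rows: no variance anywhere
  expect_warning(pca <- fit_pca(x), "truncating")
  expect_equal(pca$n_components, 0)
})

test_that("projection always uses the discovery center", {
  set.seed(16)
  x <- matrix(rnorm(15 * 30), 15, 30)
  pca <- fit_pca(x, 4)
  expect_equal(project_pca(pca, matrix(pca$center, 1)),
               matrix(0, 1, 4), ignore_attr = TRUE)
  shift <- x + 5   # validation cohort with a different mean
  expect_equal(project_pca(pca, shift),
               project_pca(pca, x) + 5 * matrix(colSums(pca$transform),
                                                15, 4, byrow = TRUE),
               tolerance = 1e-8)
  expect_error(project_pca(pca, x[, 1:10]), "columns")
})

test_that("ridge solutions match an independent QR oracle across the grid", {
  set.seed(17)
  s <- matrix(rnorm(25 * 4), 25, 4)
  y <- rnorm(25)
  for (lam in c(0, 0.5, 3, 100)) {
    fit <- connpred:::ridge_path(s, y, lam)
    # oracle: OLS by QR on the ridge-augmented centered system
    sc <- scale(s, scale = FALSE)
    yc <- y - mean(y)
    aug_x <- rbind(sc, sqrt(lam) * diag(4))
    aug_y <- c(yc, rep(0, 4))
    beta_or <- lm.fit(aug_x, aug_y)$coefficients
    expect_equal(as.numeric(fit$beta), unname(beta_or), tolerance = 1e-8)
    expect_equal(fit$intercept[1],
                 mean(y) - sum(beta_or * colMeans(s)), tolerance = 1e-8)
  }
  # lambda = 0 equals plain OLS
  ols <- lm(y ~ s)
  fit0 <- connpred:::ridge_path(s, y, 0)
  expect_equal(as.numeric(fit0$beta), unname(coef(ols)[-1]), tolerance = 1e-6)
  # closed form on a tiny 5 x 2 system
  s2 <- matrix(c(1, 2, 3, 4, 5, -1, 0, 2, 1, 3), 5, 2)
  y2 <- c(2, 1, 4, 3, 5)
  lam <- 2
  sc2 <- scale(s2, scale = FALSE); yc2 <- y2 - mean(y2)
  beta_cf <- solve(crossprod(sc2) + lam * diag(2), crossprod(sc2, yc2))
  fit2 <- connpred:::ridge_path(s2, y2, lam)
  expect_equal(as.numeric(fit2$beta), as.numeric(beta_cf), tolerance = 1e-8)
})

test_that("extreme penalties shrink coefficients to zero", {
  set.seed(18)
  s <- matrix(rnorm(30 * 5), 30, 5)
  y <- rnorm(30)
  fit <- connpred:::ridge_path(s, y, 1e12)
  expect_lt(max(abs(fit$beta)), 1e-9)
  pred <- fit$intercept[1] + s %*% fit$beta
  expect_equal(as.numeric(pred), rep(mean(y), 30), tolerance = 1e-6)
})

test_that("outer folds partition the cohort with near-equal sizes", {
  set.seed(19)
  s <- matrix(rnorm(47 * 6), 47, 6)
  y <- rnorm(47)
  fit <- fit_cv_ridge(s, y, k = 10, seed = 5)
  sizes <- table(fit$fold_id)
  expect_equal(length(sizes), 10L)
  expect_lte(diff(range(sizes)), 1)
  test_all <- sort(unlist(lapply(fit$folds, `[[`, "test_idx")))
  expect_equal(test_all, 1:47)
  for (f in seq_along(fit$folds)) {
    expect_true(all(fit$folds[[f]]$lambda %in% fit$lambda_grid))
    expect_equal(sort(c(fit$folds[[f]]$train_idx, fit$folds[[f]]$test_idx)),
                 1:47)
  }
  expect_error(fit_cv_ridge(s[1:15, ], y[1:15], k = 10), "2k")
  expect_error(fit_cv_ridge(s, replace(y, 3, NA)), "missing")
})

test_that("test-fold responses never influence the fitted fold model", {
  set.seed(20)
  s <- matrix(rnorm(40 * 5), 40, 5)
  y <- rnorm(40)
  fit1 <- fit_cv_ridge(s, y, k = 5, seed = 9)
  y2 <- y
  idx <- fit1$folds[[2]]$test_idx
  y2[idx] <- sample(y2[idx])       # permute fold 2's test responses
  fit2 <- fit_cv_ridge(s, y2, k = 5, seed = 9)
  expect_identical(fit1$folds[[2]]$coefficients,
                   fit2$folds[[2]]$coefficients)
  expect_identical(fit1$folds[[2]]$lambda, fit2$folds[[2]]$lambda)
})

test_that("out-of-fold predictions come from the held-out model only", {
  set.seed(21)
  s <- matrix(rnorm(30 * 4), 30, 4)
  y <- rnorm(30)
  fit <- fit_cv_ridge(s, y, k = 5, seed = 2)
  oof <- predict_discovery(fit, s)
  expect_equal(oof$fold, fit$fold_id)
  for (f in 1:5) {
    fold <- fit$folds[[f]]
    manual <- fold$intercept +
      s[fold$test_idx, , drop = FALSE] %*% fold$coefficients
    expect_equal(oof$predicted[fold$test_idx], as.numeric(manual))
  }
  # constant response -> constant predictions at the training mean
  const_fit <- fit_cv_ridge(s, rep(3, 30), k = 5, seed = 2)
  oof_c <- predict_discovery(const_fit, s)
  expect_equal(oof_c$predicted, rep(3, 30), tolerance = 1e-8)
})

test_that("external prediction is the linear average of fold models", {
  set.seed(22)
  s <- matrix(rnorm(40 * 5), 40, 5)
  y <- rnorm(40)
  fit <- fit_cv_ridge(s, y, k = 4, seed = 3)
  s_new <- matrix(rnorm(12 * 5), 12, 5)
  pred <- predict_external(fit, s_new)
  # algebraic identity: mean of predictions = prediction under mean model
  beta_bar <- rowMeans(vapply(fit$folds, `[[`, numeric(5), "coefficients"))
  b_bar <- mean(vapply(fit$folds, `[[`, numeric(1), "intercept"))
  expect_equal(pred, as.numeric(b_bar + s_new %*% beta_bar),
               tolerance = 1e-10)
  # identical folds -> average equals the single model
  fit_same <- fit
  for (f in 2:4) fit_same$folds[[f]] <- fit_same$folds[[1]]
  one <- fit$folds[[1]]$intercept + s_new %*% fit$folds[[1]]$coefficients
  expect_equal(predict_external(fit_same, s_new), as.numeric(one))
})

test_that("evaluation is plain Pearson correlation with guard rails", {
  y <- c(1, 3, 2, 5)
  expect_equal(evaluate_predictions(y, y)$r, 1)
  expect_equal(evaluate_predictions(-y, y)$r, -1)
  p <- c(2, 1, 4, 3)
  # hand-computed Pearson r for the 4-point toy pair
  r_hand <- sum((p - mean(p)) * (y - mean(y))) /
    sqrt(sum((p - mean(p))^2) * sum((y - mean(y))^2))
  expect_equal(evaluate_predictions(p, y)$r, r_hand, tolerance = 1e-12)
  expect_equal(evaluate_predictions(p, y)$n, 4)
  expect_error(evaluate_predictions(rep(1, 4), y), "constant")
  expect_error(evaluate_predictions(1:2, 1:2), "3 observations")
})

test_that("strong planted signal gives high out-of-fold correlation", {
  fx <- make_fitted_pipeline(n = 60, r_n = 15, seed = 23, k = 10,
                             effect = 0.8, n_signal = 20)
  expect_gt(fx$pipeline$r_discovery, 0.3)
  # out-of-fold r rises with effect size on average (monotone recovery)
  r_at <- function(effect) {
    mean(vapply(1:3, function(i) {
      coh <- generate_edge_cohort(cohort_spec(
        n_subjects = 60, n_rois = 15, n_signal_edges = 20,
        effect_size = effect, seed = 400 + i))
      fit_ls_pipeline(coh$features, coh$ls$ls_score, k = 10,
                      seed = 500 + i)$r_discovery
    }, numeric(1)))
  }
  r_small <- r_at(0.1); r_big <- r_at(1.0)
  expect_gt(r_big, r_small)
})

test_that("the nested-PCA variant also recovers strong signal", {
  fx <- make_fitted_pipeline(n = 40, r_n = 10, seed = 29, k = 5)
  coh <- fx$cohort
  pl <- fit_ls_pipeline(coh$features, coh$ls$ls_score, k = 5, seed = 30,
                        nested_pca = TRUE)
  expect_gt(evaluate_predictions(pl$oof$predicted, coh$ls$ls_score)$r, 0.2)
})
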