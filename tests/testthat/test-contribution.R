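test_that("back-projected edge weights reproduce the PCA-path predictions", {
  fx <- make_fitted_pipeline(n = 30, r_n = 10, seed = 33, k = 5)
  pl <- fx$pipeline
  w <- backproject(pl)
  expect_equal(dim(w), c(n_edges(10), 5))
  set.seed(34)
  x_new <- matrix(rnorm(20 * n_edges(10)), 20)
  s_new <- project_pca(pl$pca, x_new)
  xc <- sweep(x_new, 2, pl$pca$center)
  for (f in 1:5) {
    fold <- pl$cv$folds[[f]]
    pca_path <- fold$intercept + s_new %*% fold$coefficients
    edge_path <- fold$intercept + xc %*% w[, f]
    expect_lt(max(abs(pca_path - edge_path)), 1e-8)
  }
})

test_that("zero ridge coefficients back-project to zero edge weights", {
  fx <- make_fitted_pipeline(n = 30, r_n = 8, seed = 35, k = 5)
  pl <- fx$pipeline
  pl$cv$folds[[2]]$coefficients[] <- 0
  w <- backproject(pl)
  expect_equal(w[, 2], rep(0, n_edges(8)))
  # one-component algebra: w proportional to the loading times beta
  pca1 <- fit_pca(fx$cohort$features, 1)
  s1 <- project_pca(pca1, fx$cohort$features)
  cv1 <- fit_cv_ridge(s1, fx$cohort$ls$ls_score, k = 5, seed = 1)
  pl1 <- structure(list(pca = pca1, cv = cv1), class = "ls_pipeline")
  w1 <- backproject(pl1)
  expect_equal(w1[, 3], pca1$transform[, 1] * cv1$folds[[3]]$coefficients,
               ignore_attr = TRUE)
})

test_that("per-edge t-tests match the one-sample t oracle and handle degeneracy", {
  w_row <- c(1.1, 0.9, 1.0, 1.2, 0.8, 1.05, 0.95, 1.15, 0.85, 1.0)
  w <- rbind(w_row,
             rep(c(0.3, -0.3), 5),       # symmetric around 0
             rep(0.7, 10),               # degenerate, nonzero mean
             rep(0, 10))                 # degenerate, zero mean
  expect_warning(tab <- contribution_test(w, alpha = 0.05),
                 "zero across-fold variance")
  oracle <- t.test(w_row)
  expect_equal(tab$t_stat[1], unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(tab$p_value[1], oracle$p.value, tolerance = 1e-12)
  expect_equal(tab$t_stat[1], mean(w_row) / (sd(w_row) / sqrt(10)))

  expect_equal(tab$t_stat[2], 0)
  expect_equal(tab$p_value[2], 1)

  expect_true(tab$degenerate[3])
  expect_equal(tab$p_value[3], 0)
  expect_true(tab$significant[3])
  expect_equal(tab$sign[3], "positive")

  expect_false(tab$degenerate[4])
  expect_equal(tab$p_value[4], 1)
  expect_false(tab$significant[4])

  expect_true(all(tab$significant == (tab$p_value < 0.05 / nrow(w))))
  expect_true(all(tab$sign == ifelse(tab$mean_weight < 0,
                                     "negative", "positive")))
  expect_error(contribution_test(w[, 1, drop = FALSE]), "2 folds")
})

test_that("edge categories count within- and between-network pairs", {
  atlas9 <- default_atlas(427)
  ei <- edge_index_table(427)
  pm <- edge_pair_map(atlas9, ei)
  cats <- unique(pm)
  expect_equal(length(cats), 45)
  expect_equal(sum(vapply(strsplit(cats, "-"),
                          function(h) h[1] == h[2], logical(1))), 9)

  # two networks -> 3 categories
  atlas2 <- tibble::tibble(roi_index = 1:6,
                           roi_name = paste0("r", 1:6),
                           network = rep(c("Vis", "DMN"), each = 3))
  pm2 <- edge_pair_map(atlas2, edge_index_table(6))
  expect_equal(sort(unique(pm2)), c("DMN-DMN", "DMN-Vis", "Vis-Vis"))

  # one network -> everything within
  atlas1 <- tibble::tibble(roi_index = 1:5, roi_name = paste0("r", 1:5),
                           network = "FP")
  expect_equal(unique(edge_pair_map(atlas1, edge_index_table(5))), "FP-FP")

  bad <- atlas2; bad$network[2] <- NA
  expect_error(edge_pair_map(bad, edge_index_table(6)), "missing")
  weird <- atlas2; weird$network[1] <- "Extra"
  expect_error(edge_pair_map(weird, edge_index_table(6)), "Extra")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # worked example: E = 10, category of 4, draw 5, overlap 4
  pm <- rep(c("Vis-Vis", "Vis-DMN"), c(4, 6))
  tab <- edge_enrichment(1:5, pm)   # edges 1:4 in category, edge 5 outside
  row <- tab[tab$pair == "Vis-Vis", ]
  expect_equal(row$overlap, 4L)
  expect_equal(row$p_value, 6 / 252, tolerance = 1e-12)
  expect_equal(row$likelihood, 1 - 6 / 252)

  # brute-force enumeration oracle over all draws, E <= 12
  set.seed(36)
  for (trial in 1:12) {
    e_n <- sample(5:12, 1)
    k_cat <- sample(1:(e_n - 1), 1)
    n_sig <- sample(1:e_n, 1)
    pm_t <- rep(c("FP-FP", "FP-DMN"), c(k_cat, e_n - k_cat))
    sig <- sample.int(e_n, n_sig)
    tab_t <- edge_enrichment(sig, pm_t)
    k_obs <- sum(sig <= k_cat)
    expect_equal(tab_t$p_value[tab_t$pair == "FP-FP"],
                 brute_hyper_upper(k_obs, k_cat, e_n, n_sig),
                 tolerance = 1e-12)
  }
})

test_that("enrichment edge cases: empty set, zero overlap, exhaustive draw", {
  pm <- rep(c("Vis-Vis", "Vis-DMN", "DMN-DMN"), c(3, 4, 3))
  expect_warning(tab0 <- edge_enrichment(integer(0), pm), "empty")
  expect_true(all(tab0$p_value == 1))

  tab_z <- edge_enrichment(4:7, pm)    # nothing drawn from Vis-Vis
  expect_equal(tab_z$p_value[tab_z$pair == "Vis-Vis"], 1)

  tab_all <- edge_enrichment(1:10, pm) # the whole edge set
  expect_true(all(tab_all$p_value == 1))
  expect_equal(tab_all$overlap, tab_all$n_edges_pair)
})

test_that("overlap and category sizes are conserved", {
  set.seed(37)
  atlas <- default_atlas(30)
  ei <- edge_index_table(30)
  pm <- edge_pair_map(atlas, ei)
  sig <- sample.int(n_edges(30), 60)
  tab <- edge_enrichment(sig, pm)
  expect_equal(sum(tab$n_edges_pair), n_edges(30))
  expect_equal(sum(tab$overlap), 60L)
  expect_equal(nrow(tab), 45)
  expect_equal(sum(!tab$within), 36)
})

test_that("planted edges dominate the contribution ranking on strong signal", {
  coh <- generate_edge_cohort(cohort_spec(
    n_subjects = 80, n_rois = 15, n_signal_edges = 12, effect_size = 1,
    seed = 38))
  pl <- fit_ls_pipeline(coh$features, coh$ls$ls_score, k = 10, seed = 39)
  tab <- contribution_test(backproject(pl))
  ranks <- rank(-abs(tab$t_stat))
  planted <- ranks[coh$signal_edges]
  others <- ranks[-coh$signal_edges]
  expect_lt(median(planted), median(others))
})

test_that("contribution_analysis splits enrichment by contribution sign", {
  fx <- make_fitted_pipeline(n = 50, r_n = 12, seed = 40, k = 5,
                             effect = 1, n_signal = 10)
  atlas <- default_atlas(12)
  res <- contribution_analysis(fx$pipeline, atlas,
                               fx$cohort$edge_index)
  expect_equal(nrow(res$contributions), n_edges(12))
  expect_equal(nrow(res$enrichment), 90)
  expect_setequal(unique(res$enrichment$set), c("positive", "negative"))
  pos_rows <- res$enrichment[res$enrichment$set == "positive", ]
  n_pos <- sum(res$contributions$significant &
                 res$contributions$sign == "positive")
  expect_true(all(pos_rows$n_sig == n_pos))
  expect_equal(sum(pos_rows$overlap), n_pos)
})
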