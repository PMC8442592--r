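#' Back-project fold models to edge space
#'
#' Because PCA and ridge regression are both linear, each fold model's
#' prediction can be written directly in edge space:
#' `pred(x) = b_f + w_f' (x - center)` with `w_f = transform %*% beta_f`.
#' This returns the E x k matrix of those edge weights (intercepts are
#' excluded — they carry no edge information). The identity with the
#' PCA-path prediction holds to numerical precision for every input.
#'
#' @param pipeline A fitted [fit_ls_pipeline()] object.
#' @return E x k numeric matrix; column f holds fold f's edge weights.
#' @export
backproject <- function(pipeline) {
  stopifnot(inherits(pipeline, "ls_pipeline"))
  beta <- vapply(pipeline$cv$folds, `[[`, numeric(pipeline$pca$n_components),
                 "coefficients")
  pipeline$pca$transform %*% matrix(beta, ncol = pipeline$cv$k)
}

#' Per-edge contribution t-tests across folds
#'
#' Each edge has k back-projected weights (one per fold). A one-sample
#' t-test against zero (df = k - 1, two-sided) summarizes whether the edge
#' contributes consistently; significance uses a Bonferroni threshold
#' `alpha / E`. The contribution sign is the sign of the mean weight.
#' Degenerate edges with zero across-fold variance get p = 1 when the mean
#' is also zero and p = 0 (flagged) when it is not.
#'
#' @param weights E x k matrix from [backproject()].
#' @param alpha Family-wise error rate before Bonferroni division
#'   (default 0.05).
#' @return Tibble of class `edge_contribution` with columns `edge`,
#'   `mean_weight`, `t_stat`, `p_value`, `significant`, `sign`,
#'   `degenerate`.
#' @export
contribution_test <- function(weights, alpha = 0.05) {
  weights <- as.matrix(weights)
  k <- ncol(weights)
  if (k < 2) abort_param("need at least 2 folds for a t-test")
  e_n <- nrow(weights)
  m <- unname(rowMeans(weights))
  s <- sqrt(unname(rowSums((weights - m)^2)) / (k - 1))
  t_stat <- ifelse(s > 0, m / (s / sqrt(k)), ifelse(m == 0, 0, Inf * sign(m)))
  p <- ifelse(s > 0, 2 * pt(-abs(t_stat), df = k - 1),
              ifelse(m == 0, 1, 0))
  degenerate <- s == 0 & m != 0
  if (any(degenerate)) {
    warning(sprintf("%d edge(s) have zero across-fold variance with nonzero mean",
                    sum(degenerate)), call. = FALSE)
  }
  out <- tibble::tibble(
    edge = seq_len(e_n), mean_weight = m, t_stat = t_stat, p_value = p,
    significant = p < alpha / e_n,
    sign = ifelse(m < 0, "negative", "positive"),
    degenerate = degenerate
  )
  class(out) <- c("edge_contribution", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "n_folds") <- k
  out
}

all_network_pairs <- function(labels = rsn_labels) {
  pairs <- t(utils::combn(labels, 2))
  sort(c(paste(labels, labels, sep = "-"),
         paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]),
               sep = "-")))
}

#' Map edges to unordered network-pair categories
#'
#' Assigns every edge the unordered pair of resting-state network labels
#' of its two ROIs. Nine networks yield 45 categories: 9 within-network
#' plus 36 between-network pairs.
#'
#' @param atlas Atlas label table (see [default_atlas()]), one row per ROI.
#' @param edge_index Canonical edge table from [edge_index_table()]; must
#'   match the atlas ROI count.
#' @return Character vector of length E; each entry is a category label
#'   `"A-B"` with A <= B alphabetically.
#' @export
edge_pair_map <- function(atlas, edge_index) {
  validate_atlas(atlas)
  net <- atlas$network[order(atlas$roi_index)]
  if (max(edge_index$roi_i) > length(net)) {
    abort_param("edge_index refers to ROIs beyond the atlas")
  }
  a <- net[edge_index$roi_i]
  b <- net[edge_index$roi_j]
  paste(pmin(a, b), pmax(a, b), sep = "-")
}

#' Hypergeometric enrichment of an edge set over network pairs
#'
#' For each of the 45 network-pair categories, tests whether the selected
#' edge set overlaps the category more than expected when drawing
#' `n_sig = |set|` edges without replacement from all E edges:
#' upper-tail `p = P(X >= k_c)` with
#' `X ~ Hypergeometric(E, K_c, n_sig)`, computed as `1 - CDF(k_c - 1)`.
#' Significance applies a Bonferroni correction for the 45 categories at
#' level `alpha` (default 0.025, i.e. 0.05 split over the positive and
#' negative edge families).
#'
#' @param sig_edges Integer vector of selected edge indices (canonical
#'   ordering).
#' @param pair_map Character vector of length E from [edge_pair_map()].
#' @param alpha Per-family error rate before the 45-way Bonferroni
#'   division (default 0.025).
#' @param set_label Optional label ("positive"/"negative") stored in the
#'   output.
#' @return Tibble of class `edge_enrichment` with one row per category:
#'   `pair`, `within` (logical), `n_edges_pair` (K_c), `n_sig`, `overlap`
#'   (k_c), `p_value`, `likelihood` (1 - p), `significant`, `set`.
#' @export
edge_enrichment <- function(sig_edges, pair_map, alpha = 0.025,
                            set_label = NA_character_) {
  e_n <- length(pair_map)
  sig_edges <- as.integer(sig_edges)
  if (length(sig_edges) > 0 &&
      (min(sig_edges) < 1 || max(sig_edges) > e_n)) {
    abort_param("sig_edges must index into the edge set")
  }
  if (length(sig_edges) == 0) {
    warning("empty significant edge set; all enrichment p-values are 1",
            call. = FALSE)
  }
  cats <- all_network_pairs(sort(unique(unlist(strsplit(unique(pair_map),
                                                        "-", fixed = TRUE)))))
  cats <- if (length(cats) > 0) cats else character(0)
  n_sig <- length(sig_edges)
  k_cat <- table(factor(pair_map, levels = cats))
  overlap <- table(factor(pair_map[sig_edges], levels = cats))
  n_cat <- length(cats)
  p <- vapply(seq_len(n_cat), function(c) {
    if (n_sig == 0) return(1)
    phyper(overlap[c] - 1, k_cat[c], e_n - k_cat[c], n_sig,
           lower.tail = FALSE)
  }, numeric(1))
  halves <- strsplit(cats, "-", fixed = TRUE)
  out <- tibble::tibble(
    pair = cats,
    within = vapply(halves, function(h) h[1] == h[2], logical(1)),
    n_edges_pair = as.integer(k_cat),
    n_sig = n_sig,
    overlap = as.integer(overlap),
    p_value = p,
    likelihood = 1 - p,
    significant = p < alpha / n_cat,
    set = set_label
  )
  class(out) <- c("edge_enrichment", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Full contribution analysis of a fitted pipeline
#'
#' Back-projects the fold models to edge space, runs the per-edge t-tests,
#' and tests network-pair enrichment separately for the positively and
#' negatively contributing significant edge sets.
#'
#' @param pipeline A fitted [fit_ls_pipeline()] object.
#' @param atlas Atlas label table covering the pipeline's ROIs.
#' @param edge_index Canonical edge table matching the feature columns.
#' @param alpha_edges Pre-Bonferroni level for the edge t-tests
#'   (default 0.05).
#' @param alpha_enrichment Per-sign level for enrichment (default 0.025).
#' @return List with `contributions` (edge tibble joined with ROI pair and
#'   network category), `enrichment` (90-row tibble: 45 categories x 2
#'   signs), `weights` (E x k matrix).
#' @export
contribution_analysis <- function(pipeline, atlas, edge_index,
                                  alpha_edges = 0.05,
                                  alpha_enrichment = 0.025) {
  w <- backproject(pipeline)
  contrib <- contribution_test(w, alpha_edges)
  pm <- edge_pair_map(atlas, edge_index)
  contrib <- dplyr::mutate(contrib,
                           roi_i = edge_index$roi_i,
                           roi_j = edge_index$roi_j,
                           networks = pm)
  pos <- contrib$edge[contrib$significant & contrib$sign == "positive"]
  neg <- contrib$edge[contrib$significant & contrib$sign == "negative"]
  enr <- dplyr::bind_rows(
    edge_enrichment(pos, pm, alpha_enrichment, "positive"),
    edge_enrichment(neg, pm, alpha_enrichment, "negative"))
  list(contributions = contrib, enrichment = enr, weights = w)
}
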