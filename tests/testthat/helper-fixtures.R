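# Small deterministic fixtures built in code.

make_record <- function(t_n = 120, r_n = 6, tr = 1, seed = 99,
                        ls_score = 50) {
  set.seed(seed)
  subject_record(
    subject_id = sprintf("T%03d", seed),
    timeseries = matrix(rnorm(t_n * r_n), t_n, r_n,
                        dimnames = list(NULL, sprintf("ROI_%02d", 1:r_n))),
    motion = cbind(matrix(rnorm(t_n * 3, 0, 0.01), t_n, 3),
                   matrix(rnorm(t_n * 3, 0, 1e-4), t_n, 3)),
    tissue_signals = matrix(rnorm(t_n * 3), t_n, 3),
    tr_seconds = tr, ls_score = ls_score)
}

# brute-force upper-tail hypergeometric: enumerate every draw of n_sig
# edges from E and count draws with >= k overlap in the K-edge category
brute_hyper_upper <- function(k, K, E, n_sig) {
  draws <- utils::combn(E, n_sig)
  in_cat <- colSums(draws <= K)   # category = edges 1..K
  mean(in_cat >= k)
}

make_fitted_pipeline <- function(n = 30, r_n = 10, seed = 7, k = 5,
                                 effect = 0.6, n_signal = 8) {
  coh <- generate_edge_cohort(cohort_spec(
    n_subjects = n, n_rois = r_n, n_signal_edges = n_signal,
    effect_size = effect, seed = seed))
  list(cohort = coh,
       pipeline = fit_ls_pipeline(coh$features, coh$ls$ls_score, k = k,
                                  seed = seed + 1))
}
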