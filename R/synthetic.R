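#' Specify a synthetic cohort
#'
#' Collects the generator parameters for a synthetic resting-state cohort
#' with a sparse set of edges linearly coupled to a continuous trait
#' (life satisfaction, LS). Defaults mirror the study conditions the
#' pipeline targets: a 427-ROI connectome and LS distributed 54.47 +/- 9.00.
#'
#' @param n_subjects Number of subjects.
#' @param n_rois Number of ROIs (default 427).
#' @param n_timepoints Frames per run (time-series mode only; default 300).
#' @param tr_seconds Repetition time in seconds (default 0.72).
#' @param ls_mean,ls_sd Trait mean and SD (defaults 54.47, 9.0).
#' @param n_signal_edges Number of edges coupled to the trait.
#' @param effect_size Per-SD slope of the edge Fisher-z value on
#'   standardized LS (signal edges only).
#' @param edge_noise_sd SD of the edge-level noise (default 1).
#' @param motion_spike_rate Per-frame probability of a motion spike large
#'   enough to trigger scrubbing (time-series mode; default 0).
#' @param family_pairs Number of sibling pairs sharing edge baselines
#'   (default 0; pairs are subjects (1,2), (3,4), ...).
#' @param seed Integer seed; the same spec and seed give bit-identical
#'   cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, n_rois = 427, n_timepoints = 300,
                        tr_seconds = 0.72, ls_mean = 54.47, ls_sd = 9.0,
                        n_signal_edges = 0, effect_size = 0,
                        edge_noise_sd = 1, motion_spike_rate = 0,
                        family_pairs = 0, seed = 1) {
  chk <- function(ok, field, msg) {
    if (!ok) abort_param(sprintf("invalid cohort spec: %s %s", field, msg))
  }
  chk(is.numeric(n_subjects) && n_subjects >= 1, "n_subjects", "must be >= 1")
  chk(n_rois >= 2, "n_rois", "must be >= 2")
  chk(n_timepoints >= 1, "n_timepoints", "must be >= 1")
  chk(tr_seconds > 0, "tr_seconds", "must be > 0")
  chk(ls_sd > 0, "ls_sd", "must be > 0")
  chk(n_signal_edges >= 0 && n_signal_edges <= n_edges(n_rois),
      "n_signal_edges", "must be between 0 and n_rois*(n_rois-1)/2")
  chk(edge_noise_sd > 0, "edge_noise_sd", "must be > 0")
  chk(motion_spike_rate >= 0 && motion_spike_rate <= 1,
      "motion_spike_rate", "must be in [0, 1]")
  chk(family_pairs >= 0 && 2 * family_pairs <= n_subjects,
      "family_pairs", "needs 2 subjects per pair")
  structure(
    list(n_subjects = as.integer(n_subjects), n_rois = as.integer(n_rois),
         n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
         ls_mean = ls_mean, ls_sd = ls_sd,
         n_signal_edges = as.integer(n_signal_edges),
         effect_size = effect_size, edge_noise_sd = edge_noise_sd,
         motion_spike_rate = motion_spike_rate,
         family_pairs = as.integer(family_pairs), seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate an edge-level synthetic cohort
#'
#' Direct edge-space mode: draws, for each subject i and edge e, a Fisher-z
#' feature `z_ie = mu_e + gamma_e * (LS_i - ls_mean) / ls_sd + eps_ie`,
#' with baselines `mu_e ~ Normal(0.2, 0.1)` (a typical empirical
#' connectivity range in Fisher-z units), `gamma_e = effect_size` at the
#' `n_signal_edges` planted edges and 0 elsewhere, and
#' `eps_ie ~ Normal(0, edge_noise_sd)`. `LS_i ~ Normal(ls_mean, ls_sd)`.
#' Sibling pairs (if `family_pairs > 0`) share an extra per-pair baseline
#' offset and have noise correlated 0.5 within the pair.
#'
#' @param spec A [cohort_spec()].
#' @return List with `features` (n x E matrix), `ls` (tibble: subject_id,
#'   ls_score), `signal_edges` (integer vector of planted edge indices in
#'   the canonical ordering), `effects` (per-planted-edge slope),
#'   `edge_index` (tibble), `spec`.
#' @export
generate_edge_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  e_n <- n_edges(spec$n_rois)
  # population structure first, subject-level draws second, so cohorts with
  # the same seed and edge configuration share the planted structure
  mu <- rnorm(e_n, 0.2, 0.1)
  signal_edges <- sort(sample.int(e_n, spec$n_signal_edges))
  ls <- rnorm(n, spec$ls_mean, spec$ls_sd)
  z_ls <- (ls - spec$ls_mean) / spec$ls_sd
  gamma <- numeric(e_n)
  gamma[signal_edges] <- spec$effect_size

  eps <- matrix(rnorm(n * e_n, 0, spec$edge_noise_sd), n, e_n)
  base <- matrix(mu, n, e_n, byrow = TRUE)
  if (spec$family_pairs > 0) {
    for (p in seq_len(spec$family_pairs)) {
      a <- 2L * p - 1L; b <- 2L * p
      pair_mu <- rnorm(e_n, 0, 0.05)
      base[a, ] <- base[a, ] + pair_mu
      base[b, ] <- base[b, ] + pair_mu
      # within-pair noise correlation 0.5, marginal SD preserved
      eps[b, ] <- 0.5 * eps[a, ] + sqrt(0.75) * eps[b, ]
    }
  }
  features <- base + outer(z_ls, gamma) + eps
  ids <- sprintf("S%04d", seq_len(n))
  rownames(features) <- ids
  list(features = features,
       ls = tibble::tibble(subject_id = ids, ls_score = ls),
       signal_edges = signal_edges,
       effects = gamma[signal_edges],
       edge_index = edge_index_table(spec$n_rois),
       spec = spec)
}

# Unit-variance noise confined to the connectivity pass band, so that
# generated signals survive band-pass filtering during post-processing.
bandlimited_noise <- function(n_frames, n_series, tr_seconds,
                              band = c(0.01, 0.09)) {
  x <- matrix(rnorm(n_frames * n_series), n_frames, n_series)
  nyq <- 1 / (2 * tr_seconds)
  hi <- min(band[2], 0.9 * nyq)
  f <- as.matrix(bandpass(x, band[1], hi, tr_seconds))
  f <- sweep(f, 2, colMeans(f))
  sweep(f, 2, apply(f, 2, sd), `/`)
}

#' Generate a time-series synthetic cohort
#'
#' Full-path mode: each subject's R-ROI time series comes from a factor
#' model. Every ROI loads on a small set of background factors (subject
#' specific; shared within sibling pairs), tissue processes are partially
#' mixed into all ROIs, and each planted signal edge receives a shared
#' latent source whose loading grows with the subject's standardized LS, so
#' the edge's empirical correlation increases with the trait. Motion
#' parameters are smooth random walks; with probability
#' `motion_spike_rate` a frame receives a translation jump drawn
#' Uniform(0.6, 1.5) mm on one axis — guaranteeing framewise displacement
#' above the 0.5 mm scrubbing threshold — and a broadband artifact is added
#' to every ROI at that frame.
#'
#' All series are band-limited to the connectivity pass band so the planted
#' structure survives post-processing. Requires
#' `n_timepoints >= 80` (four times the 20 nuisance regressors).
#'
#' @param spec A [cohort_spec()].
#' @return List with `subjects` (list of [subject_record()]),
#'   `ls` (tibble), `signal_edges`, `effects`, `edge_index`, `spec`.
#' @export
generate_timeseries_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_timepoints < 80) {
    abort_param("n_timepoints must be >= 80 (4 x 20 nuisance regressors)")
  }
  set.seed(spec$seed)
  n <- spec$n_subjects
  r_n <- spec$n_rois
  t_n <- spec$n_timepoints
  e_n <- n_edges(r_n)
  ei <- edge_index_table(r_n)

  signal_edges <- sort(sample.int(e_n, spec$n_signal_edges))
  ls <- rnorm(n, spec$ls_mean, spec$ls_sd)
  z_ls <- (ls - spec$ls_mean) / spec$ls_sd
  sig_i <- ei$roi_i[signal_edges]
  sig_j <- ei$roi_j[signal_edges]

  n_bg <- 5L                 # background factors per subject
  tissue_mix <- 0.2          # tissue-to-ROI mixing weight
  base_r <- 0.25             # baseline signal-edge correlation target
  slope_r <- 0.12            # correlation increment per SD of LS per unit effect

  sibling_of <- rep(NA_integer_, n)
  if (spec$family_pairs > 0) {
    sibling_of[2L * seq_len(spec$family_pairs)] <-
      2L * seq_len(spec$family_pairs) - 1L
  }

  loadings <- vector("list", n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(sibling_of[i])) {
      b_mat <- loadings[[sibling_of[i]]]   # siblings share background loadings
    } else {
      b_mat <- matrix(rnorm(r_n * n_bg, 0, 0.35), r_n, n_bg)
    }
    loadings[[i]] <- b_mat

    f_bg <- bandlimited_noise(t_n, n_bg, spec$tr_seconds)
    x <- bandlimited_noise(t_n, r_n, spec$tr_seconds) + f_bg %*% t(b_mat)

    tissue <- bandlimited_noise(t_n, 3, spec$tr_seconds)
    w_tis <- matrix(rnorm(r_n * 3, 0, tissue_mix), r_n, 3)
    x <- x + tissue %*% t(w_tis)

    if (length(signal_edges) > 0) {
      src <- bandlimited_noise(t_n, length(signal_edges), spec$tr_seconds)
      r_target <- min(max(base_r + slope_r * spec$effect_size * z_ls[i],
                          0.02), 0.9)
      alpha <- sqrt(r_target / (1 - r_target))
      for (k in seq_along(signal_edges)) {
        a <- sig_i[k]; b <- sig_j[k]
        x[, a] <- x[, a] + alpha * sd(x[, a]) * src[, k]
        x[, b] <- x[, b] + alpha * sd(x[, b]) * src[, k]
      }
    }

    motion <- cbind(
      apply(matrix(rnorm(t_n * 3, 0, 0.01), t_n, 3), 2, cumsum),
      apply(matrix(rnorm(t_n * 3, 0, 2e-4), t_n, 3), 2, cumsum))
    spike <- runif(t_n) < spec$motion_spike_rate
    spike[1] <- FALSE
    for (t in which(spike)) {
      axis <- sample.int(3, 1)
      motion[t, axis] <- motion[t, axis] + runif(1, 0.6, 1.5)
      x[t, ] <- x[t, ] + rnorm(r_n, 0, 4)   # broadband artifact at the spike
    }

    tissue_obs <- tissue + matrix(rnorm(t_n * 3, 0, 0.05), t_n, 3)
    colnames(x) <- sprintf("ROI_%03d", seq_len(r_n))
    subjects[[i]] <- subject_record(sprintf("S%04d", i), x, motion,
                                    tissue_obs, spec$tr_seconds, ls[i])
  }

  list(subjects = subjects,
       ls = tibble::tibble(subject_id = sprintf("S%04d", seq_len(n)),
                           ls_score = ls),
       signal_edges = signal_edges,
       effects = rep(spec$effect_size, length(signal_edges)),
       edge_index = ei, spec = spec)
}
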