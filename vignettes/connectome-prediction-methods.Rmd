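---
title: "Methods: connectome-based prediction of life satisfaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-based prediction of life satisfaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the model it implements, the
choices that were genuinely open, and what the synthetic tests do and do
not establish about real resting-state data.

## The model

The quantity being predicted is a continuous trait score — life
satisfaction (LS), a self-reported global evaluation measured on a scale
where healthy young adults average about 54.5 points with an SD of 9. The
predictor is the subject's intrinsic functional connectome: the vector of
Fisher-z transformed Pearson correlations `z = atanh(r)` between all
pairs of ROI time series. With R ROIs there are E = R(R−1)/2 unique
edges (90,951 for the default 427-ROI parcellation: 400 cortical, 17
subcortical, 10 cerebellar parcels). Edges follow a fixed canonical
ordering — the strict lower triangle, row-major — identical across
subjects and cohorts, so discovery and validation feature matrices are
column-compatible by construction.

The prediction pipeline is linear end to end:

* **PCA** on the centered discovery feature matrix keeps up to
  min(n − 1, E) components (99 for n = 100). The transformation matrix and
  center are frozen; validation cohorts are projected, never refit.
* **Ridge regression** on the component scores, minimizing
  `sum (y_i − b − βᵀs_i)² + λ‖β‖²` with an unpenalized intercept. The
  outer 10-fold cross-validation assigns subjects by a seeded shuffle
  (fold sizes within 1 of each other, no stratification); within each
  outer training set, a 5-fold inner loop picks λ from 13 log-spaced
  values 10⁻³…10³ by minimum mean squared error, ties broken toward the
  larger penalty. The fold model is then refit on the full outer training
  set. Outer test folds never touch hyperparameter selection — permuting a
  fold's test responses provably leaves its fitted model unchanged, and a
  unit test asserts exactly that.
* **Evaluation** is the Pearson correlation between out-of-fold
  predictions (each subject predicted by the one model not trained on it)
  and actual scores; external validation averages the 10 fold models'
  predictions, which by linearity equals prediction under the averaged
  coefficients.

Significance comes from permutation: the trait vector is shuffled, the
entire supervised stage rerun (fold assignment redrawn by default), and
the observed r compared against the null distribution with the add-one
estimator `p = (1 + #{null ≥ observed}) / (1 + n_perm)`, one-sided in the
upper tail since the hypothesis is positive predictability (a two-sided
flag compares |r|). PCA is *not* refit inside the permutation loop: it
never sees the trait, so a shuffle cannot change it — reuse is an
exactness-preserving optimization, not an approximation.

### Interpretation in edge space

Both stages being linear, fold f's prediction is an affine function of
the edge vector: `pred(x) = b_f + w_fᵀ(x − center)` with
`w_f = T β_f`, T the E×K loading matrix. The package tests this identity
to 1e−8 on random inputs — it is the correctness oracle for the whole
back-projection. The k weights per edge feed a one-sample t-test
(df = k − 1, two-sided; Bonferroni 0.05/E), and the significant sets,
split by the sign of the mean weight, enter a hypergeometric enrichment
over the 45 unordered pairs of the nine resting-state networks: upper-tail
`P(X ≥ k_c)` with population E, K_c edges in the category, and |set|
draws, Bonferroni-corrected at 0.025/45 per sign family (0.05 split over
the two families). The population includes all E edges, not only
significant ones; this matches the edge-overlap convention of prior
network-anatomy analyses, and is configurable in the sense that the
enrichment function takes any edge set and pair map.

## Post-processing choices

The preprocessing order is fixed and logged in the function contract:
drop the first 10 s → nuisance regression → band-pass → scrub →
correlation. Published descriptions of such pipelines rarely pin down the
relative order of filtering and scrubbing; we filter first and then drop
flagged frames without interpolation, the simplest faithful reading, and
keep each step an exported function so any other order can be composed.

* **Nuisance model** (20 columns): intercept, centered linear trend, six
  rigid-body motion parameters, three tissue means (white matter,
  ventricle, gray matter), and backward-difference derivatives (first row
  zero) of the nine motion/tissue signals. Detrending rides in the same
  single-pass OLS as the other regressors. Rank-deficient designs fall
  back to the pseudoinverse with a warning rather than failing.
* **Band-pass**: 4th-order Butterworth, applied forward–backward for zero
  phase (the field's convention when only a band is specified), after
  per-column demeaning and with odd-symmetric reflection padding
  (min(T − 1, 100) samples) to tame edge transients. The tested contract
  is gain within [0.9, 1.1] at 0.05 Hz and below 0.1 at 0.3 Hz for
  TR = 0.72 s.
* **Framewise displacement**: `FD_t = Σ|Δtrans| + 50 mm · Σ|Δrot|`,
  rotations in radians (input files must declare units; readers reject
  undeclared motion files). Frames with FD strictly above 0.5 mm are
  removed — boundary frames are retained, only the flagged frame is
  dropped (no neighbor augmentation). Subjects retaining fewer than 50
  frames (configurable) are flagged for exclusion and reported, mirroring
  the usual unquantified "excessive motion" exclusion.
* **Degenerate correlations**: |r| ≥ 1 − 1e−12 between distinct ROIs
  raises an error instead of emitting an infinite Fisher z; zero-variance
  ROIs are named in the error.

## The synthetic cohort generator

The generator defines the study conditions under which everything is
tested. Defaults mirror the reference design: LS ~ Normal(54.47, 9.0²),
427 ROIs, TR 0.72 s, a discovery cohort of ~100 subjects and a larger
validation cohort drawn as disjoint subsets of one generated population
(so both share the same trait-coupled edge structure, exactly as a single
study sample split into discovery and validation halves would).

**Edge mode** draws features directly:
`z_ie = μ_e + γ_e·(LS_i − μ_LS)/σ_LS + ε_ie`, with baselines
μ_e ~ Normal(0.2, 0.1) in Fisher-z units (a typical empirical
connectivity range, keeping back-transformed r plausibly inside (−1, 1)),
γ_e equal to `effect_size` on the planted edges and zero elsewhere, and
ε ~ Normal(0, `edge_noise_sd`). Optional sibling pairs share a per-pair
baseline offset (SD 0.05) and have within-pair noise correlation 0.5 —
family structure as shared baseline rather than explicit kinship
modeling, since the reference design handles relatedness by subject
selection, not by a genetic model.

**Time-series mode** exercises the full post-processing path. Each
subject's R-ROI series is a factor model: unit-variance band-limited
noise (white noise filtered to 0.01–0.09 Hz so the planted structure
survives the analysis band-pass) plus five background factors with
subject-specific loadings ~ Normal(0, 0.35) (shared within sibling
pairs), tissue processes mixed in with weights ~ Normal(0, 0.2), and one
shared latent source per planted edge whose loading sets a target
correlation `r = clip(0.25 + 0.12·effect_size·z_LS, 0.02, 0.9)`. Because
the background factors also contribute covariance, the attained edge
correlation is not controlled exactly; the tested contract is
directional — planted-edge Fisher z increases with LS — not calibrated.
Motion is a smooth random walk (translation steps SD 0.01 mm, rotation
steps SD 2e−4 rad); with probability `motion_spike_rate` a frame gets a
translation jump Uniform(0.6, 1.5) mm on one axis, guaranteeing FD above
the 0.5 mm threshold, plus a broadband artifact across all ROIs.

What the generator does **not** emulate: hemodynamics, spatial structure
(no volumes or surfaces — label tables only), realistic noise spectra,
scanner drift beyond a linear trend, or distance-dependent motion
artifacts. Passing tests therefore demonstrate the statistical machinery
is correct and calibrated under the stated generative model, not that the
pipeline removes all artifact classes found in real acquisitions.

## Numerical choices

* Ridge is solved by SVD of the centered score matrix, which makes the
  whole λ grid nearly free per fold and handles λ = 0 as a pseudoinverse
  OLS. The independent oracles in the tests are `lm.fit` on the
  ridge-augmented system (a QR route) and the normal-equations closed
  form.
* PCA component signs are fixed (largest-magnitude loading positive) so
  fitted models are reproducible across platforms; requesting more
  components than the rank truncates with a warning.
* Per-iteration permutation seeds are derived from the master seed up
  front, so results are independent of execution order and reproducible
  bit for bit; every derived seed stays inside 32-bit integer range.
* Degenerate contribution t-tests (zero across-fold variance) get p = 1
  at zero mean and p = 0 (flagged) at nonzero mean, and the flagged count
  is surfaced rather than silently absorbed.
* The intercepts are excluded from back-projection — they carry no edge
  information.

## Open design points, resolved

* *PCA inside or outside the CV loop.* The reference procedure fits PCA
  once on the full discovery set before the fold split; we reproduce that
  as the default and document the (unsupervised) leakage caveat. A
  strictly nested variant — PCA refit per outer training set for the
  out-of-fold evaluation — is available via `nested_pca = TRUE`.
* *"Averaged predicted" at the discovery stage.* Averaging is
  unambiguous on the validation side (10 fold models, one cohort); on the
  discovery side each subject has exactly one out-of-fold prediction, and
  that is the default evaluation. Repeated-CV averaging can be composed
  from the exported pieces if wanted; the single-pass default keeps the
  permutation test exact and cheap.
* *Fold re-draw under permutation.* The null refits redraw fold
  assignments each iteration (the statistic's full variability);
  `refit_folds = FALSE` fixes them to the observed assignment.
* *λ grid, inner fold count, sidedness.* Not pinned down by the reference
  description; the defaults (13-point log grid, 5 inner folds, upper-tail
  p) are stated here once and wired through `run_config()` so they are
  provenance-logged with every run.

## Problem sizes used in the shipped tests

The test suite and acceptance script run the pipeline at reduced
connectome sizes chosen to exercise every code path with comfortable
statistical power: null calibration on 50 effect-free cohorts (n = 60,
R = 30, 99 permutations, nominal α = 0.1), planted-edge recovery on 20
cohorts (n = 100, R = 40, 30 planted edges, effect 0.5 per SD, noise SD
1), a full discovery (n = 100) + validation (n = 300) study with 199
permutations per stage, and an end-to-end time-series smoke study
(24 + 24 subjects, R = 20, 120 frames). The structural checks (90,951
edges at 427 ROIs, 99 components at n = 100, 45 network pairs) run at
full scale, as does the default atlas.

## Known limitations

* The synthetic atlas reproduces parcel counts and the nine-network
  partition, not anatomy; network-level enrichment on synthetic cohorts
  is a correctness check of the machinery, not a neuroscientific claim.
* Only single-run records are modeled; multi-run sessions should be
  concatenated after per-run preprocessing before `connectivity()`.
* No node-level (ROI) importance is computed — interpretation stops at
  edges and network pairs by design.
* Leave-one-out evaluation is out of reach of `fit_cv_ridge()` (it
  requires n ≥ 2k so every inner loop has data); use modest k for small
  cohorts.
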