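---
title: "Active-learning media optimisation: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-learning media optimisation: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediaopt)
```

`mediaopt` implements a Design–Build–Test–Learn loop for maximising a
fermentation titre over glucose and ammonium-chloride concentrations, and
the post-hoc analyses of the resulting response surfaces. This vignette
explains the models and algorithms, the synthetic-data generator that
stands in for the wet lab, the tunable parameters that matter, and the
design choices made where several defensible options existed.

## The surrogate model

Relative titres (peak areas normalised to the per-batch M9 reference, so
M9 ≡ 1.0) are modelled as a Gaussian process over the design space
(default glucose ∈ [0.1, 2] % w/v, NH4Cl ∈ [5, 120] mM — wide enough to
contain both the found and the literature optima). Inputs are mapped to
the unit square; outputs are z-scored per fit, with both transforms
stored for exact de-standardisation.

The kernel is Matérn-5/2 with separate lengthscales per axis and a signal
variance; the observation model adds a fixed per-point noise variance —
the squared standard error of the replicate mean (SEM²) of each
condition — plus a small fitted homoscedastic jitter. This is the
"heteroskedastic GP" of the pipeline: noise variances come from the data's
own replicate scatter rather than a learned noise process. Fitting on raw
replicates instead of replicate means is possible by passing per-well
rows to `gp_dataset()` directly.

Hyperparameters maximise the log marginal likelihood with analytic
gradients, under bounded multi-start L-BFGS-B (8 restarts, lengthscales
∈ [0.05, 5] on the unit-square scale, variances ∈ [1e-6, 10]). By default
the objective includes weak log-normal priors on the log hyperparameters
(lengthscales centred at 0.3, signal variance at the z-scored unit), i.e.
MAP rather than pure ML-II. The reason is practical and visible at
iteration 0: with only ~8 conditions, unpenalised ML-II regularly selects
a boundary lengthscale (one axis effectively flat) and becomes severely
overconfident, which both misleads the acquisition and corrupts the
iteration-over-iteration uncertainty comparison. The priors are weak
enough that with tens of points the MAP and ML fits agree; `prior =
"none"` in `gp_fit_config()` restores pure ML-II. The reported prediction
uncertainty is the posterior standard deviation of the latent mean
(observation noise excluded), matching the standard-error-of-the-mean
convention of the uncertainty maps.

## The acquisition

Batches are scored by Monte-Carlo q-noisy expected improvement: joint
posterior samples of the latent titre at the observed and candidate
points, improvement per sample `max(0, max over candidates − (max over
observed + ξ))`, averaged over samples. The exploration offset ξ defaults
to 0.01 on the relative-titre scale — the acquisition's
exploitation/exploration balance parameter. The incumbent under noise is
the maximum posterior mean at the observed points (configurable to the
maximum raw observation).

Sampling uses randomised-shift Halton quasi-Monte-Carlo normal draws when
the joint dimension is at most 12 (small-q scoring, where QMC error decays
near 1/N) and antithetic pseudo-Monte-Carlo pairs above (pool scoring).
`analytic_ei()` provides the closed-form q = 1 oracle used to validate
the estimator.

Batch construction is greedy-sequential rather than a joint q-dimensional
optimisation: at each of q steps, a seeded space-filling candidate pool
(Halton draws plus the current posterior-mean grid argmax) is scored
conditioned on the already-selected members through the shared joint
samples, and the argmax is added. Greedy construction is robust, trivially
parallelisable over the pool, and — because joint samples at nearby
points are strongly correlated — naturally diversifies. Two parameters
matter:

* `min_sep` (default 0.18 on the unit square): minimum pairwise
  separation between batch members. Without it greedy qNEI batches can
  collapse onto the incumbent peak; a fifth of an axis range keeps the
  plate's seven combinations experimentally distinguishable and preserves
  the exploration that drives the uncertainty decrease across iterations.
* `pool_size` / `mc_samples` (2048/4096 standalone; the loop uses
  512/2048): a 2-D space does not need a larger pool, and the loop sizes
  keep replicated multi-seed studies quick while leaving proposals
  unchanged in practice.

## The loop

Iteration 0 designs by centred Latin hypercube (7 points: one point per
axis bin, at bin centres, under seeded permutations); iterations 1 and 2
by qNEI batches. Every iteration's plate carries the 7 combinations plus
`control` (M9 salts, no added C/N; excluded from the surrogate) and
`M9_reference` (complete M9) in 6 randomised complete blocks laid out as
contiguous row-major well runs (column-major available). The M9 reference
enters the surrogate as a training point at the baseline composition
(relative titre exactly 1 after normalisation, with its replicate SEM),
anchoring the model where the normalisation is defined.

Per iteration the loop records the design, the processed
relative-abundance table, the refitted model, the 101×101 posterior
landscape ("dense grid"), and the mean grid uncertainty.
`best_improvement()` reports `100 × (best replicate-mean relative titre −
1)` — replicate means, not single wells, for robustness to single-well
outliers — while `predicted_optimum()` reports the model-predicted
argmax; the two deliberately answer different questions.
`performance_cliff()` masks the grid where the predicted titre falls
below 0.5 of M9 and traces the threshold contour.

All randomness flows from one root seed through tagged derived streams
(`derive_seed`), so every stage is independently reproducible and stable
under configuration changes elsewhere.

## Signal processing

Each (well, signal) injection trace spans 1 minute (121 samples at 2 Hz).
Processing chains four steps:

1. **AsLS baseline** (`lam = 1e6`, `p = 0.01`, the standard defaults):
   iteratively reweighted second-difference-penalised smoothing. The
   second-difference penalty leaves linear trends unpenalised, so linear
   drifts are recovered essentially exactly away from the peak; the
   residual error is the p-controlled asymmetry bias (order p × peak
   mass), about half a percent of the signal scale at defaults. Whether a
   trace is corrected at all is decided by a drift statistic (robust
   linear fit on the trailing 40 % of the trace, triggered at 0.5 % of
   the trace maximum) rather than a hand-curated signal list; an explicit
   list, `"all"`, or `"none"` can be passed instead.
2. **Trapezoid integration** of intensity − baseline over the time grid.
   Negative residuals are retained — clipping would bias low-abundance
   wells upward.
3. **IQR outlier filter** per treatment × signal × batch replicate group
   (the natural replication unit of the block design): keep values in
   median ± 1.5 IQR, quartiles by linear interpolation (type 7; the
   convention is recorded in the QC metadata). Groups below 4 values pass
   unfiltered — quartiles of 3 points are too unstable to reject data on.
4. **M9 normalisation**: divide kept areas by the mean kept
   `M9_reference` area of the same batch and signal, making the M9 wells
   of each batch average to exactly 1.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline's behaviour is demonstrated.

**Titre landscape.** A sum of anisotropic Gaussian bumps plus a constant
floor, algebraically anchored so f(M9) = 1 exactly and f(peak) equals the
specified maximum — default 2.6× at 0.8 % glucose / 50 mM NH4Cl, the
160 % improvement scale. With the default widths (0.35 %, 30 mM) the
floor lands at ≈ 0.31, so a genuine sub-0.5 performance-cliff region
exists at the space margins.

**Noise.** Replicate noise is multiplicative with CV growing linearly in
the surface value (`cv_eff = 0.15 × (1 + 0.2 v)`): biological variation
is known to grow with signal, and 15 % replicate CV is typical of
plate-scale fermentation titres. Traces additionally get a linear
baseline drift (magnitude 0.3 intensity units against a peak height of
~8 per unit relative titre) and white noise (sd 0.01); gross outliers are
optional (`outlier_prob`, `outlier_scale`).

**Growth.** Logistic curves sampled every 10 min for 36 h from an initial
OD600 of 0.1, rate 0.012 min⁻¹ and inflection at 600 min (exponential
doubling ~1 h, stationary phase from ~10–16 h — realistic for *B.
subtilis* microplates). The carrying capacity is a Monod-type smooth
function of glucose and NH4Cl. The true coupling between growth and titre
surfaces is unknown, so it is an explicit parameter (`K_fun`) rather than
a hard-wired trade-off shape: the Pareto analysis is demonstrated on, not
calibrated to, the default coupling.

**Metabolite panel.** 25 signals in four groups (6/7/7/5) plus the two
growth-derived signals downstream. Each surface is
`1 + a·q(x)·w(r) (+ asymmetric term)` in ellipse-normalised polar
coordinates about the titre peak (the ellipse with half-axes 0.6 %
glucose / 24 mM NH4Cl maps to the unit circle). The correlation structure
is planted through convex mixtures of independent smooth random fields:
members share a group latent with weight `within_group_weight` (0.85),
group latents share a panel-common core with weight
`between_group_weight` (0.4) and per-group signs (amino-acid-type groups
negative against the lipopeptide and organic-acid groups). The fields are
variance-normalised over the space so the mixture weights translate
directly into correlation strength.

The window `w(r)` vanishes at the centre and on the unit ring, and the
planted anisotropic members (exactly `n_asymmetric = 6`) add
`a·β·cos(θ − θ₀)·v(r)` with `v` rising from 0 at the centre to 1 on the
ring. This construction makes the symmetry dichotomy exact rather than
statistical: a gradient profile averages finite-difference slopes along a
radial path, which telescopes to the centre-to-ring difference, so
non-planted members (zero net change in every direction) have
direction-independent profiles, while planted members' profiles are
proportional to |cos(θ − θ₀)| — asymmetry index ≈ π/2 — however their
correlation field happens to look. A generic smooth surface with non-zero
gradient at the centre would have index ≈ π/2 too, which is why
"symmetric" panel members must be constructed as symmetric, not merely
hoped to be.

What the generator does **not** emulate: instrument-specific trace
shapes (SRM transitions, vendor formats), isotope effects, plate-position
(edge) effects, batch drift between plates, or any mechanistic link
between the panel surfaces and pathway stoichiometry. Passing tests
therefore demonstrate the pipeline's correctness and its behaviour under
calibrated noise — not that real fermentations will reproduce the same
numbers.

## Downstream analyses

* **Correlation clustering**: Spearman correlation (mid-rank ties;
  pairwise-complete observations optional for post-QC missingness),
  agglomerative clustering on 1 − ρ. Average linkage was chosen as the
  standard compromise for correlation heatmaps (single chains, complete
  over-fragments); the distance and linkage are recorded with the result.
* **PCA**: column-centred SVD, unit-variance scaling by default (the
  panel mixes lipopeptides and organic acids of different magnitudes),
  deterministic sign convention (largest-magnitude loading positive).
* **Pareto trade-off**: seeded uniform sampling of the space, predicted
  (titre, max OD) per point, non-dominated set under joint maximisation
  by an O(n log n) sweep (validated against the quadratic dominance
  oracle in the tests).
* **Anisotropy**: straight radial paths from the titre maximum to the
  0.6 %/24 mM ellipse in 36 directions, 100 points per path, average
  finite-difference slope per direction with arc length normalised to 1.
  Straight paths follow the operational description of the analysis
  (gradients along sampled radial paths); tracing true orthogonal
  trajectories of the level curves is a more complex alternative reading
  and was not implemented. Angles live in the ellipse-normalised
  coordinates, where "direction" is well-defined across the heterogeneous
  axis units; 0° is a pure glucose increase, 90° pure NH4Cl. Signed
  gradients are primary; the asymmetry index `(max|g| − min|g|) /
  mean|g|` with threshold 0.5 separates the two regimes above cleanly
  (≈ 0 vs ≈ π/2). The centre defaults to the model-predicted maximum
  (the analysis runs on model surfaces); the observed-best composition
  can be passed explicitly.

## Numerical choices and degenerate inputs

* Cholesky factorisations escalate jitter (1e-10 → 1e-4) before failing;
  non-PSD covariances after escalation are an error, not a warning.
* Posterior variances are clamped at 0 before square roots.
* A constant-titre landscape (`peak_relative_height = 1`) is generated
  exactly; the loop then reports improvement within replicate noise of 0
  and proposals stay spread out.
* Zero-variance signals make Spearman correlations NA (with a warning)
  and are a hard error in standardised PCA.
* Anisotropy paths leaving the space are clipped at the boundary and
  flagged; fully clipped directions are reported missing; an on-boundary
  centre warns.
* All generators, fits and proposals are bit-reproducible given the root
  seed; derived streams keep every stage stable when other stages change.

## Problem sizes

The replicated studies in the test suite use the study conditions — 3
iterations × 7 combinations × 6 blocks at 15 % replicate CV, 20 seeds —
with the loop's acquisition sizes (pool 512, 2048 MC samples) and a
101×101 landscape grid; panel analyses use 200 sampled compositions and
20 seeds. These sizes were chosen as the smallest at which the replicated
behaviour is stable; all are configurable upward.

## Known limitations

* The surrogate's noise model is fixed per-point SEM²; a learned
  input-dependent noise process is out of scope by design.
* Hyperparameters are point estimates (MAP); no fully Bayesian treatment.
* The acquisition optimises over a finite pool, not by gradients; in 2-D
  this is ample, in higher dimensions it would not be.
* Block geometry is contiguous well runs; no edge-effect modelling or
  Latin-square balancing across plate rows/columns.
* The equivalence of the block-randomisation permutation stream with any
  specific external randomisation tool is not attempted; only the
  randomised-complete-block property itself is guaranteed and audited.
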