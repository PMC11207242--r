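---
title: "Frequency-spatial feature fusion for motor-imagery EEG: methods and design notes"
author: "fsff package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fsff methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The decoding problem

Imagining a left- versus right-hand movement modulates the power of
sensorimotor EEG rhythms in subject-specific frequency bands (event-related
desynchronization/synchronization, ERD/ERS). A two-class motor-imagery
decoder therefore has to find, per subject, *which bands* and *which spatial
projections* of the multichannel signal carry class information. `fsff`
implements a classical machine-learning pipeline for this problem:

1. **Overlapping multi-scale filter bank.** Each epoch is band-pass
   filtered into 19 sub-bands covering 4–40 Hz: nine narrow 4 Hz bands on a
   4 Hz grid, eight wide 8 Hz bands on a 4 Hz step, and two broad bands
   (4–32, 12–40 Hz). Narrow bands resolve fine spectral structure; wide and
   broad bands capture energy that a rigid non-overlapping segmentation
   splits apart. The bank is fully configurable; `fbcsp` (nine
   non-overlapping 4 Hz bands) and `single` (one 4–40 Hz band) presets
   support ablation comparisons.
2. **Per-band common spatial patterns (CSP).** For each band, per-trial
   covariances are trace-normalized and averaged within class; the composite
   $C_1 + C_2$ is whitened and the whitened $C_1$ eigendecomposed. Spatial
   filters are the eigenvector rows composed with the whitener; the
   eigenvalues $\lambda_k \in [0,1]$ satisfy
   $\lambda_k^{(1)} + \lambda_k^{(2)} = 1$ and measure each filter's
   discriminability by their distance from $1/2$. Each trial contributes,
   per band and retained filter $k$, the log-variance feature
   $\log\!\big(\mathrm{var}(w_k^\top X) / \sum_j \mathrm{var}(w_j^\top X)\big)$,
   which is invariant to trial-wide amplitude scaling.
3. **AS-LASSO feature selection.** A weighted $\ell_1$ regression of the
   $\pm 1$ labels on the standardized features,
   $$\min_\beta \;\|y - X\beta\|_2^2 + \lambda \sum_i e^{-\mu s_i e_i}\,|\beta_i|,$$
   where $s_i \in [0,1]$ is the symmetric uncertainty between feature $i$
   and the labels, $s_i = 2 I(x_i;y)/(H(x_i) + H(y))$, and
   $e_i = |\lambda_i - \bar\lambda_{b(i)}|$ is the feature's spatial
   information (distance of its CSP eigenvalue from its band's spectrum
   mean). Weights $w_i = e^{-\mu s_i e_i}$ are inversely related to feature
   importance: task-relevant, spatially significant features are penalized
   less. Features with nonzero $\hat\beta$ are kept.
4. **Classification.** An RBF-kernel SVM (C = 1, bandwidth
   $\gamma = 1/(p\,\mathrm{var}(X))$) on the selected, re-standardized
   features; KNN, LDA, random forest and decision tree plug into the same
   harness.

The weighted problem is solved by the standard rescaling reduction: with
$x_j^{**} = x_j / w_j$ the plain LASSO solution $\hat\beta^{**}$ on the
rescaled design maps back as $\hat\beta_j = \hat\beta_j^{**}/w_j$, and the
plain problem is solved by cyclic coordinate descent. With $\mu = 0$ all
weights are 1 and the model reduces exactly to plain LASSO; with
$w = 1/|\hat\beta^{\mathrm{ols}}|^\gamma$ it reproduces the classical
adaptive LASSO — both reductions are verified in the test suite against an
independent solver (glmnet).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `bank` | 19-band overlapping | band edges in Hz; presets `default`, `fbcsp`, `single` |
| filter order | 5 | Butterworth order per band (zero-phase doubles it) |
| `n_filters_per_band` | 2 | CSP filters kept per band |
| `csp_mode` | `paired` | `paired` = largest+smallest eigenvalue filters; `largest` = literal top of the spectrum |
| `shrinkage_eps` | 1e-6 | diagonal covariance shrinkage, fraction of trace/$n_{ch}$ |
| `n_bins` | $\max(2,\lfloor\sqrt n\rfloor)$ | equal-frequency bins for symmetric uncertainty |
| `mu` | 1 | penalty-weight adjustment; 0 disables weighting |
| `lambda` | inner 5-fold CV | $\ell_1$ penalty on the unscaled objective |
| `lambda_criterion` | `class` | CV score: downstream-classifier error, or `mse` |
| `fallback_k` | 4 | columns kept if the solution is all-zero |
| `cv_folds` | 5 | outer stratified folds in `crossval()` |

## Design choices in detail

**Zero-phase filtering.** CSP consumes variances, so filter phase is
irrelevant but variance fidelity matters. Time-domain forward–backward
filtering of short (4 s) epochs leaks start-up ringing of the narrowband
order-5 filters (impulse responses decay over hundreds of samples) at the
$10^{-3}$ level. `apply_bank()` therefore applies the *squared Butterworth
magnitude response* on the DFT grid of the mirror-extended epoch: this is
the exact steady-state response of a forward–backward pass, exactly linear
and zero-lag, with no start-up transient. A 10 Hz sinusoid through the
8–12 Hz band keeps ≥ 97% of its variance; a 25 Hz sinusoid keeps ≤ 0.1%.

**Discretization for symmetric uncertainty.** CSP log-variance features are
continuous; entropies are computed after equal-frequency binning with
average-rank assignment, `bin = ceiling(rank_avg * n_bins / n)`. Tied
values always share a bin (a discrete feature with few levels keeps its own
levels), a two-valued feature always occupies two bins however unbalanced,
and the sqrt-rule bin count is a standard histogram default for trial
counts in the tens to hundreds. Entropies are in bits; the ratio is
base-invariant. Conventions: $s = 0$ for a constant feature and for an
empirically independent joint; $s = 1$ for a feature that reproduces the
labels.

**Which CSP filters to keep.** The package defaults to the classical
`paired` rule (largest + smallest eigenvalue per band). Under trace
normalization, a strong one-sided band source inflates its class's trace,
which pushes that class's *relative* power in non-source directions down —
the most discriminative filters can then sit at the *bottom* of the
whitened spectrum. On the synthetic ERD condition the literal top-of-the-
spectrum rule (`largest`, available via `csp_mode`) costs ~25 accuracy
points for exactly this reason. Eigenvalues attached to features (and hence
the spatial information $e$) always come from the whitened $C_1$ spectrum,
with the mean in $e_i$ taken per band so that $e$ is comparable across
bands of differing class-power balance.

**Penalty-weight form.** The weight is the all-in-exponent form
$e^{-\mu s_i e_i}$: it is the reading under which weights are monotone
decreasing in importance $s_i e_i$ and bounded in $(0,1]$. The alternative
reading $e^{-\mu s_i}\cdot e_i$ is available as `weight_form = "mixed"` for
comparison. Weights are floored at $10^{-8}$ so the rescaling step stays
well conditioned. The rescaling itself uses the full weight $w_j$, which is
what makes the reduced problem equivalent to the weighted objective.

**Solving and selecting $\lambda$.** Coordinate descent runs in
covariance-update form (Gram matrix shared along a path) with an active-set
strategy, converging when the largest coefficient change in a full sweep
drops below $10^{-8}$ — tight enough that solutions certify the KKT
conditions of the weighted objective to $10^{-6}$. $\lambda$ is chosen by
stratified 5-fold CV inside the training partition over a 50-point
logarithmic path spanning three decades down from $\lambda_{\max}$ (the
smallest all-zero $\lambda$), scoring each candidate by refitting the
downstream classifier on the selected features (path solves use a $10^{-6}$
tolerance; the final fit uses the default). The **one-standard-error rule**
picks the sparsest $\lambda$ within one SE of the CV minimum: plain
error-minimization frequently returns near-dense solutions on CV-error
plateaus, defeating the purpose of sparse selection, while 1-SE keeps the
selected sets small without losing accuracy. `rule = "min"` restores pure
minimization. Ties break toward the larger (sparser) $\lambda$.

**Degenerate inputs.** Constant feature columns get $s = 0$ and survive
standardization as zero columns; a zero-variance projected trial or a
singular composite covariance raise informative errors; an all-zero
$\hat\beta$ falls back to the `fallback_k` features with the largest
$s_i e_i$ and flags the fallback. Precision is reported as 0 (with a
warning) when no positives are predicted.

## The synthetic generator

`synth_epochs()` emulates the one physical signature CSP exploits: a
band-limited class difference in spatial covariance. Each source is
unit-variance band-pass-filtered Gaussian noise at designated channels,
scaled by $\sqrt r$ for class $+1$ and $1/\sqrt r$ for class $-1$ (class
band-variance ratio $r^2$), spread through a mixing matrix
$I + \mathcal N(0, 0.1^2)$ so whitening is non-trivial, with broadband
white noise everywhere. Defaults — 50 trials/class, 8 channels, 100 Hz,
4 s epochs, one 8–12 Hz source on channels 1–2 with $r = 4$, noise sd 0.5 —
describe a small, clearly separable recording: trial counts and channel
counts are at the low end of laboratory practice, and the noise level puts
the empirical class band-power ratio near the design value of 16. Sources
are variance-modulated rather than phase-locked because CSP is a variance
method.

What the generator does *not* emulate: 1/f background spectra, artifacts
(EMG, EOG), non-stationarity across a session, volume-conduction geometry
of a real head, or inter-subject variability. Passing the synthetic
end-to-end checks therefore demonstrates that the pipeline recovers
band-limited covariance structure without leakage — not that any particular
accuracy carries over to recorded EEG.

`synth_feature_table()` generates the selection-recovery condition directly
at the feature level: 100 trials × 38 columns with 4 informative columns at
a one-standard-deviation class separation, eigenvalue metadata 0.8
(informative) versus 0.55 (background) — values typical of CSP features on
discriminative versus indifferent bands.

## Verification problem sizes

The test suite certifies: solver KKT residuals and agreement with glmnet on
100 random instances ($n \le 50$, $p \le 20$) plus exact orthonormal-design
closed forms; the $\mu = 0$ and adaptive-LASSO reductions; exhaustive
agreement of symmetric uncertainty with a joint-histogram oracle over all
406 distinct two-bin empirical joints with $n \le 8$; CSP spectra against a
generalized-eigenproblem oracle on 100 random SPD pairs and the
closed-form two-channel toy (eigenvalues 0.8/0.2); feature recovery
(≥ 3 of 4 informative, ≤ 10 total columns) in ≥ 80% of 50 replicates;
and the end-to-end synthetic study at 10 generator seeds — mean CV accuracy
≥ 0.90 on the strong condition, chance on the null (the binomial band is
evaluated at one replicate's 100 trials because fold-level correlation
makes the pooled band anti-conservative), ≥ 60% of selection mass on bands
overlapping the true source band, and the overlapping bank at least as
accurate as single-band CSP. `scripts/acceptance.R` recomputes these
quantities from scratch at the same sizes.

## Known limitations

- Two-class decoding only; multi-class extensions (one-vs-rest,
  pair-wise) are out of scope.
- Subject-dependent analysis; no transfer or session-to-session adaptation.
- No artifact handling or re-referencing — epochs are assumed clean.
- $\mu$ is fixed (default 1) rather than tuned per fold by default; the
  config exposes it, and the inner CV machinery can be pointed at a grid at
  the cost of a multiplicative runtime factor.
- The on-disk container stores epochs, not continuous recordings; filtering
  happens per epoch, which is the harder case for edge effects (mitigated
  by the spectral zero-phase application above).
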