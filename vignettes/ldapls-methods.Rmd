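---
title: "PLS-corrected linear discriminants: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PLS-corrected linear discriminants: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldapls)
```

## The problem

Two-class discrimination of high-dimensional, collinear measurements —
typified by vibrational spectra, where adjacent wavenumber channels carry
nearly identical information and the sample count is often smaller than the
channel count. Classical LDA maximizes the between- to within-class scatter
ratio; its direction `w ∝ S_W⁺(m₂ − m₁)` is optimal when each class is
homoscedastic Gaussian, but the pooled scatter estimate is easily dominated
by within-class structure that has nothing to do with the boundary, tilting
the direction. This package implements a PLS-based correction of the LDA
direction (LDA-PLS), a continuous blend between the LDA and corrected
directions (ex-LDA-PLS), the from-scratch LDA and NIPALS-PLS primitives they
rest on, and a comparative evaluation harness.

## Model and algorithms

### LDA (two-class closed form)

Rather than solving the generalized eigenproblem, we use the rank-1
structure of `S_B` and compute `w ∝ S_W⁺(m₂ − m₁)` directly, with the
pseudo-inverse formed by SVD. Two numerical choices:

* **Singular-value cutoff** `rtol = 1e-10` relative to the largest singular
  value — standard pseudo-inverse practice, and the route that makes the
  `k > n` regime (singular `S_W`) work unchanged.
* **Scatter normalization.** `S_W` is a raw sum of outer products, `S_B` a
  plain outer product. Any positive rescaling of either only rescales `w`,
  which is unit-normalized, so the convention is observationally
  irrelevant (and tested as such).
* **Orientation.** `w` is oriented so the `+1` class projects higher; this
  pins down classifier thresholds and blending across runs.

### NIPALS-PLS

The alternating iteration `w ∝ Xᵀu`, `t = Xw`, `q ∝ Yᵀt`, `u = Yq`, with
convergence judged on the relative change of `t` (tolerance `1e-10`, cap
500 iterations; for a single-column response the loop converges in one
pass with `w ∝ Xᵀy` exactly). After convergence, `p = Xᵀt/(tᵀt)` and
`b = uᵀt/(tᵀt)`; deflation `X ← X − tpᵀ`, `Y ← Y − b·tqᵀ` uses the fitted
part of `Y` (the PLS1/PLS2 standard). Coefficients are assembled by the
closed form `B = W(PᵀW)⁻¹ diag(b) Qᵀ`. Component signs are fixed so each
weight vector's largest-magnitude entry is positive — NIPALS signs are
otherwise arbitrary, and fixing them makes stored models comparable.

All NIPALS computations operate on column-centered `X` and `Y`. Centering
is learned on training data only and re-applied to held-out data; this is
required both for the structural identities below (e.g. `w ∝ Xᵀy` only
holds centered) and to keep the evaluation protocol leakage-free. Optional
unit-variance scaling exists but is off by default: spectra-style data
carry meaningful relative intensities and we found no reason to assume
autoscaling.

### LDA-PLS

Per outer component on the current residual: compute the LDA direction,
project (`c = Xw`), regress `c` on `X` by PLS with `n_lv` latent variables,
keep the coefficient vector `B` as the corrected direction, deflate along
the normalized score `t = XB/‖XB‖` with loading `p = Xᵀt`, and repeat. Two
ambiguities were resolved as follows:

* **Deflation direction.** We deflate along the score of the *extracted*
  direction `B`, so later components model variance the already-kept
  direction does not explain. The alternative (deflating along the LDA
  score `Xw`) is exposed via `deflation = "lda_score"` for sensitivity
  analysis; both share the identical first component.
* **Recompute vs. reuse.** The LDA direction is recomputed on each deflated
  residual (the loop structure of the algorithm), not reused from stage 1.

The latent-variable count governs the correction. Three exact identities
anchor the implementation (each is a frozen test and recomputed by the
acceptance script):

1. `n_lv = 1`: `B ∝ XᵀX w_lda`. Since `S_W w_lda ∝ (m₂ − m₁)` and
   `XᵀX = S_W + const·(m₂−m₁)(m₂−m₁)ᵀ` on centered data, on full-rank
   two-dimensional data `B` is exactly the class-mean difference direction.
2. `n_lv = 2` on full-rank 2-D data: `B` coincides with `w_lda` (the
   regression becomes exact at the data's rank).
3. `n_lv = rank(X)` generally: `B ∝ w_lda`, because full-rank PLS equals
   least squares and the label `c = Xw` is itself linear in `X`.

### ex-LDA-PLS

Integer latent-variable counts make the correction jumpy; the blend

`w(λ) = normalize((1−λ) ŵ_lda + λ B̂)`

moves continuously between the LDA (λ = 0) and LDA-PLS (λ = 1) directions.
Both inputs are unit-normalized before blending: their raw scales differ by
an arbitrary proportionality constant, which would otherwise distort what a
given λ means. The convex combination is the simplest form with the right
endpoints. `B` is pre-oriented like `w_lda` (positive class projects
higher), so the blend path does not pass near zero on non-degenerate data;
an exactly antiparallel pair at interior λ raises an explicit error.

λ is selected by a single traversal of the grid `{0, 0.001, …, 1}` (1001
points): the training set is split 50/50 (stratified, seeded) into a
selection half — on which the LDA and LDA-PLS directions and the per-λ
classifier are fitted — and a verification half on which each λ is scored.
Ties go to the smallest λ (minimal departure from plain LDA). The split
ratio is a design choice; 50/50 gives the verification half enough mass to
rank 1001 candidates. For multi-component ex-LDA-PLS models every
component's pair is blended at the same selected λ.

### Classifier and metrics

The "Bayesian linear classifier" on projected scores is realized as the
linear Gaussian discriminant: class-conditional Gaussians with pooled
covariance and empirical priors — the canonical linear Bayes rule. A
diagonal-covariance (naive) switch is provided. A singular pooled
covariance receives a ridge of `1e-8 ×` its mean diagonal, with a warning.
G-Mean is `√(TPR·TNR)` and F-Value the harmonic precision/recall mean for
the class coded `+1`; with no predicted positives the F-Value is defined as
0 and flagged, and a class absent from the truth flags the affected metrics
as undefined (excluded from means with a logged count).

## Evaluation protocol

Each run draws a stratified 7:3 train/test split; hyperparameters are
selected strictly inside the training part (latent variables by stratified
10-fold cross-validation over 1–10 with a smallest-on-ties rule; λ by the
half-split search above); the classifier is fitted on projected training
scores; accuracy (both parts), G-Mean and F-Value (test part) are recorded
and averaged over runs (default 20). Stratification is used even though
the protocol could split fully at random: it prevents empty-class folds on
imbalanced data, which the G-Mean/F-Value discussion presupposes. Both
train and test accuracy are averaged over runs. The PCA baseline keeps the
smallest number of leading components reaching a 0.95 cumulative
contribution rate (a fixed component count is used in sweeps); PLS-LDA
reduces to PLS scores first and runs LDA in score space, yielding
one-dimensional projections. The whole report is a pure function of
(dataset, configuration, seed).

## Synthetic data

Two seeded generators stand in for unavailable measured data.

**Toy set** (`make_toy2d`, default 1224 samples × 2 features, labels
−1/+1): each class is a horizontal band (uniform in x over ±3, uniform
vertical noise of half-width 0.3 around ±1); 10% of each class is displaced
by ±(12, 1.6) — horizontally plus a diagonal lift toward the other class,
in opposite senses per class, with the positive class's lift scaled by 0.1.
The displaced points dominate the pooled within-class scatter and tilt the
LDA direction; the asymmetric lift additionally drags the pooled-Gaussian
threshold so plain LDA misclassifies a handful of points, while a slightly
rotated direction — reachable on the λ grid — still separates the classes
perfectly. Every generated set carries an internal separability
certificate (directional margin over an angle fan must exceed a configured
ε, else the generator errors). The default parameters were fixed once so
that the frozen generator exhibits this phenomenon robustly across seeds,
and are kept in version control; exact coordinates of any particular
measured figure are not reproduced, only the qualitative contract.

**Collinear spectra** (`make_collinear_spectra`): the class signal lives in
a few smooth Gaussian bumps along the feature axis (alternating-sign
amplitudes, class mean scores at ±`class_shift`/2), with per-sample latent
variation and additive noise smoothed by the same kernel, so neighboring
features are strongly correlated (lag-1 autocorrelation > 0.9 at the
defaults). With `k > n` the within-class scatter is singular, exercising
the SVD route. Defaults (`class_shift = 4`, `noise_sd = 0.3`) put the
high signal-to-noise regime where every pipeline method should exceed 0.95
test accuracy — a sanity anchor, not a claim about measured spectra.

What these generators do *not* emulate: instrument physics (baseline
drift, cosmic spikes, detector noise correlations across samples),
class-conditional covariance differences, label noise, and batch effects.
Passing tests on them demonstrates algorithmic correctness and the
qualitative geometry of the methods, not field performance on real
spectra.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run the structural identities
on ~100 random datasets of n = 50–60 and k = 2–8, the toy phenomenon on the
full 1224-sample set with the 1001-point λ grid, and the small-sample
protocol on n = 50, k = 500 with 5 repeated splits and a fixed 5-LV inner
regression — sizes chosen to exercise every code path (including singular
`S_W`) while keeping a full run in seconds on one core. Cross-validated
latent-variable selection is exercised on smaller instances; the protocol
accepts either fixed or cross-validated counts.

## Known limitations

* Strictly two classes; multi-class extensions and kernel variants are out
  of scope.
* No sparse-matrix or spectral file-format support; delimited text only.
* The λ search performs a single half-split traversal; on small datasets
  the selected λ can be unstable (by design it never does worse on the
  verification half than either endpoint, but that guarantee does not
  transfer to test data).
* Shrinkage-covariance LDA is not implemented; where a comparison is
  needed, `MASS::lda` serves as an external cross-check of the plain LDA
  direction in the test suite only.
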