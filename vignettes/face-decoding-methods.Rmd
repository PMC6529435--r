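---
title: "Linear latent-space decoding of faces from fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear latent-space decoding of faces from fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`facedec` implements a linear encoding/decoding framework for face images.
Every face is described by a latent vector `z` of length `d` (here the
coordinates of the image on the top `d` principal components of pixel
space; any other embedding exposing `encode()`/`decode()` can plug into
the same seam).  The encoding model assumes that each voxel's activation
is a weighted sum of the latent features plus a constant face-evoked
"bias":

    Y = X W

where the rows of `X` are `[1, z]` (bias term first, `d + 1` columns), `Y`
holds the corresponding voxel activations, and `W` is the
`(d + 1) x n_voxels` weight matrix.  Training is ordinary least squares in
closed form,

    W = (X'X)^-1 X'Y,

and decoding a novel activation pattern `y` inverts the same linear
system,

    x = y W' (W W')^-1,

whose first coefficient is a bias estimate (returned, flagged, and unused
downstream) and whose remaining `d` coefficients are the decoded latent
vector.  The framework's central identity — `decode(W, x W) = x` for any
full-row-rank `W` — is exercised at machine precision in the test suite.

Rather than fitting `W` to pre-extracted activation patterns, the package
follows the standard event-related GLM route: stimulus schedules become
design matrices whose regressors are HRF-convolved boxcars.  The bias
regressor is a unit-height stick at every face onset (the face-vs-fixation
contrast); each latent dimension contributes a parametric regressor whose
stick heights are that dimension's value for the presented stimulus.
One-back repeat trials and imagery blocks get their own nuisance columns
and never enter the encoding fit; fixation trials are the implicit
baseline.

## Assumptions

* Linearity of the BOLD response in the latent features, and temporal
  linearity of the HRF convolution.
* Latent coordinates approximately centred and mutually uncorrelated
  across stimuli — this is what makes the design well-conditioned; the
  design's rank is checked and recorded on every build.
* Activation patterns for novel faces are estimable per stimulus, either
  as per-condition GLM betas (default) or as block averages (used for 12 s
  imagery trials).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `d` | 32 (pipeline); up to 1024 supported | latent dimension; `W` has `d + 1` rows |
| HRF | peak 6 s, undershoot 16 s, dispersions 1 s, ratio 6, length 32 s | canonical double-gamma, unit peak |
| `dt` | `tr/16` | fine grid for boxcar convolution |
| `tr` | 2 s | repetition time |
| trial timing | 1 s stimulus, 3 s inter-trial interval | rapid event-related design |
| `reps_per_test` | 15 | presentations per test face, averaged through the GLM |
| selection policy | `top_fraction(0.3)` on rank-sum of (t, delta-R2) | two-criterion voxel selection |
| pseudo-inverse cutoff | 1e-10 (relative) | shared inversion policy, warns when active |

The HRF parameters are the de-facto canonical set; the kernel is checked
to be zero at `t = 0`, to peak between 4 and 6 s, and to integrate to a
positive value.  Parametric modulators are not mean-centred per run by
default (latent coordinates are already approximately centred); a
`mean_center` flag and an `orthogonalize`-against-bias flag are provided
for users who want the alternative conventions, both off by default
because neither is required for a full-rank design.

## What the simulator emulates — and what it does not

The forward model (`make_brain()` + `simulate_run()`) supplies the test
bed that scanner data would otherwise provide:

* a ground-truth weight matrix `W_true` with sparse signed latent tuning
  (10% of dimensions per voxel, floor of 3 so `W W'` stays
  well-conditioned at small `d`) and a dense positive bias row — every
  in-scale voxel responds to faces, only some carry feature information;
* three equal-sized voxel populations (occipital, temporal,
  frontoparietal) laid out in coordinate blocks, with per-region signal
  scales defaulting to `(1, 0.5, 0.05)` so that decodability falls off
  from posterior to anterior, the qualitative pattern expected of
  perception;
* AR(1) Gaussian noise (default lag-1 coefficient 0.3) plus a sinusoidal
  low-frequency drift (amplitude 0.5, period 128 s) — the minimal model
  with fMRI-like temporal structure;
* schedules with 88 face presentations per run, randomly interleaved test
  faces, 8 one-back repeats, 30 null fixation trials, 6 s run-boundary
  blanks, and optional 12 s imagery blocks alternating between run start
  (odd runs) and run end (even runs);
* an imagery signal injected only into temporal-region voxels at
  configurable gain, emulating top-down reinstatement that is decodable
  from higher-order regions but not early visual cortex.

The default noise SD is 4 in the units of unit-variance latents; the
pipeline default is 20 because PCA latents of rendered faces have
variances well above 1.  Both were fixed once so that simulated decoding
sits in the regime the framework targets: high but imperfect accuracy at
the full selection, a clear occipital > temporal > frontoparietal
gradient, and gender classification above chance but below its
true-latent ceiling.

The simulator does **not** emulate physiological noise, motion,
susceptibility artifacts, spatial autocorrelation, anatomical geometry, or
any nonlinearity of the BOLD response.  Passing tests therefore show that
the estimators are correct and well-behaved under the stated generative
model; they say nothing about preprocessing choices or biological effect
sizes in real data.

## The synthetic faces

Stimuli are schematic grayscale faces drawn from 12 interpretable
generative parameters (face oval, eye geometry, mouth curvature and width,
brow thickness, jaw width, hair extent, nose length, skin tone, vertical
offset), each uniform on `[-1, 1]`.  Binary attributes are thresholds on
designated axes — `male` is jaw width > 0 — so the ground-truth attribute
direction is known and axis-recovery can be scored as a cosine.  The jaw
effect is rendered strongly (lower-face width modulation of up to 45%) so
that the attribute is visually salient the way gender is in photographs;
with a weaker rendering the attribute axis is still recovered but the
sign-projection classifier's ceiling drops toward chance and the
chance-to-ceiling band becomes too narrow to resolve with 10–20 test
faces.  Anti-aliased rendering makes every parameter move at least one
pixel at 64 x 64, and PCA on rendered samples yields at least 12
components with nonzero variance, so the latent space can represent all
generative axes.

## Statistics

Identification is scored by Pearson correlation between decoded and
candidate latent vectors.  Pairwise accuracy is the fraction of ordered
(target, distractor) pairs won — equivalently `(n - rank)/(n - 1)`
averaged over items — and full recognition requires rank 1 among all
candidates (chance `1/n`).  Because the comparisons for one item share an
estimate, significance uses rank nulls rather than a binomial on pairs:

* Monte-Carlo: draws of independent uniform target ranks converted to
  surrogate accuracies; p-values use the add-one rule
  `(1 + #{surrogate >= observed})/(n_draws + 1)` and count ties against
  the observation, so sampling never reports p = 0 and the test stays
  conservative (verified: the Monte-Carlo p dominates the pairwise
  binomial p across an accuracy grid).
* Exhaustive: group designs small enough (`n_candidates^n_subjects <= 1e7`,
  e.g. 4 subjects x 20 candidates = 160,000 outcomes) are enumerated
  exactly.

Friedman tests use the classic midrank rank-sum chi-square (so an
all-constant table gives 0 rather than NaN); binomial tails come from
`pbinom`.  SSIM follows the standard windowed
luminance–contrast–structure product with `k1 = 0.01`, `k2 = 0.03`, 8 x 8
sliding windows and unbiased window variances.  Variance partitioning is
operationalised as commonality analysis: ground-truth latents (items and
dimensions pooled) are regressed on all seven subsets of the three
region-wise predictions and the seven R² values are decomposed into
unique/shared components that sum exactly to the full-model R².  The
exact regression layout for this analysis was an open design choice; the
pooled-observations commonality form was chosen because it yields an
exact additive decomposition and treats the three regions symmetrically.

## Numerical choices and degenerate inputs

* All inversions (`X'X`, `W W'`, nested-R² fits) share one pseudo-inverse
  policy: relative singular-value cutoff 1e-10 with a logged warning, so
  rank-deficient problems degrade to minimum-norm solutions instead of
  failing.
* PCA is computed by SVD of the centred data matrix (stable for
  `n_pixels >> n_images`); component signs are fixed by making each
  component's largest-magnitude loading positive, so models are
  bit-reproducible across platforms.
* Region splits break coordinate ties by voxel index; exact-zero attribute
  projections classify negative with a logged tie; zero-variance weight
  columns get sensitivity 0 with a flag; empty voxel selections raise an
  error that names the thresholds.
* Events are validated (non-negative onsets, positive durations, known
  trial types) and stably sorted; all-identical voxel coordinates are
  rejected as degenerate geometry.

## Open design decisions

* Whether test-face activation patterns are GLM betas or averaged evoked
  responses is not determined by the framework's mathematics; both are
  implemented (`pattern_method = "glm"` default, `"average"` for
  imagery-style block averaging) and the default was chosen because the
  per-condition GLM is the standard event-related workflow and is exact
  in the noiseless limit when the training regressors are supplied as
  nuisance.
* The anatomical sense of the second split axis (which half of the
  anterior voxels counts as "temporal") is a dataset convention; it is
  configurable (`split_axis`) rather than asserted.
* The selection criterion combines visual responsiveness and
  latent-model improvement.  Absolute thresholds are dataset-dependent,
  so the default policy ranks voxels on the sum of their within-criterion
  ranks and keeps a target fraction; a `conjunction(t_min, dr2_min)`
  policy is available when thresholds are known.

## Problem sizes

The shipped test suite and demonstration pipeline run at desk scale,
chosen as the package's reference conditions: latent dimension 32 with
3000 voxels and 500 training faces for the closed-form and pipeline
checks (about 25 minutes of simulated scanning); latent dimension 6–8
with 90–150 voxels and 20 seeds for the stochastic recovery suites
(repetition, noise and region-ordering trends); 2000 rendered faces for
attribute-axis recovery; and a single d = 1024 fit verifying the
full-dimension weight-matrix layout.  Schedules at acquisition scale
(8000 training faces, 20 test faces at 45+ repetitions) are generated and
validated for their composition, without simulating their BOLD data.

## Limitations

* The decoder is deliberately unregularised, matching the closed-form
  model; ridge or Bayesian variants are out of scope.
* PCA is the only built-in embedding; deep generative embeddings enter
  through the `encode`/`decode` seam but are not trained here.
* The simulator's region structure is a caricature (coordinate blocks,
  shared noise parameters); it supports qualitative ordering claims, not
  anatomical inference.
* Preprocessing (slice timing, realignment, coregistration) is assumed
  done; `read_bold()` ingests cleaned 4-D volumes or matrices.
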