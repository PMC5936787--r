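---
title: "Surround-inhibition contour detection: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surround-inhibition contour detection: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smci)
```

## The model

Neurons in primary visual cortex respond to oriented luminance structure
inside their classical receptive field (CRF), and that response is
modulated — mostly suppressed — by the annular non-classical surround.
The suppression is strongest when the surround contains the same kind of
structure as the center: a pixel inside homogeneous texture is inhibited
hard, while a pixel on an isolated contour is not. `smci` implements this
center–surround account as a contour detector and adds two accelerations
and a sparseness-based noise-suppression step.

The stages, with the package functions that implement them:

1. **CRF response** (`orientation_responses()`, `crf_response()`). The
   image is correlated with a bank of `n_theta` first-derivative-of-
   Gaussian kernels at scale `sigma`; responses are rectified by absolute
   value and combined winner-take-all. Orientations span [0, π): since the
   response is an absolute value, a bank over [0, 2π) would duplicate it.
   `theta` denotes the direction of the derivative axis (the axis crossing
   the contour), measured from the column axis; ties in the
   winner-take-all go to the lowest orientation index so results are
   deterministic and order-independent.

2. **Local cues** (`raised_cosine_window()`, `luminance_map()`,
   `contrast_map()`). Luminance is the raised-cosine-weighted window mean;
   contrast is the weighted variance around that mean divided by its
   square. The same window weights both cues. The radial Hann profile
   `0.5 (1 + cos(π d / R))`, `R = size/2`, is the standard 2-D reading of
   a "raised cosine" window.

3. **Inhibitory weights** (`scalar_cue_weight()`, `orientation_weight()`,
   `combine_weights()`). Each cue yields a per-pixel weight in [0, 1]:
   the `W_d`-weighted surround sum of Gaussian similarities between the
   center's cue value and each surround value (for the orientation cue, a
   single Gaussian similarity between the center and surround orientation
   *vectors*). The distance kernel `W_d` (`distance_kernel()`) is a
   half-wave-rectified difference of Gaussians with outer scale
   `4 * sigma`, L1-normalized; normalization to 1 is what bounds the
   scalar-cue weights by 1, which the min/max fusion implicitly assumes.
   Fusion is scale-guided: where the min-max-normalized response at
   `sigma` exceeds the one at `2 * sigma` the pixel is treated as
   texture-like and the maximum of the three weights is used; otherwise
   the minimum. Normalization is global per response map; a constant map
   normalizes to zero (min branch), a deliberate convention for degenerate
   inputs.

4. **Suppression** (`suppress()`).
   `res = max(0, E − alpha · W_com · (E * W_d))` — the surround activity
   (`E` correlated with `W_d`), gated by the combined weight and scaled by
   `alpha`, is subtracted and the result half-wave rectified.

5. **Sparseness modulation** (`sparseness_map()`, `apply_sparseness()`).
   Gradient magnitudes in each `ws × ws` window are histogrammed into
   `n_bins` equal-width bins over [0, global max] and scored with Hoyer's
   sparseness `(√n − ‖h‖₁/‖h‖₂)/(√n − 1)`; the response is multiplied by
   the score. Texture windows have broad histograms (score near 0),
   contour windows peaked ones (score near 1). Multiplication happens on
   the real-valued response, before thinning.

6. **Post-processing** (`nonmax_suppress()`, `hysteresis()`,
   `evaluate_edges()`). Non-maximum suppression walks the derivative axis
   of the winning orientation; hysteresis keeps the fraction `p` of
   nonzero candidates (with `p = 1`, the default, every candidate
   survives, so the low/high ratio is inert); evaluation greedily matches
   predicted to ground-truth pixels one-to-one within a pixel tolerance
   and reports precision, recall and `F = 2PR/(P+R)`.

## Acceleration

The weight computation dominates the detector's cost, and most of it is
wasted: salient contours occupy a small fraction of an image, and nearby
units respond similarly.

* **Prior filtering** (`prior_mask()`): weights are computed only where
  the CRF response reaches `prior_fraction` (default 0.30) of the global
  maximum. Sub-threshold pixels get weight **1** — maximal inhibition —
  so background is actively discarded rather than passed through. The
  mask is applied to all three cue weights: suppressing a single cue
  could not deliver a meaningful saving, since the three are computed
  over the same surround.

* **Uniform sampling** (`sampled_positions()`, `reconstruct_field()`):
  with stride 2, weights are computed on every other column (or row, or
  both) and missing points are reconstructed as
  `2/3 · (lower-index neighbor) + 1/3 · (higher-index neighbor)`; under
  two-direction sampling the remaining centers combine the four
  reconstructed neighbors with coefficients 1/3, 1/3, 1/6, 1/6, which
  expands to 4/9, 2/9, 2/9, 1/9 over the surrounding computed points. The
  asymmetric coefficients (rather than symmetric midpoint averaging) are
  treated as normative — the worked indicator example depends on them —
  with the larger share oriented toward the lower-index neighbor. The
  final row and column are always sampled so no stencil extrapolates.
  Only stride 2 is supported; the stencils are specific to it.

* **Combined** (the default accelerated mode): prior filtering at
  `combined_fraction` (default 0.10) plus one-direction sampling — the
  one-direction variant preserves accuracy better than two-direction
  sampling, so the combination uses it.

Because the weight routine accumulates offset-major over the nonzero
entries of `W_d` regardless of which pixels are requested, accelerated
runs are *bitwise identical* to the full computation at every pixel they
actually evaluate, and `prior_fraction = 0` with sampling off reproduces
the full detector exactly. An instrumented counter
(`$weight_evals`) reports how many pixel locations were explicitly
evaluated — a hardware-independent stand-in for wall-clock comparisons.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 5 | surround inhibition strength |
| `sigma_dtheta` | 0.2 | orientation-dissimilarity sensitivity |
| `sigma_dl`, `sigma_dc` | 0.05 | luminance / contrast sensitivities |
| `p` | 1 | fraction of candidates kept by hysteresis |
| `ws` | 5 px | sparseness window side |
| `sigma` | 2 px | CRF filter scale (coarse scale fixed at 2σ) |
| `n_theta` | 8 | orientations in the bank |
| `window_size` | 11 px | cue window side (≈ 5σ at the default σ) |
| `n_bins` | 16 | sparseness histogram bins |
| `prior_fraction` / `combined_fraction` | 0.30 / 0.10 | prior-filter thresholds |

The first group is the detector's published setting; the second are
package choices: 8 orientations is conventional for surround-inhibition
detectors; an 11-pixel window is large enough to estimate a local
variance yet still local at σ = 2; 16 bins resolves the gradient
histogram without emptying it in a 5 × 5 window.

## Numerical choices and conventions

* Coordinates are (row, column), 1-based in R; "x" in the formulas is the
  column index. One border policy — symmetric, edge-repeating mirror
  reflection — is used for every correlation in the package, so variant
  comparisons are never confounded by border handling.
* The derivative kernel uses an isotropic Gaussian (aspect ratio 1,
  configurable); support is the smallest odd square ≥ `8 sigma`, at which
  truncation error is negligible.
* The contrast denominator carries a guard `eps = 1e-6` against division
  by zero luminance.
* The sparseness statistic is implemented with the square roots of the
  Hoyer measure, which is what bounds it to [0, 1]; an unbounded
  no-square-root variant is available (`printed_sparseness = TRUE`) for
  auditability. An all-zero gradient histogram scores 0 (no structure).
* The surround orientation average is the `W_d`-weighted mean of the
  orientation vector field, mirroring the scalar cues; a wide-Gaussian
  alternative sits behind `ncrf_weighting = "gaussian"`. The inhibition
  term `E * W_d` uses `E` at scale σ only.
* Non-maximum suppression uses a keep-first tie rule (a pixel survives
  iff it strictly exceeds the preceding neighbor and at least equals the
  following one along the derivative axis), so equal plateaus keep
  exactly one pixel and the thinned map never contains side-by-side
  ridge pixels.
* Greedy distance-ordered matching (not optimal bipartite assignment) is
  used in evaluation; at tolerance ≤ 2 px the difference is negligible
  and the evaluator stays dependency-free. Both per-image scoring and a
  pooled aggregate are possible by summing the returned match counts.

## The synthetic scenes

`generate_scene()` builds seeded 64 × 64 test scenes: a salient structure
(step edge, disc outline, or bright bar) at contrast 0.5 over a
background of short randomly oriented line segments (density 0.15 ≈ 50
segments), with one-pixel-wide ground truth and a disjoint texture mask
(a 2-pixel guard band separates the two). These sizes keep a full
detection under a few seconds while leaving the surround kernel
(65 × 65 at σ = 2) smaller than the image.

The scenes emulate the structure the mechanism targets — a contour
occupying a small fraction of a cluttered image — but not the statistics
of natural images: no shading, no multi-scale texture, no annotator
disagreement. Passing tests on them demonstrates that the mechanisms work
as specified (texture is suppressed relative to contours, acceleration
preserves the weight field, sparseness shifts response toward contours);
they say nothing quantitative about natural-image benchmarks, for which
an external corpus adapter would be needed.

## Known limitations

* Grayscale only; color-opponent cues are out of scope.
* Purely feed-forward; no top-down or feedback modulation.
* The sparseness histogram is computed from the raw image gradient (the
  windowed statistic is generic); computing it from the CRF response
  instead is a one-line change but is not the default.
* Sampling stride is fixed at 2; coarser strides would need different
  stencil coefficients.
* The evaluator scores one ground-truth map; averaging multiple human
  annotations is left to an external adapter.
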