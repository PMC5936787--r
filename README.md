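# smci — fast multi-cue surround-inhibition contour detection

`smci` detects salient contours in grayscale images with a computational
model of surround inhibition in primary visual cortex (V1). It is aimed at
researchers in biologically inspired vision and at anyone who needs an
unsupervised, training-free contour detector whose behavior is
interpretable in terms of center–surround mechanisms.

## The model

An orientation-selective V1 unit at scale σ is modeled as the first
derivative of a 2-D Gaussian; the classical-receptive-field (CRF) response
is the winner-take-all over a bank of N_θ orientations:

    e_i(x, y; θ_i, σ) = | I * ∂g(x̃, ỹ; θ_i, σ) / ∂x̃ | ,
    E(x, y; σ)        = max_i e_i(x, y; θ_i, σ).

Three local cues are extracted — the orientation vector Θ (the per-pixel
bank responses), local luminance L, and local luminance contrast C, the
latter two in a raised-cosine window. For each cue, an inhibitory weight
in [0, 1] measures how similar the pixel is to its annular surround
(weighted by a normalized difference-of-Gaussians distance kernel W_d);
e.g. for luminance:

    W_L(x, y) = Σ_i exp( −|L(x,y) − L(x_i,y_i)|² / 2σ_Δl² ) · W_d(x_i−x, y_i−y).

A scale-guided rule fuses the three weights (max where the normalized
fine-scale response beats the coarse-scale one, min otherwise), and the
contour response is the half-wave-rectified inhibited CRF response:

    Res = H( E − α · W_com · (E * W_d) ),   H(z) = max(z, 0).

Texture is homogeneous with its surround, so it is inhibited strongly;
isolated contours are not. Two accelerations make the expensive per-pixel
weight computation cheap: **prior filtering** skips pixels whose CRF
response is below a fraction (30%, or 10% when combined with sampling) of
the image maximum, assigning them maximal inhibition; **uniform sampling**
computes weights only on every other grid line and reconstructs the rest
with fixed stencils (2/3, 1/3 along a line; 1/3, 1/3, 1/6, 1/6 at
centers). Finally a windowed gradient-histogram **Hoyer sparseness** score
in [0, 1] multiplies the response, attenuating residual texture noise
(broad histograms) while sparing contours (peaked histograms).

## Worked example

```r
library(smci)
scene <- generate_scene("disc-on-texture", size = 64, seed = 42)
det   <- smci_detect(scene$image, mode = "combined", sparse = TRUE)
det
#> smci detection (combined + sparseness): 64 x 64 image
#>   weight evaluations: 940 / 4096 pixels (22.9%)
#>   edge pixels after hysteresis: 226
evaluate_edges(det$binary, scene$contour_mask)
#> P = 0.544, R = 0.984, F = 0.701 (123/226 pred, 123/125 gt matched, tol 2 px)
```

The accelerated detector computed inhibitory weights at only 22.9% of the
pixel locations yet recovered 123 of the 125 ground-truth disc-boundary
pixels (recall 0.984); the remaining predictions are responses to the
texture clutter, which lowers precision on this deliberately hostile
scene. Running `mode = "mci"` (the full model, 4096/4096 weight
evaluations) on the same scene yields the identical F-score of 0.701 —
acceleration does not cost accuracy here.

The command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "smci.R", package = "smci"))')
Rscript $CLI synth  --kind disc-on-texture --size 64 --seed 42 --out scene/
Rscript $CLI detect --input scene/image.pgm --output out/ --mode combined
Rscript $CLI eval   --pred out/binary.png --gt scene/contour.png --out out/eval.csv
```

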