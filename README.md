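# leeac — local edge-enhanced active contours for skin lesion border detection

Automated delineation of pigmented skin lesions in dermoscopy images.
Edge-based active contours find lesion borders by evolving a level-set
contour until an *edge-stop function* (ESF) — a field that is small at
object edges — halts it.  On the hard cases of dermoscopy (fuzzy borders,
low lesion/skin contrast, hair and other artifacts that cast strong false
edges) a plain gradient ESF never gets small enough at the true border and
the contour **leaks** through it.  `leeac` implements a robust ESF that
fuses two complementary sources of border evidence and solves the
segmentation with a reaction–diffusion regularized level set.

## Method

For an image *I* the pipeline computes, in order:

1. **Coarse localization** — intermeans (Ridler–Calvard) thresholding:
   the fixed point of `T ← (mean(I ≤ T) + mean(I > T)) / 2`, giving a
   rough lesion mask used only to place sampling patches and the initial
   contour.
2. **Patches** — a foreground (lesion) and a background (healthy skin)
   rectangle, 70×90 by default, placed fully inside their regions.
3. **Denoising** — Perona–Malik anisotropic diffusion,
   `∂I/∂t = div(c(|∇I|) ∇I)` with `c = 1/(1 + √(1 + |∇I|²/γ²))`
   (a classic rational coefficient is also available).
4. **SPH edge features** — every pixel is a particle with mass equal to
   its intensity; a compact-support poly6 kernel
   `W(r) = C (h² − r²)³` (support `|r| < h`) interpolates the intensity
   gradient as `∇A(r_i) = Σ_j m_j ∇W(r_i − r_j)`, and the edge indicator
   is `g = 1 / (1 + m̂^p)` with `m̂` the rescaled gradient magnitude.
5. **Probability map** — per-channel Gaussian color models fitted on the
   two patches give a foreground likelihood `P_F`; geodesic distances
   `D_F, D_B` over the 8-connected pixel graph (step cost = probability
   change) combine into `s = D_B / (D_F + D_B)`; the probability matrix
   is minimized at the border band, `prob(s) = 2 (s − 0.7)²`.
6. **Fusion** — the robust ESF is `g_new = g · prob`, which vanishes both
   at strong intensity edges and on the probabilistic boundary, so fuzzy
   borders still stop the contour.
7. **Level set** — reaction–diffusion evolution of a level-set field φ:
   a distance-regularized reaction step (double-well regularization,
   edge-weighted length term, area term `β v g_new δ_ε(φ)`) alternating
   with explicit diffusion `φ ← φ + τ₂ Δφ`, stopped when the enclosed
   area is stable within 10 px over consecutive iterations.

Quality is scored with the Dice coefficient `2|O∩G| / (|O|+|G|)`, the
Jaccard index `|O∩G| / |O∪G|`, and the border error
`(FN+FP) / (TN+TP)`.

A seeded synthetic dermoscopy generator (elliptical lesion with radial
irregularity, boundary blur, contrast control, Gaussian noise, Bézier
hair strokes) provides ground-truthed images for every test.

## Worked example

```r
library(leeac)

fx  <- generateLesion(lesionSpec(seed = 7L))   # image + ground truth
res <- runPipeline(fx$image)                   # full pipeline, defaults
res
#> SegmentationResult: 224x224 mask, lesion area 13070 px, 120 iterations,
#>   converged (area-change rule)

diceCoefficient(maskOf(res), fx$truth)
#> [1] 0.9881551
```

The same from the shell:

```sh
Rscript inst/scripts/leeac.R synth --out demo --seed 5
Rscript inst/scripts/leeac.R segment demo/img_01_sharp.png --out mask.png
#> {"threshold":123.367893999447,"patches":"auto","esf":"fused",
#>  "iterations":121,"finalArea":13138,"converged":true}
Rscript inst/scripts/leeac.R eval mask.png demo/truth_01_sharp.png
#> dice 0.9861  jaccard 0.9726  border_error 0.0072
```

`threshold` is the intermeans intensity cut, `finalArea` the lesion pixel
count, and `converged` reports that the area-change rule (not the
iteration cap) ended the evolution.  Dice/Jaccard near 1 and border error
near 0 indicate close agreement with the ground-truth border.

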