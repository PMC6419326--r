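---
title: "Border detection with edge-enhanced active contours: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Border detection with edge-enhanced active contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(leeac)
```

## The problem

Dermoscopy images show a pigmented lesion on surrounding skin.  Feature
extraction downstream (border irregularity, abrupt cutoff, pigment
structures) needs an accurate lesion border, but manual delineation is
subjective and slow.  Edge-based active contours automate it: a closed
contour, represented implicitly as the zero level set of a field
$\varphi$, shrinks from an initial rectangle until an edge-stop function
(ESF) $g \ge 0$ — small at edges — removes its driving force.

The failure mode this package targets is *leaking*: when the border is
fuzzy or the lesion/skin contrast low, and especially when artifacts
such as hairs cast the strongest gradients in the image, a plain
gradient ESF never approaches zero on the true border and the contour
passes through it.  The remedy implemented here fuses local SPH edge
features with a geodesic-distance foreground-probability map into a
robust ESF.

## Pipeline and models

### Coarse localization

Intermeans thresholding iterates $T \leftarrow (\mu_{\le T} + \mu_{>T})/2$
from the global mean until the move is below 0.5 intensity units.  The
darker class is taken as the lesion (pigmented lesions are darker than
skin; `invert` covers the converse).  The resulting mask is used only
for patch placement and contour initialization, never as part of the
segmentation itself.  Because thin dark hairs survive any intensity
threshold, the pipeline applies a 5-px-disc morphological opening to
this *localization* mask; without it a single hair touching the lesion
inflates the initial rectangle to nearly the whole frame.

### Sampling patches

Color models need pixel samples of pure lesion and pure skin.  The
70×90 default patch (a typical dermoscopy sampling box) is placed as
the fully-inside window of its region closest to a natural anchor — the
largest-component centroid for the lesion, the background pixel
farthest from any lesion pixel (distance transform) for the skin —
computed exactly with summed-area tables.  Fully-inside placement is
not cosmetic: a patch corner that pokes into the other region
contaminates the Gaussian models and, far worse, plants geodesic seed
pixels on the wrong side of the border, which short-circuits the
distance map (we observed the background foreground-distance collapse
from ~1 to ~0.006 with a corner of the lesion patch outside the
lesion).  When the coarse lesion is too small to host the configured
patch, the pipeline shrinks the window by 20% steps (lower bound 12 px)
until placement succeeds.

### Denoising

Perona–Malik diffusion with conduction coefficient
$c(\nabla I) = 1/(1+\sqrt{1+|\nabla I|^2/\gamma^2})$ (default), or the
classic rational $1/(1+|\nabla I|^2/\gamma^2)$.  Defaults
$\gamma = 15$, 20 iterations, $dt = 0.2$ (the 2-D explicit scheme is
stable for $dt \le 1/4$).  The default coefficient decays only like
$\gamma/|\nabla I|$, so it smooths more aggressively across strong
edges than the classic form; the classic variant is the one that keeps
a 140-unit step crest within ~1% while flattening flat-region noise,
and the tests pin exactly that behavior.  Both are exposed because the
default form is the package's reference behavior and the classic form
its established alternative.

### SPH edge features

Each pixel is an SPH particle with mass equal to its denoised grayscale
intensity.  The poly6 kernel
$W(r) = C\,(h^2-r^2)^3$ for $|r| < h$ (zero outside) satisfies the
feasibility conditions — non-negative, even, compactly supported, unit
integral — and has the analytic gradient
$\nabla W = -2nC\,\mathbf r\,(h^2-|\mathbf r|^2)^{n-1}$, which for the
cubic form and the 3-D constant $C = 315/(64\pi h^9)$ equals
$-(945/(32\pi h^9))\,\mathbf r\,(h^2-|\mathbf r|^2)^2$.  A squared
radial polynomial is exposed as `exponentAsPrinted`.  Two
normalizations are available: the closed-form 3-D constant, and a
discrete renormalization (default) that divides by the kernel sum over
the support grid so a constant image reproduces itself.

**Grid pitch.**  With unit pixel spacing and the smoothing length
$h = 1$, the support $|r| < h$ contains no neighbor pixel and the
interpolated gradient degenerates to zero everywhere.  The package
therefore measures inter-pixel distance with a `spacing` parameter,
default 0.5, so $h = 1$ yields a 3×3 stencil (axis neighbors at
$r = 0.5$, diagonal at $r \approx 0.71$).  Edge extraction uses
replicate padding so constant images give an exactly zero field and the
image frame casts no spurious edge; density interpolation keeps
truncated neighborhoods.

The edge indicator is $g = 1/(1+\hat m^p)$, $p \in \{1, 2\}$ (default
2), where $\hat m$ is the gradient magnitude divided by its 99th
percentile, capped at 1, and scaled to $[0, 10]$.  The percentile
rescale makes $g$ invariant to the normalization convention; the cap
bounds the influence of extreme outliers.  Note the consequence
exploited by the leak experiments: when hairs carry the strongest
gradients, they set the percentile and the fuzzy border's $g$ stays
high — precisely the leak mechanism.

### Probability map

Per channel $i$ and label, a Gaussian
$p(x) = e^{-(x-\mu)^2/2\sigma^2}/(\sqrt{2\pi}\sigma)$ is fitted to the
patch samples (population SD, floored at $10^{-3}$ for constant
patches).  The per-channel foreground probability
$P^i = p^i_F/(p^i_F + p^i_B)$ (densities floored at $10^{-12}$) is
averaged with channel weights (uniform by default; the weights are a
free parameter with no established assignment).  By construction
$P_F + P_B = 1$.

Color alone fails where lesion interior resembles skin, so spatial
connectivity is added through geodesic distances: on the 8-connected
pixel graph with step cost $|P_F(q) - P_F(p)| + \varepsilon\,\ell$
($\ell$ the Euclidean step length, $\varepsilon = 10^{-4}$ a
regularizing tie-break), the exact Dijkstra distance to the foreground
and background patch pixels gives $D_F, D_B$.  Crossing the border
costs the full probability swing regardless of path, so distances
encode "which side of the border" robustly.  The label rule (foreground
iff $D_F < D_B$) is made continuous as $s = D_B/(D_F+D_B)$, which
honors the rule exactly at $s = 0.5$; where both distances vanish the
color likelihood is used.  The implementation attaches a virtual
zero-cost source to all seed pixels and runs one single-source Dijkstra
(igraph); an independent Bellman–Ford oracle verifies it exactly in the
tests.

The probability matrix is minimized at the border band with
$\mathrm{prob}(s) = 2(s-c)^2$, center $c = 0.7$ by default (the
experimentally preferred center for dermoscopy; $c = 0.5$ gives the
symmetric baseline), and fused multiplicatively: $g_{new} = g \cdot
\mathrm{prob}$.  An optional hard floor (`edgeThreshold`) zeroes weak
fused values; it is off by default.  Whether prob should be computed
from the geodesic $s$ or the raw color likelihood is genuinely open;
the geodesic field is the default (`prob.useGeodesic`) because it is
the leak fix, and the raw alternative remains selectable.

### Level-set evolution

The reaction step is a distance-regularized evolution
$$\varphi \leftarrow \varphi + \tau_1\big[\mu\,\mathrm{div}(d_p(|\nabla\varphi|)\nabla\varphi)
 + \lambda\,\delta_\epsilon(\varphi)\,\mathrm{div}(g_{new}\tfrac{\nabla\varphi}{|\nabla\varphi|})
 + \beta' g_{new}\,\delta_\epsilon(\varphi)\big]$$
with the double-well $d_p$ (wells at $|\nabla\varphi| = 0$ and $1$),
the smoothed compact Dirac $\delta_\epsilon$, and the effective balloon
weight $\beta' = \beta v$ — the curvature/length and $g v$ speed terms
of the two-step reaction–diffusion scheme mapped onto the
distance-regularized term structure, with the reaction multiplicative
in $|\nabla\varphi|$ (the additive literal form is dimensionally
inconsistent but exposed as `reaction = "as_printed"`).  The diffusion
step $\varphi \leftarrow \varphi + \tau_2\,\Delta\varphi$ (5-point
Laplacian, Neumann borders) regularizes without reinitialization.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| $\tau_1$ | 0.3 | reaction time step; reference value for this scheme |
| $\tau_2$ | 0.01 | diffusion time step (explicit stability needs $\le 0.1$) |
| $v$ | 0.7 | propagation speed constant |
| $\mu$ | 0.5 | $\mu\tau_1 = 0.15$, near the $1/4$ explicit ceiling: the distance band must be rebuilt as fast as the front moves, else the front detaches from its transition band and stalls |
| $\lambda$ | 5 | edge-attraction strength, common practice |
| $\beta$ | 1.5 | balloon weight (effective $\beta v \approx 1$) |
| $\epsilon$ | 2.5 | Dirac width; deliberately wider than $c_0$ so the binary-step plateau still feels a small force and the front cannot freeze against it |
| $c_0$ | 2 | binary-step magnitude |

The initial field is the exact binary step ($-c_0$ inside the coarse
bounding box dilated by 10 px, $+c_0$ outside); before iterating it is
conditioned by 8 explicit diffusion sweeps ($dt = 0.25$) so a narrow
transition band exists for the Dirac terms to act on.  $|\nabla\varphi|$
is floored at $10^{-10}$.

**Stopping.**  The evolution stops when the enclosed area (pixels with
$\varphi < 0$) is stable within `areaTol` (10 px) — but because that
area is an integer pixel count, a steadily moving front crosses pixel
layers in bursts and shows isolated zero-change iterations long before
the border is reached.  The rule therefore requires a *sustained* run
of `areaWindow` (default 10) consecutive small changes; window 1
reproduces the plain two-iteration comparison.  A `maxIter` cap (500)
guarantees termination; hitting it is reported as non-convergence in
the result.  Of the final $\varphi < 0$ region only the connected
component overlapping the initial rectangle is kept — the single
topological selection needed to output one lesion, with no
morphological cleanup of the segmentation.

## The synthetic generator

`lesionSpec()`/`generateLesion()` emulate the challenge axes of
dermoscopy border detection: a radially perturbed ellipse (4 random
harmonics, amplitude `irregularity`) as ground truth; a soft
lesion/skin transition (Gaussian blur of the truth mask, `blurSigma`);
adjustable contrast through the two mean RGB colors; i.i.d. per-channel
Gaussian noise; and dark cubic-Bézier hair strokes 1–3 px wide.  The
generator is a pure function of its spec including the seed.

Conditions were fixed once: a 224×224 canvas (the smallest square on
which a centered lesion leaves room for two non-overlapping 70×90
patches), semi-axes (58, 70) so a 70×90 window fits inside the lesion
at the default irregularity, noise SD 8 (visible but not dominant at
8-bit scale), skin (200, 160, 140) and lesion (110, 70, 60) palettes.
`fixtureSuite()` builds six classes × two seeds: sharp; fuzzy with blur
4, 8, 12 (the two heavier blurs at contrast 30 with 3 hairs); low
contrast (Δ = 25, 3 hairs); and a heavily haired fuzzy case.  The hair
load on the heavy-blur/low-contrast classes is what puts them in the
leak regime: with hairs setting the gradient scale, the plain-gradient
ESF retains high values on the fuzzy border and the contour collapses
through it (Dice < 0.15 in our runs), while the fused ESF stops at the
probability border (Dice > 0.9).  Without artifacts, denoising plus the
percentile rescale keep the plain ESF's border valley deep enough that
both indicators behave near-identically — the leak pathology the fusion
cures is an artifact-driven one.

What passing on these fixtures does *not* show: real dermoscopy
exhibits ruler markings, air bubbles, specular highlights, multi-modal
pigment textures and vignetting, none of which are modeled; color
distributions are Gaussian by construction, matching the model family
the pipeline fits (real lesions are heavier-tailed); and the lesion is
a single simply connected blob.  Results on the battery validate the
mechanics and the leak-resistance mechanism, not clinical performance.

## Numerical choices and degenerate inputs

* Intermeans: a constant image has no bimodal structure and errors; a
  transiently empty class during iteration is nudged back inside.
* Gaussian densities floored at $10^{-12}$, SDs at $10^{-3}$, gradient
  magnitudes at $10^{-10}$: outlier pixels and constant patches stay
  finite.
* Geodesic ε-regularizer $10^{-4}$ per unit step breaks ties toward
  short paths and keeps distances strictly positive off the seeds.
* Distance-transform ties for the background anchor break row-major;
  window-placement ties resolve by distance to the anchor.
* The edge-indicator percentile rescale makes results invariant to the
  kernel normalization convention and to global intensity scaling of
  the magnitude field.
* All computations are deterministic; the only RNG is the synthetic
  generator, which isolates and restores the caller's RNG state.

## Known limitations

* The fused ESF stops at the probabilistic border band, which for
  heavily blurred boundaries sits slightly outside the gradient crest —
  a small systematic over-segmentation on clean fuzzy lesions, the
  price of not leaking on artifact-laden ones.
* A hair arrangement that fragments the geodesic border ring can leave
  the fused contour without a closed stopping band (one fixture seed in
  the battery shows this; the evolution then runs to the iteration cap).
* Single-lesion output by construction; no narrow-band acceleration, so
  runtime scales with image area times iterations (a 224×224 fixture
  takes a few seconds per run on one core).
* Gaussian, B-spline and Q-spline SPH kernels are named in the
  literature but not implemented; the config reserves the slot.
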