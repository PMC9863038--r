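---
title: "Specular highlight removal for endoscopy: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specular highlight removal for endoscopy: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endospec)
```

This vignette is the package's own account of the method it implements:
what each stage computes, which parameters matter and why their defaults
are what they are, what the synthetic data generator does and does not
emulate, and the numerical decisions taken where the design was open.

## Why brightness comes first

Thresholding color channels to find specular highlights fails at the two
ends of the exposure range: in a bright frame a fixed threshold swallows
whole well-lit regions, in a dark one it misses every faint highlight.
The pipeline therefore classifies each frame before detecting anything.
With `la` the mean BT.601 luma and `La` the expected brightness of a
normally exposed frame, the relative deviation

$$T_1 = \frac{l_a - L_a}{l_a}$$

is compared against a band $[-t_1, t_1]$: above it the frame is *high*,
below it *low*, inside it *medium*. Defaults `La = 112` and `t1 = 0.3`
are the values reported to separate clinical material best; both are
exposed in `classifierParams()`. Two readings of the rule needed fixing:
the printed low-brightness condition overlaps the medium band unless it
is read as $T_1 < -t_1$ (the only partition-consistent reading, and the
one implemented, with boundary ties going to medium), and the denominator
is deliberately $l_a$, not $L_a$ — the deviation is relative to the
*observed* exposure. Which scalar "brightness" means is unstated in the
source material; the package defaults to BT.601 luma because `La = 112`
sits on an 8-bit intensity scale and luma is the conventional scalar
brightness, but `channel = "v"` (HSV value) and `"gray"` (plain mean) are
available. A fully black frame, where $T_1$ is undefined, is classified
low without computing it.

## Low-light enhancement

Low frames are enhanced on the HSV value channel only; hue and
saturation pass through untouched, which is what keeps tissue color
undistorted. The chain is: adaptive gamma, one level of Haar wavelet
analysis on both the original and the gamma-corrected channel,
singular-value equalization of the approximation band, soft-threshold
denoising of the detail bands, inverse transform, requantization.

Three formulas in this chain are cited but not printed by the source
material, so the package pins standard, parameter-free choices and keeps
each behind a single replaceable function:

* **Gamma** (`adaptiveGamma`): $\gamma = \log 0.5 / \log(\mu_V/255)$,
  the map-the-mean-to-mid-gray rule; monotone, brightening exactly when
  $\mu_V < 127.5$, with 0 and 255 fixed points. $\mu_V$ is clipped to
  $[1, 254]$ so the logarithm is always defined. A fixed exponent can be
  supplied instead (`gamma = 1` disables the correction).
* **Equalization** (`singularEqualize`): with $LF = U\Delta V^\top$, the
  factor $\xi = (\max\Delta + \max\Delta_\gamma)/(2\max\Delta)$ scales
  the whole singular spectrum, i.e. $LF_{eq} = U(\xi\Delta)V^\top$. This
  transfers half of the gamma correction's intensity gain while keeping
  the original singular vectors; for any matrix this equals $\xi \cdot
  LF$, which the tests exploit as a closed form. An all-zero band (black
  frame) falls back to the gamma-corrected band.
* **Denoising** (`softThresholdBands`): universal threshold
  $\lambda = \hat\sigma\sqrt{2\ln N}$ with
  $\hat\sigma = \mathrm{median}(|HH|)/0.6745$, the MAD estimate from the
  diagonal band.

The wavelet is Haar at level 1 — the equalization acts on a single
approximation band, so deeper pyramids would change the method, not just
a parameter. Haar is implemented in the package directly (orthonormal,
~30 lines); odd dimensions are handled by replicating the last row or
column and cropping after synthesis, which keeps reconstruction exact to
floating point. Requantization rounds half away from zero and clips to
$[0, 255]$; with gamma forced to 1 and denoising off the whole chain
returns its input within one intensity step, which the tests assert.

Because the equalized band is $\xi \cdot LF$ and $\xi > 1$ exactly when
gamma brightened the channel, the mean value channel strictly increases
for any non-constant dark frame — the brightening guarantee the tests
check on 50 seeded low frames.

## Detection

**Absolute highlights** are saturated spots. Endoscopic tissue is
red-dominant (hemoglobin), so saturation is most discriminative on the G
and B channels: under a highlight all three channels are nearly equal
and very high, while diffuse tissue keeps G and B well below R. After
per-channel contrast enhancement with disc top-hat/bottom-hat filters
(`out = in + tophat − bottomhat`, clipped), the single global threshold

$$Th = \max(g, b) - \tau \cdot \frac{\sigma_g + \sigma_b}{2}$$

flags every pixel with $\max(G(p), B(p)) \ge Th$. $\tau$ depends on the
brightness class — 0.3 (high), 0.8 (medium), 1.1 (low, applied after
enhancement): the brighter the frame, the larger the threshold must stay
to avoid swallowing well-lit tissue. Two readings were pinned here: the
"maximum of the g and b channels" is the *global* maximum (one adaptive
scalar threshold per frame), and the per-pixel criterion is
$\max(G, B)$. A near-constant frame ($\sigma_g + \sigma_b < 1$) would
make $Th$ collapse onto the maximum and flag everything, so the detector
declares no absolute highlights instead — the formula presupposes that
highlights (an intensity spread) exist.

**Relative highlights** are fainter but sharply bounded, so they are
found in the gradient domain: 3×3 Sobel magnitude on the grayscale
(exact spatial-domain arithmetic — a constant frame yields an exactly
zero field), candidates at `g >= sobelThreshold`, an intensity floor
(`gray >= minIntensityRel`) to discard dark edges such as vessel walls,
and a hole fill so a bright blob outlined by its own edge ring is
flagged in full. The unstated custom threshold defaults to 4× the mean
gradient magnitude (scale-adaptive) and the floor to mean + sd of the
grayscale; both are configurable. The top-hat radius defaults to 5 px up
to 512-px frames and scales proportionally above; the final mask is the
union of both branches dilated by a 2 px Euclidean disc, which is what
covers the dark halo rings around bright spots.

The contrast enhancement feeds only the absolute branch; the gradient
branch runs on the unenhanced grayscale of the working frame, mirroring
the split between color-space analysis and gradient analysis.

## Inpainting

The repair is exemplar-based: the hole $\Omega$ is filled patch by patch
from the known region $\phi$, ordered by a priority on the fill front
$\partial\Omega$. The classic algorithm uses $P(p) = C(p)D(p)$ — the
product of the confidence term (fraction of known information in the
9×9 patch at $p$, Criminisi's update rule after each fill) and the data
term (isophote strength across the front, normalized by $\alpha = 255$)
— with a global search for the SSD-best source patch. It is retained,
independently coded, as `mode = "criminisi"`, and serves as the
reference the improved mode is tested against byte for byte when the
improved mode's window is forced to the whole frame and its priority to
the original product.

The improved mode changes three things:

* **Per-region repair.** Highlights in endoscopy are many, small and
  unrelated; the priorities of one region say nothing about another. The
  mask's 8-connected components are repaired one at a time
  (raster-encounter order), so each step evaluates priorities on one
  region's boundary only.
* **Hybrid priority.** The plain product collapses when either factor
  does: the confidence decays to zero deep in large holes (making the
  order effectively random), and the data term is zero on structureless
  fronts. The priority is therefore
  $$P(p) = \begin{cases} R_C(p) + \beta D(p) & C(p) < 0.5\\
  C(p)\left(D(p) + \dfrac{1}{1+|K(p)|}\right) & C(p) \ge 0.5\end{cases}$$
  with the regularized confidence $R_C = (1-w)C + w$ ($0 < w < 1$) and
  the isophote curvature $K = \nabla\cdot(\nabla I/|\nabla I|)$. In the
  low-confidence branch the additive form keeps the data term
  influential; in the high-confidence branch the curvature-penalized
  constant keeps the priority away from zero when $D = 0$ and favors
  straight isophotes (the term tends to 1 as isophotes straighten). The
  printed form of both branches is typographically corrupted in the
  source material; these readings are the package's, chosen to be
  bounded, partition-consistent and to satisfy the stated motivations,
  and the combiner lives in one replaceable function
  (`patchPriority`). Defaults `w = 0.7` and `β = 0.5` are package
  choices within the stated constraint $0 < w < 1$ (neither value is
  given); both are configurable.
* **Adaptive local search.** Tissue statistics are local; the best match
  is almost always near the hole, and a global search both mismatches
  and scales with frame area. The search window is the region's bounding
  box expanded by $n\,h$ rows and $n\,w$ columns, $n = n_1$ for short
  contours ($l_c < a$) and $n_2$ otherwise, clipped to the frame.
  Defaults $n_1 = 2$, $n_2 = 4$ and the resolution-dependent pivot
  $a = 0.05(H+W)$ are package choices (none is stated). If the clipped
  window contains no fully-known candidate patch, $n$ grows by one and
  the window is recomputed, up to the whole frame — this guarantees
  progress on pathological masks.

### Numerical choices

* **Isophote estimation.** The gradient "over known pixels only" is not
  computable at the front pixel itself for the along-front direction (its
  neighbors in that direction are masked), which would zero the data term
  on every straight front. The data term therefore uses the strongest
  gradient among the known pixels of the target patch — central
  differences where both neighbors are known, one-sided at the front —
  rotated 90° and projected on the front normal (from the gradient of
  the evolving mask, unit-normalized; an isolated pixel with no defined
  normal uses $(1,0)$ by convention). This is the standard
  exemplar-inpainting reading of "the isophote at $p$".
* **Curvature** uses central differences of the normalized gradient
  field with an $\varepsilon = 10^{-6}$ magnitude guard (flat regions
  return 0). On a radial cone it reproduces $1/r$ within 20%, which the
  tests check.
* **Tie-breaking** is lexicographic $(y, x)$ everywhere — equal
  priorities and equal SSD both resolve to the smallest row, then
  column — making every repair bit-reproducible.
* **Candidate patches must be fully known** (no partially known
  sources); filled pixels become usable sources for later steps, with
  confidence set to the target's $C(p)$ at fill time.
* **Border patches** are cropped at the frame border, with denominators
  and SSD sums taken over the cropped support.
* **Cost locality.** All per-step state (image, mask, confidence,
  grayscale) is cropped once per region to the search window plus a
  patch margin, so per-step cost is independent of canvas size; the only
  whole-frame work is one labeling pass and the final copy-back. The
  tests verify that a fixed 20×20 highlight costs the identical number
  of candidate evaluations on a 256² and a 1024² canvas (holding `a`
  fixed across the two, since the auto pivot is resolution-dependent by
  design) and that CPU time grows by less than 25%.

## Evaluation

Detection is scored per pixel: accuracy, precision, recall, F1, Dice and
Jaccard from the confusion counts. F1 and Dice are algebraically the
same number; both are reported because both names are conventional, and
the tests assert their equality to $10^{-12}$ on random tables.
Undefined 0/0 ratios (empty truth and prediction) return 0 with a
warning — the conservative convention that never rewards an empty
prediction — while accuracy is computed normally. Dataset aggregation is
provided both pooled (summing counts, the default) and per-image
(averaging scores); the two differ whenever highlight load varies across
frames, and no claim is made about which matches any published table.

Repair quality uses the no-reference coefficient of variation
$COV = (\sigma/\mu)\cdot 100$ (population $\sigma$, grayscale luma — the
source material specifies neither) over the *detected* region. The
detected region includes the dilation ring around the saturated core;
that matters, because over the core alone the COV before repair is
trivially near zero (a specular blob has nearly equal, saturated
channels), whereas the detected area — saturated core, halo and
transition against tissue — has a large spread before repair and a small
one after, which is the direction the pipeline report and the tests
measure. NIQE, the other common no-reference score, needs a pretrained
natural-scene-statistics model and is out of scope; any external scorer
with the same call shape can be applied to the returned images.

## The synthetic generator

`generateFixture()` emulates the image features each stage keys on, not
endoscopic photometry: a red-dominant smooth background (R above G and B
everywhere, built from blurred uniform noise), darker curvilinear
vessels (random walks), soft-edged yellowish fat blobs (Gaussian
profiles, so their edges stay below the gradient branch's threshold, as
diffuse fat boundaries do), and specular blobs with channels within 8 of
each other at intensity ≥ 240, optionally ringed by a 1–2 px darker
halo. Exposure is set by bisection on a multiplicative gain through a
soft saturating tone curve ($255(1-e^{-s/170})$, a camera-response
stand-in that keeps bright tissue from clipping into the specular range
in high-brightness frames), until the classifier lands on the requested
class; the specular blobs are composited after the tone map, since real
specular spots saturate the sensor regardless of exposure. The
ground-truth mask is exactly the blob set; default specs put the
highlight load at roughly 0.2–3% of the frame, the range typical of
clinical material. Generation is fully determined by the seed, and the
caller's RNG state is restored.

What it does not emulate — sensor noise, chromatic aberration, motion
blur, interlacing, mucus and fluid reflections with structured texture,
and highlights that are *not* saturated. Passing the synthetic suite
therefore shows the formulas and the machinery behave as specified under
the stated image model; it does not certify clinical detection rates,
which in the source material are established on annotated clinical
datasets that are not redistributable.

## Problem sizes in the tests

The default fixture is 192×192 with three blobs of radius 4–9 px;
detection and repair on 50 such frames run in a few minutes on one CPU,
and the suite uses 96–128 px frames where only per-stage behavior is at
stake. The locality check uses a 20×20 highlight on 256² and 1024²
canvases; the classic-mode equivalence check uses twenty 32² frames with
single rectangular holes, where the exhaustive global search is cheap.
These sizes are the package's chosen study conditions; all scale
linearly in highlight pixels, not frame pixels, for the improved mode.

## Known limitations

* The detector's absolute branch presumes highlights exist; on a
  highlight-free but textured frame it will flag the brightest G/B
  pixels (the threshold is anchored at the observed maximum). The
  degenerate guard only covers near-constant frames.
* COV decreasing is necessary, not sufficient, for a good repair — a
  blurred fill also lowers it. Structure preservation is checked
  separately (edge continuation through holes).
* The classic reference mode is exhaustive by construction and intended
  for small frames and tests, not production use.
* Frames below the patch size (9 px) cannot be inpainted.
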