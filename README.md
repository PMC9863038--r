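# endospec

Specular-reflection handling for endoscopic images: brightness
classification, low-light enhancement, brightness-adaptive highlight
detection, and exemplar-based inpainting with per-region priorities and
adaptive local search.

## The problem

Endoscopes film wet, smooth mucosa from a few centimeters away with the
light source next to the lens, so frames are peppered with specular
reflections: near-saturated spots where R ≈ G ≈ B at very high intensity,
often ringed by a darker halo. These spots hide tissue, distract the
surgeon, and break downstream vision algorithms (polyp detection, lesion
segmentation, instrument tracking). Restoring plausible tissue behind the
highlights is a standard preprocessing step for minimally invasive
surgery imaging, and it has to stay fast on high-definition frames.

The package is aimed at researchers in medical image analysis who need a
tested, scriptable implementation of this preprocessing chain, and it
ships a seeded generator of endoscopic-like frames with ground-truth
masks so every stage can be exercised and benchmarked with no clinical
data.

## The method

Four stages, run in order by `runPipeline()`:

1. **Brightness classification.** With `la` the mean BT.601 luma of the
   frame and `La = 112` the expected brightness of a normal frame, the
   relative deviation `T1 = (la − La)/la` assigns the class: *high* if
   `T1 > t1`, *low* if `T1 < −t1`, *medium* otherwise (`t1 = 0.3`).
2. **Low-light enhancement** (low frames only). On the HSV value channel
   `V`: adaptive gamma `γ = log 0.5 / log(μ_V/255)`, a single-level Haar
   DWT of both `V` and `V_γ`, singular-value equalization of the
   approximation band — with SVD `LF = UΔVᵀ` the whole spectrum is scaled
   by `ξ = (max Δ + max Δ_γ)/(2 max Δ)` — soft-threshold denoising of the
   detail bands (universal threshold, MAD noise estimate), and the
   inverse DWT. H and S are untouched, so colors are preserved.
3. **Highlight detection.** The frame is contrast-enhanced per channel
   with disc top-hat/bottom-hat filters; the *absolute* branch thresholds
   `max(G, B)` at `Th = max(g,b) − τ·(σ_g + σ_b)/2`, where `τ` is 0.3 /
   0.8 / 1.1 for high / medium / enhanced-low frames — brighter frames
   get a stricter threshold. The *relative* branch takes the Sobel
   gradient magnitude of the grayscale, keeps strong, bright transitions,
   and fills enclosed rings. The union is dilated with a disc (radius 2)
   so halo rings are covered, and the mask is painted green on the frame.
4. **Exemplar-based inpainting.** Each 8-connected region is repaired
   separately. Boundary pixels get the hybrid priority
   `P(p) = R_C(p) + β·D(p)` when the confidence `C(p) < 0.5` (with the
   regularized confidence `R_C = (1−w)·C + w`), and
   `P(p) = C(p)·(D(p) + 1/(1+|K(p)|))` otherwise, where `D` is the
   isophote data term and `K` the isophote curvature. The best-matching
   9×9 source patch (SSD over known pixels) is searched only inside an
   adaptive window: the region's bounding box expanded by `n·h` and `n·w`,
   with `n = n1` for short contours (`l_c < a`) and `n = n2` otherwise.
   Repair cost therefore tracks the highlight size, not the frame size.
   The classic global-search algorithm with priority `C(p)·D(p)` is kept
   as the `"criminisi"` reference mode.

Detection quality is scored with the six standard pixel metrics
(accuracy, precision, recall, F1, Dice, Jaccard); repair quality with the
no-reference coefficient of variation `COV = (σ/μ)·100` of the repaired
area (smaller = more uniform).

## Worked example

```r
library(endospec)

fx <- generateFixture(syntheticSpec(seed = 7, targetClass = "medium"))
fx$image
#> RgbImage: 192 x 192 pixels, 3 channels (R,G,B), range [50, 250]
fx$mask
#> HighlightMask: 192 x 192, 222 specular pixels (0.60%)

res <- runPipeline(fx$image)
cat("class:", res$report$class, " Th:", round(res$report$Th, 2),
    " regions:", res$report$nRegions, "\n")
#> class: medium   Th: 240.56   regions: 3

round(scoreDetection(res$mask, dilateMask(fx$mask, 2)), 4)
#>  accuracy precision    recall        f1      dice   jaccard
#>         1         1         1         1         1         1

r1 <- res$report$regions[[1]]
cat(sprintf("region 1: %d px, %d fill steps, COV %.1f -> %.1f\n",
            r1$nPixels, r1$steps, r1$covBefore, r1$covAfter))
#> region 1: 105 px, 4 fill steps, COV 50.4 -> 1.6
```

The synthetic frame lands in the requested brightness class, the three
injected specular blobs are detected exactly (scored against the ground
truth dilated by the same radius the detector uses), and repairing the
first region drops the intensity spread of the detected area from a COV
of 50 (saturated spot plus halo against tissue) to 1.6 (uniform tissue).

A command-line front end over the same functions is installed at
`inst/cli/endospec.R`:

```sh
Rscript inst/cli/endospec.R run --input frame.png --out clean.png \
    --mask-out mask.png --report report.json
```

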