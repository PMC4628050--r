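# mammoseg

Segmentation of masses in digital mammograms, with a full evaluation suite
and synthetic phantoms for testing. The package is aimed at researchers in
medical image analysis who need a reproducible, dependency-light
implementation of the classic fuzzy-enhancement + graph-cut segmentation
family, together with the standard metrics used to grade segmentations
against ground truth.

## What it implements

**Fuzzy contrast enhancement.** The gray-level histogram is characterized by
five parameters (α = min, γ = max/2, β₁ = (α+γ)/2, β₂ = (max+γ)/2, max) and
each level *u* is mapped to a membership value *P* by a piecewise quadratic
intensification (e.g. `P = 2((u−α)/(γ−α))²` on [α, β₁)), then back to gray
levels by the affine map `g = round(α + P(max−α))`. The result stretches
mid-range structure toward the histogram center.

**Otsu's thresholding.** `otsu_threshold()` maximizes the between-class
variance σ_b²(t) = ω₀ω₁(μ₀−μ₁)², and also supplies the segmentation's
*dynamic* merge scale: the Otsu split of the edge-weight histogram.

**Graph-cut region merging.** The image becomes a weighted 8-neighbor pixel
graph (weights |I(vᵢ)−I(vⱼ)|); edges are sorted ascending and merged through
a union-find forest under the dynamic-threshold criterion

    merge(R1, R2)  iff  IRM(R1,R2) ≤ min(Int(R1) + k/|R1|, Int(R2) + k/|R2|)

where IRM is the (minimal) connecting weight and Int(R) the largest weight
absorbed into R. The default k comes from Otsu's method on the weights.

**ROI extraction and pectoral flagging.** The suspected mass is detected as
the brightest valid region, then delineated at half-maximum on the merge
criterion's k → 0 fine partition; the pectoral muscle (a bright wedge at a
top corner) is flagged and excluded.

**Metrics.** MSE/PSNR, NSD/ENL, index of fuzziness, fuzzy entropy,
target-to-background contrast (moments and entropy), local refinement error,
region-overlap acceptance (IoU at k = 0.75), boundary F-measure by exact
min-cost bipartite edgel matching, sensitivity/specificity/PPV/NPV/accuracy,
and ROC AUC.

**Phantoms.** A seeded generator of mammogram-like images (background,
breast silhouette, pectoral wedge, Gaussian masses, noise) with exact
analytic ground-truth masks.

## Worked example

```r
library(mammoseg)

ph <- generate_phantom(phantom_spec(
  breast_level = 90L, pectoral_level = 170L,
  masses = list(c(70, 60, 6, 120)), noise_sigma = 5, seed = 11))

res <- segment_mammogram(ph$image)
res$segmentation
#> <mammo_seg 128 x 128, 213 regions, k_scale = 34.04>

evaluate_segmentation(res$roi_mask, ph$mass_mask, image = ph$image)
#> <mammo_report>
#>   sensitivity                    0.932886
#>   specificity                    0.999014
#>   region_iou                     0.842424
#>   region_dice                    0.914474
#>   overlap_accepted               TRUE
#>   f_measure                      0.971963
#>   auc                            0.966504
#>   ...
```

The phantom carries one Gaussian mass (σ = 6 px, amplitude 120) under noise
σ = 5. The segmenter chose its merge scale 34.0 from the edge-weight
histogram, produced 213 regions, flagged the pectoral wedge, and the
extracted ROI overlaps the true half-maximum mass disc with IoU 0.84
(Dice 0.91) — above the 0.75 overlap-acceptance threshold; the boundary
F-measure matches predicted and true mass contours at 0.97, and pixel
intensity separates mass from background with AUC 0.97.

A command-line interface wraps the same functions:

```sh
inst/cli/mammoseg phantom --out /tmp/ph --n 2 --seed 1
inst/cli/mammoseg segment /tmp/ph/phantom_002/image.pgm \
    --labels labels.pgm --roi roi.png --report seg.json
inst/cli/mammoseg evaluate --pred roi.png \
    --truth /tmp/ph/phantom_002/mass_mask.png \
    --image /tmp/ph/phantom_002/image.pgm --out report.json
```

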