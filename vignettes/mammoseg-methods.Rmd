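---
title: "Mass segmentation in mammograms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass segmentation in mammograms: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammoseg)
```

`mammoseg` segments bright masses in digital mammograms and evaluates the
result. The pipeline has four stages — fuzzy histogram-based contrast
enhancement, Otsu thresholding, graph-based region merging with a dynamic
threshold, and region-of-interest (ROI) extraction with pectoral-muscle
flagging — plus a metric suite and a synthetic phantom generator that makes
everything testable without clinical data. This vignette explains each model,
its assumptions and tunable parameters, and the design decisions taken where
the method family leaves choices open.

## Fuzzy contrast enhancement

The enhancement characterizes the global gray-level histogram by five
parameters: `alpha` (observed minimum), `max` (observed maximum),
`gamma = max/2`, `beta1 = (alpha + gamma)/2` and `beta2 = (max + gamma)/2`.
Gray levels are mapped to membership values `P` by a piecewise quadratic
(S-function style) intensification:

* `alpha <= u < beta1`: `P = 2((u - alpha)/(gamma - alpha))^2`
* `beta1 <= u < gamma`: `P = 1 - 2((u - gamma)/(gamma - alpha))^2`
* `gamma <= u < beta2`: `P = 1 - 2((u - gamma)/(max - gamma))^2`
* `beta2 <= u <= max`, two variants (the `mode` argument):
  * **corrected** (default): `P = 2((u - max)/(max - gamma))^2`
  * **literal**: `P = 2((u - gamma)/(max - gamma))^2`, clamped to `[0, 1]`

The literal fourth branch reaches 2 at `u = max`, which breaks the membership
range and the intent of suppressing levels above `beta2`; the corrected
variant is continuous at `beta2` (both give 1/2), vanishes at both ends of the
dynamic range and peaks at exactly 1 at `gamma`. Both are provided because the
literal form documents the published transform faithfully.

Defuzzification is not prescribed by the transform family; we use the simplest
monotone map back onto the original dynamic range,
`g = round(alpha + P (max - alpha))`, rounding half away from zero. The
middle "fuzzy modification" step is the identity by default — the
intensification already lives in the membership rules — with a `modify` hook
for experimentation. Enhancement is global (one histogram per image),
pointwise and deterministic; a constant image is passed through with a
warning. Note the composite map is deliberately **not** monotone in `u`: it
amplifies mid-range structure at the cost of extreme levels, so it is a
preprocessing aid for inspection and enhancement metrics, not a step of the
segmentation path.

## Otsu's method and the dynamic merge scale

`otsu_threshold()` maximizes the between-class variance
$\sigma_b^2(t)=\omega_0\omega_1(\mu_0-\mu_1)^2$ with the lower class
`{level <= t}` and ties resolved at the smallest `t` (determinism). Besides
standalone image thresholding, Otsu's method supplies the segmentation's
"dynamic" scale: the edge weights of the pixel graph are binned into 256
equal-width bins, and the bin center at the Otsu threshold becomes the default
merge scale `k_scale`. The rationale: the weight distribution of a mammogram
pixel graph is a mixture of small within-tissue dissimilarities and large
between-structure ones, and Otsu's criterion places the split between the two
populations without a hand-set constant. The weight histogram granularity
(256 bins) mirrors the 8-bit convention and is configurable.

## Graph-based region merging

The image maps to a graph with one vertex per pixel and edges between
8-neighbors (4-connectivity available). The default edge weight is the
intensity dissimilarity `|I(vi) - I(vj)|`; a `spatial_literal` mode using only
coordinate distance is kept for reference, though under it every weight is 1
or `sqrt(2)` and segmentation cannot depend on image content. Edges are sorted
ascending, ties broken by `(weight, i, j)` so runs are bit-reproducible, and a
union-find forest processes them once. Two regions joined by the current edge
of weight `w` (their inter-region measure, IRM — minimal by the ascending
order) merge iff

    w <= min(Int(R1) + k_scale/|R1|, Int(R2) + k_scale/|R2|)

where `Int(R)` is the largest weight accepted into `R`'s merge history. The
threshold is *dynamic* in the sense that it adapts per region pair: small or
internally homogeneous regions merge readily, large heterogeneous ones resist.
Limit behavior anchors the semantics: `k_scale = 0` yields connected
components of constant intensity, `k_scale -> Inf` a single region, and the
region count is non-increasing in `k_scale`.

A cleanup stage then guarantees a minimum region size
(default `max(16, 1e-4 * n_pixels)` pixels, suppressing speckle). It walks the
sorted edges twice: first merging pairs where *both* sides are undersized,
then attaching any remaining undersized region to its lowest-weight neighbor.
The two-pass form matters on smooth intensity ramps, where single-pass
"either side small" sweeping lets one band chain-absorb dozens of thin
iso-intensity shells and produce a single thick band spanning a large
intensity range; pairing small fragments first keeps the agglomerated groups
narrow in intensity, which the ROI delineation below depends on.

## ROI extraction and pectoral flagging

A bright mass with a smooth (approximately Gaussian) profile is not delineated
by the merge criterion as one region: its interior has no strong edges, so the
segmenter produces a nested family of quasi-annular regions around the peak.
`extract_roi()` therefore works in two stages.

**Detection** runs on the supplied segmentation. Candidate seeds are regions
within `[min_area, max_area_frac * n]` pixels that do not touch the image
border and do not belong to the pectoral zone; the brightest candidate (by
mean intensity) is the seed, and its peak intensity is estimated by the upper
decile of its own pixels. The surrounding-tissue level comes from walking the
region-adjacency graph downhill (always into the brightest neighbor) until the
first region covering at least `context_frac` (default 5%) of the image —
normally the breast plateau.

**Delineation** places the mass boundary at *half-maximum*, the standard
convention for the extent of a blob with a smooth profile: the cut level is
`(peak + surround)/2`. Because the scale-`k` regions are too coarse to place
that boundary, the cut is evaluated on the finest partition the merge
criterion defines — its `k_scale = 0` limit (iso-intensity components plus the
minimum-size agglomeration). The ROI is the connected union, on that
partition's adjacency graph, of cells whose mean reaches the cut level, grown
from the cell holding the seed's brightest pixel. The surround estimate is
then refined from an annulus one to two ROI radii out (past the mass's own
shoulder but still local) and the cut repeated up to three times; refinement
can only raise the cut, so it corrects over-inclusion (e.g. when the context
walk reached the dark background through fragmented tissue) and never causes
runaway shrinkage. The final mask is always a union of whole delineation
cells, never a pixel-level threshold.

`flag_pectoral()` marks the region containing a designated top-corner pixel
when it is brighter than the image mean (`auto` picks the brighter corner).
Because noise shatters the muscle into fragments, the ROI stage excludes a
*pectoral zone*: the structure connected to the flagged region at near-muscle
intensity, grown over neighbors whose mean lies within `[0.85, 1.12]` of the
muscle level. The band is two-sided on purpose — darker neighbors are
surrounding tissue, and markedly brighter neighbors are not muscle (a mass
core outshines the muscle), so a mass lying close to the muscle cannot be
swallowed into the zone.

## Evaluation metrics

All quantities are implemented with explicit, reproducible conventions:
population (biased) standard deviations throughout; PSNR with an infinity
sentinel at zero MSE; ENL `(mean/sd)^2`; linear index of fuzziness
`(2/N) sum min(P, 1-P)` and normalized fuzzy entropy, both 0 iff the plane is
crisp and 1 iff all `P = 0.5`; target-to-background contrast by moments and by
base-2 histogram entropies with an `eps = 1e-12` denominator guard capped at
`1e12`; the asymmetric local refinement error
`|R(A,p) \ R(B,p)| / |R(A,p)|`; region-overlap acceptance as inclusive
intersection-over-union at `k = 0.75`; and ROC AUC via the Mann–Whitney rank
identity with half-credit for ties. Boundary agreement extracts 8-connected
region borders and matches edgels one-to-one by a maximum-cardinality
minimum-cost assignment (admissible within `d_max = 2` px, cost = Euclidean
distance), solved exactly as a unit-capacity min-cost flow for up to 5000
edgels per side and by greedy nearest-unmatched beyond, with a warning. The
F-measure depends only on the matched count, so the greedy fallback can
perturb it only slightly and never changes the admissibility radius.

## The phantom generator

Synthetic phantoms stand in for mammograms so that ground truth is exact: a
dark background, a half-elliptical breast silhouette anchored to the chest
wall side (the vertical semi-axis slightly exceeds the half-height so the
wedge reaches the corner pixel), a triangular pectoral wedge in the top corner
of that side, Gaussian-profile masses `A exp(-d^2/(2 sigma^2))`, and additive
Gaussian noise, clipped and rounded to the integer range. The mass ground
truth is the analytic union of half-maximum discs (radius
`sigma sqrt(2 log 2)` — the full-width-at-half-maximum convention), which the
generator owns exactly. Each phantom is seeded; the caller's RNG state is
restored.

`phantom_suite()` varies size (96–160 px), mass count (0–3, always including a
mass-free negative case), geometry side, amplitudes (60–130 over breast 100)
and noise (0–8), phantom `i` using seed `master_seed + i`. The recovery
benchmark `phantom_recovery_suite()` uses 128×128 phantoms with background 25,
breast 90, pectoral 170, and a single conspicuous, well-circumscribed mass
(`sigma` 4–7 px, amplitude 100–160) — the kind of clearly delineated bright
mass a segmentation method is expected to capture — at noise 0 or 5. Problem
sizes (20-phantom suites, 128×128) were chosen so the whole acceptance run
completes in minutes on one core.

What passing phantom tests does and does not show: the phantoms emulate the
*salient geometry* of screening mammograms (silhouette, wedge, bright compact
masses, sensor noise) but not tissue texture, spiculated or ill-defined
masses, calcifications, or intensity inhomogeneity. A texture hook exists in
principle (multiplicative low-frequency fields could be added to the
generator), but results here demonstrate correctness of the machinery and
recoverability of compact masses, not clinical performance.

## Numerical choices and degenerate inputs

* Ties everywhere are broken deterministically (smallest threshold, smallest
  pixel id); identical inputs give byte-identical outputs, including the JSON
  evaluation reports (fixed field order, 15 significant digits).
* Constant images: enhancement returns the input with a warning; segmentation
  yields one region; Otsu raises a degenerate-histogram error.
* Degenerate histogram orderings (`min > max/2`, so `gamma <= alpha`) make the
  lower membership branches empty; the piecewise domains are evaluated as
  stated rather than assumed non-empty.
* Membership continuity at the breakpoints holds to well below `1e-9`; the
  unimodality of the corrected plane (non-decreasing up to `gamma`,
  non-increasing after) is property-tested.
* The merge loop is compiled (C++ union-find with union-by-size and path
  halving); everything else is vectorized R.

## Known limitations

* The half-maximum delineation assumes a roughly unimodal bright mass on a
  locally flat surround; plateaued (clipped) or strongly overlapping masses
  widen the estimate.
* The pectoral zone logic assumes the muscle is the brightest large structure
  at a top corner; a mass both adjacent to the muscle and at near-muscle
  intensity can evade seeding (observed roughly once per several hundred
  random phantoms).
* `spatial_literal` weights are provided for documentation of the published
  formula, not for use.
* Enhancement is global; micro-calcification-scale local contrast is out of
  scope.
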