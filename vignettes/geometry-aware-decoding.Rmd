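---
title: "Geometry-aware decoding of extreme-point heatmaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-aware decoding of extreme-point heatmaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extremecell)
```

## The problem

Bottom-up cell detectors locate each cell by five characteristic points —
the topmost, bottommost, leftmost and rightmost points of its boundary plus
its center — predicted as per-pixel heatmaps by a keypoint network. Turning
those heatmaps into detections requires *grouping*: picking one peak per
extreme-point type and deciding whether the four of them belong to the same
cell. Brute-force grouping accepts any combination whose geometric center is
endorsed by the center map. In microscopy this fails in a characteristic
way: fields are globally sparse but locally dense, and when cells touch or
line up, an extreme point of one cell pairs with the extreme points of a
neighbor while a third cell's center (or a center-map tail) endorses the
combination. The result is a wide spurious box stitched across cells, often
scoring as high as the true detections.

`extremecell` implements the decoding side of a geometry-aware remedy: every
candidate combination is verified against a per-class library of *adjacency
spectra* before it may become a detection. The package also ships the
training losses as pure functions, a synthetic scene/heatmap simulator that
stands in for the trained network, COCO-style AP evaluation, and
readers/writers for LabelMe and COCO JSON.

## The adjacency spectrum

The four extreme points of a cell, connected in their cyclic spatial order
top → right → bottom → left, form an undirected 4-cycle graph $G$. Its
adjacency matrix $A(G)$ has entries $a_{ij} = \omega_{ij}$, the Euclidean
distance between extreme points $i$ and $j$ when they are adjacent in the
cycle and 0 otherwise. The *adjacency spectrum* is the descending-sorted
solution of the characteristic equation $\det(\lambda I - A) = 0$; for a
symmetric matrix all four roots are real.

Because the entries of $A$ depend only on pairwise distances, the spectrum
is invariant under rotation, translation and reflection of the points, and
scales linearly when the points are scaled — exactly the invariances of "a
cell of this type, anywhere in the field, at fixed magnification". Two
structural identities follow from the cycle having zero diagonal and
bipartite structure: $\sum_i \lambda_i = 0$ and
$\lambda_1 = -\lambda_4,\ \lambda_2 = -\lambda_3$. Closed forms used as test
oracles: an equal-weight cycle $w$ has spectrum $(2w, 0, 0, -2w)$;
alternating weights $a, b$ give $(a+b, |a-b|, -(|a-b|), -(a+b))$.

A class reference ("Spec0") is built from annotated training instances:
every instance's spectrum is stored, the centroid is their elementwise
mean, and a cluster radius $r_0$ is derived from the distances of training
spectra to the centroid. Two radius rules ship: `max` (every training
spectrum inside) and `quantile(q)` (default $q = 0.95$, robust to outlier
annotations), each inflated by a tolerance multiplier (default 1.1). A
candidate is accepted iff the Euclidean distance between its spectrum and
the centroid is at most $r_0$. A `nearest` mode compares against the
nearest stored training spectrum instead of the centroid; both
interpretations are defensible readings of verification against a stored
library, and the centroid mode is the default because it is cheaper and
smoother. Spectra are kept in raw pixels, so verification is
size-sensitive — a deliberate choice, since cell size at fixed
magnification is diagnostic; an optional perimeter normalization provides
magnification-invariant matching.

## Decoding pipeline

Per class:

1. **Peak extraction.** A grid cell is a peak iff its response reaches
   `peak_threshold` (default 0.1) and is `>=` every value in its 3×3
   neighborhood (truncated at edges). The `>=` comparison means plateau
   cells all qualify; ties on truncation are resolved in row-major scan
   order. This matches a brute-force per-cell scan exactly (tested).
2. **Offset refinement.** Heatmaps live on a grid down-sampled by a factor
   $s$; offset maps carry the lost sub-cell fraction
   $x/s - \lfloor x/s \rfloor$ per axis. A refined position is
   $s(\text{cell} + \text{offset})$; with simulator-rendered offsets the
   decoded keypoint position is exact. Without offset maps the decoder
   falls back to cell centers and warns.
3. **Center grouping.** All (top, left, bottom, right) combinations are
   enumerated, ordered by compactness (ascending sum of the six pairwise
   distances among the four extremes; ties by score descending) so that
   plausible single-cell candidates come before cross-cell mixtures. A
   combination is a candidate iff it is geometrically valid and the center
   map's response at the cell of its induced center exceeds
   `center_threshold` (strict `>` by default; configurable). The candidate
   score is the mean of the five responses.
4. **Verification and consumption.** With verification on, candidates are
   visited in order; each accepted ("fully successful") candidate consumes
   its four extreme peaks so they cannot be recombined — this directly
   prevents the double-combination error where already-combined points pair
   again with a neighbor's points. A rejected ("semi-successful") candidate
   leaves its peaks available and grouping continues.
5. **Scoring and suppression.** Detections below `score_threshold` are
   dropped; greedy same-class suppression removes boxes with IoU above 0.5
   against a kept higher-scored detection.

### The geometric validity predicate

Validity requires `top.y <= bottom.y`, `left.x <= right.x`, the induced
center inside the box — and additionally that each extreme's transverse
coordinate lies inside the box: the leftmost point of a genuine cell
necessarily has its y between the top and bottom extremes, and likewise for
the other three points. The additional checks hold by construction for
every true extreme set, and without them a far-away instance's extreme can
be borrowed while the combination's center still lands on a true center
cell, producing spurious detections even in well-separated scenes. They are
therefore part of what "the geometric relationship" of an extreme set
means here.

### Center lookup

The candidate center is continuous; the center map is a grid. Two lookup
rules are available: `nearest` (default; round half-down per axis) and
`floor`, which matches the renderer's assignment of keypoints to cells. On
noise-free maps, `floor` guarantees that a perfectly decoded true candidate
reads its center keypoint's own cell (response exactly 1), which allows a
high `center_threshold` to separate true candidates from chance-endorsed
cross-cell ones; `nearest` is kept as the default because with real
(noisy, miscalibrated) maps there is no alignment guarantee to exploit.

## Losses

The detector trains under two losses, implemented here as pure functions
for verification rather than training. The pixel-wise classification loss
is a variance-focused focal loss over Gaussian-softened ground truth
$Y \in [0,1]$ with predictions $\hat Y$:

$$L_{det} = -\frac{1}{N}\sum_{ij}
\begin{cases}(1-\hat Y_{ij})^\alpha \log \hat Y_{ij} & Y_{ij} = 1\\
(1-Y_{ij})^\beta \hat Y_{ij}^\alpha \log(1-\hat Y_{ij}) & \text{otherwise}
\end{cases}$$

with $\alpha = 2$, $\beta = 4$ and $N$ the number of annotated targets
(supplied by the caller, never inferred). Only cells with $Y = 1$ exactly
are positives; Gaussian-softened neighbors fall in the otherwise-branch
where $(1-Y)^\beta$ down-weights them. Predictions are clipped into
$(\varepsilon, 1-\varepsilon)$ with $\varepsilon = 10^{-7}$ to keep the
logarithms finite. The offset loss is smooth-L1 between predicted and true
sub-cell offsets, averaged over keypoints; smooth-L1 is $0.5x^2$ for
$|x|<1$ and $|x|-0.5$ beyond, continuous with continuous slope at
$|x|=1$.

## The synthetic simulator

The simulator exists so that every decoder stage is testable without
microscopy data or trained weights. It emulates, at the level the decoder
sees:

- **Shape families** mirroring the morphologies of interest: ellipse
  (nuclei), crescent (*Toxoplasma*; analytic difference of two discs),
  spindle (*Trypanosoma*; two symmetric circular arcs meeting at sharp
  tips), pear (*Babesia*; two discs bridged by their external tangents).
  Default sizes are 12–30 px across, the scale of cells in 100× oil
  immersion crops. Any simple-polygon family would do; extreme points are
  read off the polygon exactly as mask annotations would be.
- **Placement** that is globally sparse and locally dense: a configurable
  fraction of instances is placed as touching/overlapping pairs (partner
  polygons required to intersect), the rest by rejection sampling without
  contact. `min_spacing` adds clearance for isolated-cell fixtures.
- **Heatmaps**: each keypoint contributes an unnormalized Gaussian
  $\exp(-d^2/2\sigma^2)$ in grid-cell distance around its cell, combined
  across instances by elementwise max (values never exceed 1 and every
  annotated keypoint cell is exactly 1). The softening width defaults to
  $\sigma = 1.2$ grid cells (≈5 px at the default $s = 4$): softening
  should stay below the object scale, the way keypoint-radius rules tie
  the radius to box size; at 16–24 px cells a broader kernel would endorse
  combination centers half an object away, which no usable trained network
  does. Additive Gaussian noise (clipped to $[0,1]$) and optional
  salt-and-pepper impulses model prediction noise.
- **Offsets**: the true sub-cell fractions at each keypoint's cell, with
  later instances overwriting on (rare) collisions, deterministically.

What it does **not** emulate: stain texture, illumination, debris, missed
or hallucinated keypoints, miscalibrated response magnitudes, or
correlated network errors. Passing the end-to-end tests therefore shows
the decoder is exact over its own contract — not that any particular
network reaches a given AP on real slides.

### Fixtures used by the end-to-end checks

*Isolated recovery.* Fifty seeded noise-free scenes with
`overlap_fraction = 0` and `min_spacing = 28` check decoding fidelity:
every instance must be recovered at IoU ≥ 0.75 with zero spare detections,
and AP50 = AP75 = 100 through the evaluation module. These scenes use
`center_lookup = "floor"` with `center_threshold = 0.9`: on clean maps
every true combination scores exactly 1 at its own center cell, so the
high threshold removes chance-aligned cross-cell combinations — which are
deliberately *not* the subject of this check. Problem size (192×192 px,
4–7 cells) keeps the full suite in a couple of minutes on one core.

*Juxtaposed chains.* The verification-benefit fixture builds diagonal
chains of three round cells A–C–B with C exactly midway between A and B,
cell-size jitter of 10% across chains, and sub-cell phases arranged so
that the decoded centers of A and B read a one-cell Gaussian tail while
the cross-cell combination (A's top/left with B's bottom/right) lands
exactly on C's center cell. The spurious wide box then scores at least as
high as the true cells — the stitched-across-cells failure in its
sharpest form. At identical default thresholds, enabling spectrum
verification (reference built from the fixture's own annotations, `max`
rule) strictly removes the false positives of every scene and strictly
raises AP50; the wide candidate's spectrum sits roughly twice the linear
scale of the training spectra, far outside the cluster radius, and peak
consumption by the previously accepted true cells blocks it as well.

## Evaluation

`evaluate_detections()` implements COCO-style AP: greedy score-ordered
one-to-one matching per class and image, 101-point interpolated AP per IoU
threshold over 0.50:0.05:0.95, averaged over classes (classes with no
ground truth are excluded, matching the COCO convention that categories
come from the ground truth), and `ap_avg` the mean over thresholds. Boxes
are real rectangles, no +1 convention; COCO `[x, y, w, h]` converts with
`xmax = x + w`. Score ties break by input order. The suite checks
agreement within 0.1 AP against an independent transcription of the COCO
evaluator's per-image matching and accumulation.

## Numerical choices and degenerate inputs

- Eigenvalues come from the symmetric eigensolver (`eigen(symmetric =
  TRUE)`); tests require agreement with the quartic characteristic
  polynomial's roots to 1e-8 on 1000 random quadrilaterals.
- Coincident extreme points are not errors: the adjacency matrix is built
  (with a warning) and the candidate's spectrum will normally fail
  verification.
- Degenerate polygons (all vertices collinear) raise a classed error from
  `extreme_points()`.
- All randomness flows through per-call seeds; generator and renderer
  restore the caller's RNG state.
- Peak plateaus: `>=` window comparison, row-major tie-break; documented
  and oracle-tested.

## Limitations

- Verification in raw pixel units presumes fixed magnification between
  reference building and detection; use the normalization flag otherwise.
- Brute-force grouping is quartic in peaks per type; `max_peaks` (default
  40) bounds the work, which is ample for fields with tens of cells.
- The center point never joins the verification graph; only the 4-cycle on
  extremes is used.
- The simulator's idealized heatmaps cannot certify performance on real
  microscopy images; they certify the decoder's contract.
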