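---
title: "Detecting mitral annulus hinge points with an additive-kernel SVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mitral annulus hinge points with an additive-kernel SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a 2D apical four-chamber echocardiogram the mitral annulus appears as the
pair of points where the mitral leaflets attach to the heart wall: the
*septal* hinge point (next to the interventricular septum) and the *lateral*
hinge point (on the free wall). Locating them reliably matters for chamber
segmentation, valve modelling and multi-modality registration, but
ultrasound frames are noisy, low-resolution and full of dropout, so simple
edge or corner detectors (Sobel/Laplace, HOG/SIFT-style interest points) are
not dependable there. This package implements a three-layer detector:

1. a **sparse local-context feature** describing the tissue layout around a
   pixel,
2. a **histogram-intersection-kernel SVM** classifying every pixel, with an
   exact fast evaluation that makes per-pixel scanning cheap, and
3. a **density-field refinement** that turns the classifier's candidate
   cloud into exactly two landmark coordinates.

Because clinical data cannot ship with the package, a synthetic phantom
generator produces four-chamber-like frames with known ground truth; all
tests and the worked examples run on phantoms.

```{r, eval = FALSE}
library(mahinge)
demo <- cmd_demo(seed = 1)
```

## The local-context feature

Cardiac tissues keep a fixed spatial arrangement in the four-chamber view,
so the neighbourhood of a pixel — which directions look like blood pool,
which like wall — identifies structures that local gradients cannot.
Sampling every neighbour would be enormous; instead the feature samples
**eight directions at 45° intervals** at radii `{1, 3, 5, 9, 13, 17, 23,
29}` pixels, denser near the centre where the context is most informative.
Each sampling point contributes the **mean of its 3×3 neighbourhood**
rather than a raw gray value, which suppresses speckle without blurring
away structure; with the centre pixel included this gives a 65-dimensional
vector of gray means in `[0, 255]`.

Layout and conventions (frozen, since train and test must agree):
centre first, then directions in the fixed order
`(0,1), (1,1), (1,0), (1,-1), (0,-1), (-1,-1), (-1,0), (-1,1)` as
`(row, col)` offsets with rows increasing downward, radii ascending within
each direction; all coordinates are 1-based, matching R matrices. At the
image border both the 3×3 mean and out-of-range sampling offsets use
replicate-edge padding: replication keeps feature entries inside the
image's gray range instead of injecting artificial zeros, which matters
because the intersection kernel treats coordinates as nonnegative masses.
Features are *not* normalised to histograms — the kernel only requires
nonnegativity, and raw gray means preserve the absolute bright/dark
contrast that distinguishes wall from blood pool.

## The classifier and its fast evaluation

A soft-margin C-SVM is trained in the dual over the **histogram
intersection kernel** `K(x, z) = Σᵢ min(xᵢ, zᵢ)`, giving the decision
function

```
h(z) = Σₗ αₗ yₗ K(xₗ, z) + b ,   0 ≤ αₗ ≤ C,  Σₗ αₗ yₗ = 0 .
```

Evaluating this directly costs `O(m·n)` per query for `m` support vectors —
prohibitive when every pixel of a frame is a query. But the kernel is
*additive*: the sum over dimensions can be exchanged with the sum over
support vectors, so `h(z) = Σᵢ hᵢ(zᵢ) + b` with
`hᵢ(zᵢ) = Σₗ αₗ yₗ min(zᵢ, x_{l,i})`. Sorting the support values in each
dimension once after training and splitting the sum at `r`, the number of
sorted values `≤ zᵢ`, gives

```
hᵢ(zᵢ) = Aᵢ(r) + zᵢ · Bᵢ(r)
```

where `Aᵢ` is the prefix sum of `coef × sorted value` and `Bᵢ` the suffix
sum of the coefficients. Each query then needs one binary search per
dimension: `O(n log m)`, exact — not an approximation. `decide_naive()` is
kept as the reference implementation and the test suite drives thousands of
randomized (model, query) pairs through both paths, demanding agreement to
a relative `10⁻⁹`.

Numerical corner cases, all handled and tested: ties (`r` counts values
`≤ zᵢ`, duplicates counted, matching the largest-index definition); queries
below every support value (`r = 0`, `hᵢ = zᵢ·Bᵢ(0)` — algebraically zero at
the SVM optimum since `Bᵢ(0) = Σ αₗ yₗ`, but the general form keeps the
fast path identical to the naive one when the solver's equality holds only
to tolerance); a decision value of exactly zero classifies as `+1`.
Each `hᵢ` is continuous and piecewise linear with breakpoints exactly at
the sorted support values, which the suite also verifies.

Training itself is standard convex QP and is delegated to the SMO solver in
**kernlab** over a precomputed Gram matrix; the package's contribution is
the evaluation machinery around it. `C = 1` by default — the method is not
sensitive to it on phantom data and it is exposed in the configuration.
Linear and RBF kernels are available behind the same interface purely as
comparison baselines (they disagree visibly with the intersection kernel on
the standard phantom, which is itself a test).

## Candidate refinement

The classifier is deliberately permissive: the candidate set contains both
hinge clusters and scattered false positives. Density separates them. Every
candidate stamps a diamond **block-distance template** onto a field:

```
F(A) = Σ_{y ∈ C, D_block(y,A) < R} (R − D_block(y, A)) ,   R = 10 .
```

The "11-neighbourhood" around a candidate is read as the support of this
template — all pixels within block distance `< R` — giving a diamond of
width `2R − 1`, nonnegative weights, and value exactly `R` at an isolated
candidate's own pixel. A box (Chebyshev) variant would differ only at the
template corners; the diamond reading is the default and `R` is
configurable (`R = 8` behaves nearly identically, consistent with the
method's reported insensitivity to template size).

An **adaptive threshold** `H` is then searched so that the pixels with
field value *strictly greater than* `H` form exactly two connected
components (8-connectivity by default). The search is a binary search over
the sorted distinct field values: fewer than two components means the
threshold is too high (regions merged away or erased), so `H` decreases;
more than two means too low, so `H` increases. The component count is not
monotone in `H`, so every probe is recorded; if no probe hits exactly two,
the probe with the most components is taken and the two components with
the largest summed field weight are kept, with a `fallback` flag on the
result. A field whose every threshold yields one component cannot produce
two landmarks; `localize()` then returns a flagged no-detection result
rather than an arbitrary split.

Thresholding can also discard genuine hinge candidates and bias the
component centroids, so a final **two-centre K-means** re-partitions all
candidates within block distance `scale` (default `2R`) of either
centroid, seeded at the centroids: Euclidean assignment, mean update, at
most 100 sweeps. The tiny Lloyd loop is written in-package because its
degenerate-case contract (an emptied cluster is reseeded at its initial
centre and flagged) is not expressible through `stats::kmeans`, which
instead raises an error; on non-degenerate inputs the two agree exactly
and a test asserts that. Cluster means round to the nearest pixel; the
smaller-column point is labelled septal.

## The phantom generator

`generate_frame()` draws a four-chamber-like scene: dark chambers
(intensity 30) separated by bright walls (intensity 200, 5 px thick) — an
outer border, a mid-image septum, and an atrioventricular wall at 55% of
the image height interrupted by a 24 px valve gap in the lateral half. The
gap endpoints are the ground-truth hinge points; the gap centre jitters
independently per frame (±6 px). Speckle is multiplicative mean-one Gamma
noise with shape `k` (`speckle_shape`), clipped to `[0, 255]`: small `k`
is heavy speckle (`k = 2` gives a relative standard deviation of ~70%),
`k = 8` is the moderate default, `k = 32` light, `Inf` disables noise.
Mean wall/chamber contrast survives any `k ≥ 1`, the documented floor.
The defaults — 128×128 px at 0.7 mm/px — put the annulus at a scale where
the 29 px maximum sampling radius spans chamber, wall and gap, as it does
in clinical frames.

Two geometric constraints are worth knowing. First, the hinge separation
(gap width) must exceed the `2R = 20` px merging scale of the density
template, otherwise the two candidate clusters fuse into a single
component and the threshold stage cannot separate them — the 24 px
default (~17 mm, a plausible open-valve orifice) respects this, and it is
a genuine limitation of the refinement stage, not only of the phantom.
Second, the gap must fit between the septum and the free wall after
jitter, which the generator validates.

What the phantom does **not** emulate: beam-angle-dependent speckle
correlation, attenuation and shadowing, leaflet motion, probe geometry, or
anatomical shape variation. Passing tests on phantoms therefore
demonstrates the pipeline's mechanics — feature discriminability, exactness
of the fast evaluation, refinement behaviour — not clinical accuracy; the
published accuracy of the original method on patient data (mean error
≈ 1 mm) is not reproducible without that data and is not claimed.

## Training-set construction

The original method never describes its training set, so the package makes
its own choices and exposes them in `training_spec()`: positives are all
pixels within 2 px (Euclidean) of a truth point; negatives are 120 pixels
per frame drawn uniformly at least 12 px from both truth points. Uniform
negatives must be numerous enough to cover the bright wall structures —
with too few (≈40/frame), septum pixels go unsampled and the classifier
fires along the entire septum. The band between 2 and 12 px stays
unlabelled, tolerating annotation jitter. With `positive_radius = 0` the
positives collapse to the two truth pixels; with `negatives_per_frame = 0`
the set is single-class and the trainer refuses it, by contract.

## Problem sizes and runtime choices

The shipped experiments are desk-scale by design: the end-to-end recovery
test trains on 20 phantom frames (≈2 900 examples) and evaluates 20
held-out frames at three speckle levels (shapes 2, 8, 32), checking that
the median localization error stays within 3 px per landmark at the
moderate level and does not increase as speckle lightens. The demo uses 8
training and 6 test frames. Scanning a 128×128 frame classifies all 16 384
pixels; the table-based evaluation is what makes stride-1 scanning the
default rather than a luxury.

## Known limitations

- Exactly two landmarks: the pipeline assumes one open mitral valve in
  view and cannot return more or fewer (a single merged cluster is a
  flagged no-detection).
- The septal/lateral assignment is purely by column order, which is
  correct for the standard four-chamber orientation only.
- Per-frame detection: no temporal tracking across the cardiac cycle.
- Landmark accuracy is bounded by candidate-cluster symmetry; candidates
  bleeding into the valve gap bias the cluster mean inward by a pixel or
  two, visible in the phantom experiments.
- The piecewise-linear-approximation variant of the additive evaluation
  (fixed-size lookup tables) is deliberately not implemented; only the
  exact sorted-table method is.
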