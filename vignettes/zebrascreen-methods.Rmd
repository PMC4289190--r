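---
title: "Methods: random-subwindow classification of zebrafish larva phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-subwindow classification of zebrafish larva phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebrascreen)
```

## The problem

In zebrafish embryo toxicity screening, batches of larvae are exposed to a
compound, photographed one fish per well under a stereomicroscope, and scored
by eye for morphological defects — death, retention in the chorion,
curvatures of the tail or body axis, edema, yolk-sac necrosis, blood
accumulations (hemostasis), shortened tails. Manual scoring is the
rate-limiting and least reproducible step of the assay. `zebrascreen`
implements a supervised image-classification pipeline that automates it: the
larva is located and cropped, described by randomly extracted subwindows,
classified by ensembles of extremely randomized trees, routed through a
two-tier decision scheme over an 11-term phenotype vocabulary, and the
per-plate class proportions are converted to dose-response estimates (LC50,
EC50 and the teratogenicity index TI = LC50/EC50).

## Localization and cropping

Raw well images are mostly bright background. The larva is found by a chain
of classical morphological operators:

1. **Variance filter** (radius $r$, default 2 px): each pixel is replaced by
   the population variance of its $(2r+1)^2$ neighborhood, which highlights
   object edges. The border ring of width $r$, where the window would leave
   the image, is set to zero. Grayscale is the unweighted channel mean —
   larvae are dark on a bright background in all three channels, so no
   channel weighting is warranted.
2. **Binarization**: a global Otsu threshold (maximum between-class variance
   over a 256-level histogram) on the variance image. A constant image has
   nothing separable and yields an all-false mask with a warning.
3. **Two dilatations** with a 3×3 square structuring element close the edge
   response into a continuous outline.
4. **Connected components** under 8-connectivity; the largest component is
   assumed to be the larva. Equal-area ties are broken toward the smallest
   bounding-box origin so results are deterministic.
5. **Square crop**: if the component's bounding box has aspect ratio at most
   `circular_ratio_max` (default 1.2) — the near-circular case of an
   unhatched chorion — the tight bounding square is used; otherwise a square
   of side $\max(h, w)$ centered on the box. A square that would leave the
   image is clipped to a rectangle (the near-border fallback) rather than
   shifted, so the object stays centered.

The radius, threshold rule and circularity cutoff are explicit knobs with
the defaults above; none is sensitive on synthetic data (the capture rate
stays at 100% for radii 1–4).

Coordinates throughout the package are R-native: 1-based row/column indices
with closed intervals. Bounding boxes are `c(row_min, col_min, row_max,
col_max)`, all inclusive.

## Subwindows and the TRGB encoding

An image is represented by `n_subwindows` square subwindows (default 1000)
drawn at random positions and sizes. Sides are uniform on the integer
interval $[\lceil f_{\min} m\rceil, \lfloor f_{\max} m\rfloor]$ where $m$ is
the image's smaller dimension; positions are uniform among placements fully
inside the image. Squares relative to the minimum dimension avoid
anisotropic distortion (crops are near-square after preprocessing). The
default size range is 50–90% of the image: phenotypes here are global body
shapes, which large windows capture best, while the random placement still
provides the translation robustness the method is known for.

Each subwindow is resized per channel by bilinear interpolation to a fixed
`patch_px` × `patch_px` grid and standardized per RGB channel within the
subwindow — subtract the channel mean, divide by the channel's *population*
standard deviation (TRGB). A constant channel maps to zeros. The encoding is
therefore invariant to per-channel affine illumination changes, which is
what makes models transfer across acquisition sessions. The default patch
edge is 16, giving $M = 3 \times 16^2 = 768$ attributes, and the vector is
laid out channel-planar (all R, then G, then B; row-major within a plane) so
that spatial neighborhoods are well defined for the neighbor-difference node
tests. A 32×32 patch (3072 attributes) is available by setting
`patch_px = 32`; the 768-attribute default is what the ensemble's
`n_tests = 28` ≈ $\sqrt{M}$ convention assumes.

## Extremely randomized trees

The classifier is an ensemble of `n_trees` (default 10, the minimal
recommended count) extremely randomized trees grown on the pooled labeled
patch vectors. At each node, `n_tests` (K, default 28) candidate tests are
drawn; each candidate picks its attribute uniformly at random and its
threshold uniformly in the *open* interval between the node-local minimum
and maximum of the tested quantity, so a drawn split is never degenerate.
Two test families exist:

* **SIMPLETHRES** — threshold a single (TRGB) pixel value;
* **DIFFNEIGHBOR** — threshold the difference between a pixel and one of
  its 8 spatial neighbors in the same channel plane (edge pixels have
  fewer neighbors; the neighbor is uniform among those present). Pixel
  differences cancel additive channel shifts even before TRGB does.

The kept test maximizes the normalized Shannon information gain
$2\,I(\text{split};\text{class}) / (H_c + H_s)$ — the customary score for
this family of trees; score ties keep the first-drawn candidate. A node
becomes a leaf when it is class-pure, smaller than `n_min`, or admits no
non-degenerate test. `n_min` is 1 in C mode and 1000 in BAGS mode (the
recommended values for the two regimes). Leaves store raw class counts;
probabilities are formed lazily as counts/total. Leaf identifiers are unique
and contiguous across the ensemble.

Every tree runs in its own deterministic random substream derived from the
ensemble seed, so the same seed always rebuilds the identical ensemble
regardless of scheduling, and models serialize to byte-stable versioned
JSON. Tree induction, propagation and the patch encoder are implemented in
C++ (via Rcpp), as is usual for tree ensembles in R.

### Image-level decisions

* **C mode**: every subwindow is propagated through every tree; the leaf
  class-frequency vectors are averaged over all (subwindow, tree) pairs and
  the image takes the most probable class (argmax, ties broken by class
  order). Test-time subwindows are drawn with the same sampler parameters as
  training.
* **BAGS mode**: the image descriptor is the frequency with which its
  subwindows land in each leaf of each tree, normalized per tree by the
  subwindow count so that each per-tree block sums to one and descriptors
  are comparable across images. Descriptors are classified by a linear SVM
  (cost 1 by default; one-vs-rest with a largest-decision-value rule for
  more than two classes). Normalization per tree is a fixed convention here;
  raw counts differ only by a constant factor at fixed subwindow count.

## The two-tier pipeline

"Dead" and "Chorion" are exclusive classes: a larva in either carries no
other label. Tier one is a single three-class model over
Chorion/Dead/Others trained on the full learning set ("Others" covers
normal larvae and every other defect). Images gated as Dead or Chorion
receive that singleton label set and nothing else runs. Images gated as
Others go to tier two: one balanced binary one-vs-rest model per remaining
vocabulary term, trained after removing all Dead/Chorion images. Balancing
undersamples the majority class to the minority size with a seeded draw.

Two deliberate choices follow the same reasoning a screening lab would use:
"Normal" is a directly trained binary model rather than the complement of
all other calls (the complement accumulates every other model's errors, and
under-calling Normal in controls can void an experiment), and "Up Curved
Tail/Fish" — true whenever either curvature term is — is trained as its own
model rather than derived, matching how the term is scored. Gate misrouting
is accepted as-is at prediction time; there is no second-chance routing.

Because the gate removes images before the binary models see them,
per-defect performance must be scored on the *entire* test set: an image
wrongly gated out is negative for every term, hence a false negative for
each true defect it carries, and an image wrongly gated in is scored by its
binary calls. `aggregate_two_tier_confusion()` applies exactly this
carry-over tally; for every term TP+FP+TN+FN equals the test-set size.

## Hyperparameter tuning

`tune_classifier()` evaluates a grid over mode × subwindow-size-range ×
test-kind by randomized cross-validation: `n_runs` (default 25, the middle
of the customary 5–75 range) random 2/3–1/3 splits, stratified by class,
with the same seeded splits reused across grid points so comparisons are
paired. The best mean held-out accuracy wins, ties going to the earlier
grid row, and a final model is refit on the full balanced sample.

## Dose-response readout

For each concentration $d$ the classified plate yields the survival
fraction $1-$ (Dead fraction) and the teratogenicity response, the fraction
of *surviving* larvae not called Normal. Both response curves are fitted as
four-parameter log-logistic functions of $x = \log_{10} d$:

$$f(x) = c + \frac{u - c}{1 + 10^{\,h (m - x)}}$$

with asymptotes bounded in $[0, 1]$, slope $h$ positive (responses are
modeled as increasing mortality/abnormality, which fixes the label-swap
degeneracy) and kept within a plausibility range (default $[0.05, 5]$,
argument `hill_range`): sparse log-spaced designs often leave the slope
unidentified upward, and an unbounded slope then produces step-like
interpolating fits whose parameter covariance degenerates. The untreated
control is placed at a pseudo-log position two decades below the lowest
dose. LC50 and EC50 are the fitted midpoints
$10^m$; TI = LC50/EC50 holds exactly by construction and its log-scale
standard error is the delta-method combination
$\sqrt{se_{LC50}^2 + se_{EC50}^2}$ of the two independent fits.

The fit is weighted least squares (Levenberg–Marquardt, multiple starts
over slope and midpoint) with binomial weights $n_i / (\tilde p_i (1 -
\tilde p_i))$, $\tilde p_i$ continuity-corrected, and the parameter
covariance is taken *unscaled*, $(J^\top W J)^{-1}$: each observed fraction's
sampling variance is known from its denominator, so the residual mean
square — which would rest on very few degrees of freedom with 6
concentrations and 4 parameters — is not used to rescale it. Concentrations
with no survivors carry no teratogenicity information and are dropped from
that curve; if fewer than four usable points remain the fit is reported
failed while the raw fractions are still returned.

## The synthetic generator

Real screening images cannot ship with the package, so every stage is
validated against a parametric-geometric renderer whose ground truth is
exact by construction: a bright (≈228) background with a mild illumination
gradient and Gaussian noise (σ = 8 by default, in 0–255 intensity units),
and one dark object per image. A larva is a disc-swept parametric spine
with a tapering width profile, yolk-sac ellipse and eye; the phenotype
classes modify it geometrically — distal tail bend down/up (±65 px at the
256 canvas), a whole-body arc for the axis curvature, a 40% shorter tail, a
pale rimmed edema sac, a darkened enlarged necrotic yolk, and 2–4 red blood
spots for hemostasis (blood accumulations genuinely occur anywhere along
the embryo, and several spots make the class separable from Normal by
construction, as the generator's contract requires). "Dead" renders as an
irregular dark necrosed mass and "Chorion" as a ring enclosing a curled
embryo, which exercises the circular-crop branch. Class parameter ranges
are disjoint, so the 11-term vocabulary is separable by design; a small
dark debris distractor is available to test localization robustness.

Synthetic plates draw each embryo's fate from log-logistic curves in dose:
death with midpoint LC50, abnormality among survivors with midpoint EC50,
the defect uniform over the non-lethal classes. The default plate emulates
a caffeine-like compound — LC50 = 6.6 mM, EC50 = 0.13 mM, Hill slopes 2
and 1.5, 25 embryos at each of 6 log-spaced doses (0, 0.04, 0.2, 1, 5,
25 mM) bracketing both midpoints, the plate design a toxicologist would
choose to estimate both endpoints from one run.

What the generator does *not* emulate: optical blur and depth of field,
methylcellulose streaks and reflections, pigmentation variation between
fish, multiple larvae or heavy debris per well, and the label ambiguity of
borderline real phenotypes. Passing tests therefore demonstrate the
correctness and internal consistency of the pipeline — localization
geometry, encoding invariances, tree semantics, gate routing, carry-over
accounting, curve-fit calibration — not field performance on real imagery,
which depends on a lab-specific learning set.

## Problem sizes and numerical choices in the test suite

The shipped tests run the full pipeline at desk scale, chosen so the whole
suite completes in a few minutes: two-tier experiments use 40 training and
20 test images per class at 150 subwindows per image; the localization
study uses 200 images including near-border placements; the dose-response
recovery study refits 100 independently simulated plates at the default
plate design; the hardest two-class separation (the two curvature
phenotypes) is additionally checked at the full 1000-subwindow setting.
Numerical tolerances follow the quantity: exact-arithmetic identities are
asserted at 1e−12, standardization contracts at 1e−9, and stochastic
recoveries at their binomial or fitted-SE bounds.

## Known limitations

* Subwindow classification aggregates weak local votes; defects occupying
  a small image fraction (hemostasis, edema in real imagery) are
  intrinsically harder, and the package inherits that property.
* The linear SVM uses the usual hinge loss of libsvm; no probability
  calibration is provided in BAGS mode (margins only).
* The dose-response module assumes monotone responses; hormetic curves are
  out of scope, and EC50 estimates extrapolated below the lowest tested
  dose carry large (honestly reported) standard errors.
* One fish per well is assumed; multi-larva segmentation is out of scope.
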