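---
title: "Predicting facial trait judgments: models, descriptors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting facial trait judgments: models, descriptors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facetraits)
```

## The scientific question and the modeling frame

Observers assign social trait ratings (dominance, trustworthiness,
attractiveness, ...) to neutral faces quickly and with high inter-rater
agreement. `facetraits` frames the computational side of this phenomenon as
a supervised classification problem: given a face representation, can a
classifier predict whether a face sits in the high or low tail of a trait's
rating distribution? Two representation families are compared under one
protocol — a *structural* descriptor using only landmark geometry, and two
*holistic* descriptors using the full shape-normalized image — so any
performance difference is attributable to the information channel, not the
protocol.

Because the rated face databases used in this literature are distributed on
request only, the package ships a synthetic face generator whose planted
trait signals make the whole pipeline testable end to end with known ground
truth. All empirical statements in this vignette are the ones computed by
the package's test suite and acceptance script.

## The synthetic face model

Faces are drawn from a linear statistical shape model around a fixed
21-landmark template (brows, eye corners, nose, mouth, chin, cheeks, jaw)
in a 64×64 image:

* landmark perturbation = `modes %*% coefficients`, coefficients i.i.d.
  `N(0, mode_sd²)` with `mode_sd = 2` px by default. The five default modes
  are orthonormalized, interpretable directions: eye spacing, mouth width,
  chin drop, face width, brow raise. Extra modes, if configured, are seeded
  random directions orthogonalized against them.
* the image is a deterministic rendering of the landmarks plus two
  appearance latents (skin tone, brow shade): filled polygons/ellipses on a
  shaded oval with light Gaussian smoothing. Appearance is therefore
  coupled to structure — as in real faces — while the latents add an
  appearance-only channel.
* trait scores follow `clip(intercept + Σ w·feature + N(0, noise_sd), 1, 9)`
  over named structural features (mouth width, inter-ocular distance, brow
  height, ...) and appearance features (skin tone, brow shade). The nine
  default specs share features so that a dominance-like group (dominant,
  threatening, mean, frightening: lowered brows, wide face, dark brows) and
  a valence-like group (attractive, trustworthy, competent, extroverted:
  eye spacing, mouth width, skin tone) emerge, giving the trait-space PCA a
  meaningful two-factor structure. `likable` is planted on skin tone only,
  providing an appearance-only contrast trait.

Default scale: 300 faces, matching the size of rated synthetic-face
databases in this literature; rating noise `noise_sd = 0.6` gives planted
signals an R² near 0.8, i.e. strong but not deterministic ratings.

What the generator does **not** emulate: photorealistic texture,
non-frontal pose, landmark marking error, or rater effects beyond additive
Gaussian noise. Consequences worth keeping in mind: (a) descriptors face no
nuisance variation from lighting or identity texture, so absolute
accuracies are optimistic relative to real data; (b) because landmarks are
noiseless functions of the shape modes, geometrically equivalent features
(e.g. the mouth-corner distance and each corner's polar relations) tie in
label correlation — on manually marked data, independent marking noise
would separate them.

## The structural descriptor

With landmarks `p_i` and training-mean positions `m_i`, the descriptor
concatenates: (1) the polar difference of each point to its own mean
position, (2) the polar relation of each face point to *all* mean points
(including `i = j`, making set 1 a redundant but explicit block), and
(3) all within-face distances `‖p_i − p_j‖, i < j`. Length
`2P + 2P² + P(P−1)/2 = 1134` at `P = 21`. Conventions, fixed so feature
indices are stable: angles by `atan2` in image coordinates (y down),
radians in (−π, π], defined 0 at zero radius; set 2 row-major in face point
then mean point; set 3 lexicographic. Every index maps to its landmark set
and kind (radius/angle/distance), which is what the importance analysis
consumes.

The mean shape is recomputed from the training portion inside each CV fold.
The paper-level alternative (a database-wide mean) differs negligibly at
n = 300 but leaks rank information across folds, so the fold-hygienic
choice is used.

## Shape normalization and the holistic descriptors

Holistic descriptors must see appearance, not structure, so each image is
warped until its landmarks coincide with a reference configuration — the
training face minimizing summed distance to the mean shape, which minimizes
the average deformation. The warp is piecewise affine over a Delaunay
triangulation (Bowyer–Watson; a deterministic microscopic jitter resolves
the cocircular degeneracies of the symmetric template) of the reference
landmarks plus 8 border anchors; triangle vertices are interpolated
exactly, so landmarks land on the reference within numerical precision.
The reference is chosen once per dataset rather than per fold: it is a
fixed normalization frame whose choice uses no label information, and
per-fold re-warping would multiply the image-processing cost tenfold.

*EigenFaces*: PCA of the vectorized warped images, retaining the smallest
number of components whose cumulative eigenvalue share reaches 0.95; the
basis is refit on each training fold. *HOG*: central-difference gradients
with replicate padding, unsigned orientations folded to [0°, 180°),
magnitude-weighted 9-bin cell histograms with linear bin interpolation,
8-px cells, 2×2-cell blocks at 1-cell overlap, block-wise L2 normalization
with ε = 1e−6 — 1764 features at 64×64. A constant image maps to the zero
descriptor, and global intensity scaling cancels in the block
normalization.

## The classifier bank and the evaluation protocol

Scores are binarized by rank: top third → class, bottom third → no-class,
middle third discarded (reducing the influence of borderline ratings); ties
break by stable sample order. Features are z-scored with training-fold
statistics — required for the distance- and kernel-based methods on
mixed-unit features. The bank:

* **GentleBoost**, 100 iterations of weighted-least-squares regression
  stumps (exact minimizer found by cumulative-sum scan over all features
  and thresholds), weights updated `w ← w·exp(−y f(x))`; confidence = the
  additive score.
* **SVM-RBF** (via `e1071`), `(C, γ)` tuned by an inner 3-fold grid search
  on the training fold over `C ∈ {1, 10, 100}` × `γ ∈ {0.5, 1, 2}/d`;
  confidence = signed margin.
* **Decision tree** (via `rpart`), cost-complexity pruned at the
  minimum-cross-validated-error subtree; confidence = leaf class posterior.
* **5-NN**, Euclidean, majority vote; distance ties break toward the
  smaller sample index; vote ties cannot occur at odd k; confidence = vote
  share.
* **Parzen + Random Subspace**: 25 random halves of the feature space,
  each classified by a two-class Gaussian product-kernel density comparison
  with per-class, per-feature Silverman bandwidths (floored at 1e−3 on the
  standardized scale); majority vote; confidence = vote share.

Accuracy is estimated by stratified N-fold cross-validation (default
N = 10) and reported with the half-width `t_{(1+level)/2, N−1} · s/√N` of
the Student-t interval on fold accuracies (a z-multiplier is available as a
configuration switch; at N = 10 the difference is ~12% of the width).
Out-of-fold predicted labels are stored — the descriptor-agreement analysis
correlates those, never refit-on-all predictions, so the comparison is
leak-free.

## Second-level analyses

* **Descriptor agreement**: Pearson correlation of two aligned ±1
  out-of-fold label vectors (the phi coefficient); constant vectors are
  reported as 0 with an `undefined` flag.
* **Landmark importance**: features whose |correlation| with the trait
  labels passes a threshold (default: top 5% quantile) each increment the
  count of every landmark they involve — both endpoints for pairwise
  features, since a mean point carries the same anatomical identity as its
  face point — and counts are normalized by their maximum.
* **Angle vs distance share**: the same selection tallied by feature kind.
* **Trait PCA**: eigen-decomposition of the trait correlation matrix on
  continuous scores (the two leading components play the valence/dominance
  role). Binarized scores can be substituted, but continuous scores retain
  more information and are the default.

## Problem sizes and numerical choices

The test suite and acceptance script run at the following sizes, chosen as
the package's study conditions: the planted-signal study uses 300 faces
(→ 200 after binarization, 10-fold CV); the permuted-label null uses 10
replicate datasets of 120 faces; tiny fixtures (10–120 faces) cover unit
properties. Degenerate inputs are handled explicitly: zero-radius polar
angles are 0; constant feature columns correlate 0 (flagged); single-class
training folds raise an error (stratification prevents them); collinear
warp triangles raise an error naming the triangle; out-of-bounds landmark
samples are redrawn at most 10 times before failing.

## Known limitations

Absolute accuracies on synthetic faces are not comparable to accuracies on
rated human-face databases; only the qualitative pattern — joint
learnability by structural and holistic channels, channel-specific traits,
recovery of planted anatomical loci — transfers. The renderer's appearance
space is low-dimensional, which flatters the eigen-decomposition descriptor
relative to richly textured data. The importance maps describe this
pipeline's feature selections, not claims about human perception.
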