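---
title: "Methods: segmentation, descriptors and the neural-network optimizer in lesiondx"
author: "lesiondx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, descriptors and the neural-network optimizer in lesiondx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesiondx)
```

# Overview

`lesiondx` implements a complete computer-aided diagnosis chain for
dermoscopy-style skin-lesion images: noise reduction and contrast
enhancement, region-of-interest (ROI) segmentation by kernel fuzzy C-means
over SLIC superpixels with a spectral-clustering refinement, extraction of
19 shape/intensity/texture descriptors from the ROI, and wrapper feature
selection plus SVM hyperparameter tuning driven by a population
metaheuristic — the neural network algorithm (NNA) and its improved
variant (INNA). Because real dermoscopy archives cannot ship with a
package, a seeded synthetic-data module generates lesion images with exact
ground-truth masks and labelled feature tables; every stage is tested
against those.

# Preprocessing

Noise reduction is a 3×3 median filter (`medianFilterImage()`): each pixel
is replaced by the median of its neighbourhood, which removes
salt-and-pepper impulses while keeping edges. The window is configurable
but larger masks increasingly blur lesion borders. The image border is
handled by edge replication; this choice only affects a 1-pixel frame and
is configurable through padding in the caller.

Contrast enhancement (`stretchContrast()`) maps the observed intensity
range linearly onto the full 8-bit range through a 256-entry lookup table,
`out = round(255 (in - min)/(max - min))` with round-half-up. For RGB
input the stretch is applied to the HSV value channel, rescaling the three
channels by a common per-pixel factor so hue and saturation are untouched
(a per-channel mode exists). A constant image has no range to stretch and
is rejected as degenerate rather than silently returned.

# Segmentation

The ROI chain is:

1. **SLIC superpixels** (`slicSuperpixels()`): localized k-means in
   (L, a, b, row, col) space with distance
   `sqrt(dLab² + (dxy/S)² m²)`, grid spacing `S = sqrt(N/K)` and
   compactness `m = 10`. The default `K = 400` superpixels keeps single
   superpixels well inside either the lesion or the skin at the 128×128
   scale of the synthetic images. Fragments left after the competitive
   assignment are merged into the dominant adjacent superpixel so every
   label is spatially connected.
2. **Color features** (`colorFeatures()`): per superpixel, hue, saturation
   and value histograms quantized to 8, 4 and 2 bins, each block
   normalized to sum to 1 (14 values).
3. **Texture features** (`textureFeatures()`): mean absolute response to a
   zero-mean Gabor bank, 2 wavelengths × 4 orientations. The backend is
   pluggable (`kernels =`) so any multiscale directional decomposition —
   e.g. a nonsubsampled pyramid — can be substituted. Inside
   `segmentLesion()` the texture block is divided by its maximum so it
   lives on the same [0, 1] scale as the histograms. We deliberately do
   **not** z-score columns: near-constant histogram bins would be blown up
   to unit-variance noise dimensions, which empirically destroys the
   cluster geometry, whereas a single global rescaling preserves the
   relative information in each block.
4. **Kernel fuzzy C-means** (`kernelFuzzyCMeans()`): fuzzy clustering with
   the Gaussian kernel `K(x, v) = exp(-||x - v||²/ρ)`. The membership and
   centre updates are the standard kernelized form with fuzzifier `m = 2`:
   memberships proportional to `(1 - K)^{-1/(m-1)}` normalized per sample,
   centres the kernel-weighted means. `ρ` defaults to the median pairwise
   squared distance of the feature table, a scale-free heuristic.
   Iteration stops when the largest membership change drops below `1e-5`
   or after 300 iterations; the objective `2 Σ u^m (1 - K)` is tracked and
   tested to be non-increasing.
5. **Affinity graph** (`buildAffinity()`): pairs that are not t-nearest
   neighbours (t = 10) get weight 0; neighbouring pairs in the same
   hardened cluster get 1; the rest get `exp(-ln2 · xor(u_i, u_j))` with
   the fuzzy XOR defined as the mean over clusters of
   `max(min(a, 1-b), min(1-a, b))`. The *negative* exponent is a design
   decision: the XOR measures dissimilarity (0 for identical crisp
   memberships), so a similarity weight must decrease in it — the
   increasing variant would contradict the same-cluster rule giving 1; it
   remains available behind `flipSign = FALSE`.
6. **Spectral embedding** (`spectralEmbed()`): the symmetric normalization
   `D^{-1/2} W D^{-1/2}` (the one-sided normalization `D^{-1/2} W D^{1/2}`
   is not symmetric and breaks the orthogonal eigenvector machinery), top-k
   eigenvectors, rows normalized to unit length; `ε = 1e-12` is added to
   degrees so isolated nodes cannot divide by zero.
7. **k-means** on the embedding rows (10 restarts, seeded) and mask
   painting. The lesion cluster is the one with lower mean luminance
   (lesions are pigmented and darker than surrounding skin); ties fall
   back to the spatially central cluster, and a `"central"` rule is
   available outright for inverted-polarity material.

# The 19 descriptors

`extractFeatures()` computes geometry from the mask, intensity statistics
from in-mask luminance, and co-occurrence statistics from a masked GLCM
(8 grey levels, four symmetric offsets averaged). Conventions that needed
fixing where the textbook formulas are degenerate or ambiguous:

* **Perimeter** is the Vossepoel–Smeulders corrected length of the traced
  outer contour (`0.980 Ne + 1.406 No − 0.091 Nc` over axial steps,
  diagonal steps and corners); the naive chain-code length overestimates
  smooth boundaries by about 5%, which would bias every perimeter-derived
  descriptor. The raw exposed-edge count is available via
  `perimeterMethod = "edges"`.
* **Irregularity index** is `4π·area/perimeter²` (1 for a circle, smaller
  for ragged borders). **Compactness** as the textbook
  `2·N·π/area` is identically `2π` when area is the pixel count — an
  information-free constant — so the package uses the standard
  `perimeter²/(4π·area)`; the constant variant sits behind
  `printedCompactness = TRUE`.
* **Axes** `a, b` are the full major/minor axis lengths of the
  moment-equivalent ellipse (4√eigenvalues of the mask covariance);
  eccentricity is `sqrt(a² − b²)/a`.
* Two elongation variants are retained under distinct names
  (`elongation_radius` uses the maximal centroid-to-boundary radius,
  `elongation_axis` the major axis) because both appear in the descriptor
  set this package mirrors.
* **Mean/variance/SD** are over in-mask pixels (ROI statistics are what
  feed the classifier); **correlation, entropy, energy** are GLCM
  statistics, since computing a co-occurrence correlation on raw pixel
  intensities is dimensionally meaningless.
* Degenerate masks (under 10 pixels, collinear pixels, zero perimeter)
  raise errors naming the offending descriptor rather than returning NaN.

Invariance properties covered by tests: translation leaves all 19
unchanged; exact 90° rotation leaves the Hu moments φ1–φ3 unchanged to
1e-9; uniform intensity offsets leave the geometric block unchanged.

# The optimizer

Candidate solutions ("patterns") form an `nPop × D` matrix `X`; a square
weight matrix `W` mixes patterns the way a neural layer mixes inputs. One
generation of `nnaOptimize()`:

1. **Mixing**: `Xnew_j = Σ_i W_ij X_i`, `X ← clip(X + Xnew)`. Columns of
   `W` are kept non-negative and summing to one, so each mixed pattern is a
   convex combination — this is the normalization axis that makes the
   update bounded (the row-sum alternative would not constrain the mixing
   that actually happens along columns).
2. **Weight update**: every weight column moves toward the target
   pattern's column, `W_i ← W_i + 2·rand·(W_T − W_i)`, clipped to [0, 1]
   and renormalized. In the improved variant the step is multiplied by the
   **magnitude** of a Lévy draw. The magnitude is deliberate: the factor
   modulates the size of an already-directed step; a signed, zero-mean
   heavy-tailed factor turns the weight contraction into a random walk and
   demonstrably removes the improved variant's advantage on unimodal
   functions.
3. **Operator scheduling**: with probability β the generation is an
   *exploration* generation in which each pattern is bias-perturbed with
   probability γ — `round(D·γ)` coordinates resampled uniformly in the
   box and `round(nPop·γ)` of its weight entries resampled U(0, 1) — and
   every pattern not bias-perturbed moves toward the target by the
   transfer function `X_i ← X_i + 2·rand·(X_T − X_i)`. Scheduling the
   switch per generation rather than per pattern is a deliberate design
   choice: a per-pattern switch keeps a constant fraction of fully
   resampled patterns inside the mixing pool at every generation, which
   injects box-scale noise into every mixed pattern and prevents both the
   weight matrix and the population from ever contracting, while
   per-generation scheduling produces coherent contraction phases
   punctuated by exploration bursts.
4. **Elitism and decay**: the best-ever solution is re-inserted over the
   worst pattern whenever a generation fails to improve, so the recorded
   history is non-increasing; γ and β decay by the factor 0.99 per
   generation from initial value 1.

Lévy steps use Mantegna's algorithm, `step = A/|B|^{1/τ}` with
`A ~ N(0, σ²)`, `B ~ N(0, 1)` and the standard σ(τ) scale (σ ≈ 0.6966 at
the default τ = 1.5); steps are clipped to ±10 to guard against the rare
heavy-tail overflow, and the clip is configurable. The chaotic
initialization fills each weight row with successive iterates of the
logistic map `β' = ρβ(1−β)` at ρ = 4 from a random start in (0, 1).
Bounds are enforced by clipping (the simplest contract consistent with
uniform resampling inside the box), and the bias operator draws its
coordinate indices uniformly over the D dimensions. All randomness comes
from one stream seeded by `config$seed`, drawn in a fixed documented
order, so every run is bit-reproducible.

# Benchmark harness

`evaluateBenchmark()` provides six classic box-constrained test functions
(Rosenbrock, Sum Squares, Step 2, Schwefel 2.22, Schwefel 1.2,
Chung–Reynolds), each vanishing at its canonical minimizer. Rosenbrock is
the classic non-convex form `Σ 100(x_{i+1} − x_i²)² + (x_i − 1)²`; the
variant without the inner square that occasionally appears in print is a
convex quadratic that any optimizer drives to numerical zero and is not a
meaningful test problem. Schwefel 2.22 uses the classic sum *plus*
product of absolute values (the sum-minus-product variant, which does not
have minimum 0, is available behind `printedForm = TRUE`). Step 2 is
`Σ (x_i + 0.5)²` without a floor.

`runStudy()` reports Min/Max/Mean/Std of final best costs over `runs`
independent seeded runs per (algorithm, function) cell; the default study
configuration is population 100, 100 generations, dimension 30, 20 runs.
At this budget (10,100 objective evaluations per run) the 30-D Rosenbrock
means for both variants land in the tens: the exploration decay
0.99^100 ≈ 0.37 still resamples about a third of the coordinates of
gated patterns in the final generation, so runs converge to the
neighbourhood of the origin plateau (f(0) = D − 1 = 29) rather than
crawling far down the banana valley, which demands a longer exploitation
phase than this budget contains. The binding comparative
claim — that the improved variant is at least as good as the base variant
in median on 30-D sum-squares over paired seeds — is asserted in the
acceptance tests at exactly this budget.

# Feature selection, SVM and metrics

The wrapper (`selectFeatures()`) searches `[0, 1]^19` with the improved
optimizer; candidates are thresholded at 0.5 (with an argmax fallback so
the subset is never empty), scored by a linear SVM under stratified
5-fold cross-validation with *pooled* out-of-fold predictions, and the
pooled confusion matrix is summarized by the fitness
`(TP·TN − FP·FN)/((TN+FP)(TP+FP)(TP+FN)(TN+FN))` — an unnormalized
correlation-type score that the optimizer maximizes (it is the quantity
whose square-rooted-denominator cousin is the Matthews correlation; the
product denominator is kept as-is for the selection objective, while the
reported MCC in `evaluateMetrics()` uses the standard square root).
Fitness values are memoized per distinct subset, making a selection run
cost one cross-validation per *unique* subset visited. Folds are a pure
function of the seed and are frozen across all candidates of a run, so
the optimizer compares subsets on identical splits.

`tuneSvm()` searches `log10(C) ∈ [−3, 3]` (plus `log10(γ) ∈ [−4, 1]` for
the RBF kernel) with the same machinery. `trainSvm()` wraps the standard
soft-margin SVM with linear, RBF, polynomial and sigmoid kernels,
z-scoring features on the training data. The pipeline applies one
stratified 80/20 train/test split, seeded, *before* any selection or
tuning, so the held-out metrics are leakage-free.

# Synthetic data

`generateLesion()` renders a radially perturbed ellipse,
`r(θ) = r_ellipse(θ)(1 + Σ_h A_h cos(hθ + φ_h))` with harmonics 2–5 and
equal amplitudes `A_h = irregularity/√n_H`, so the enclosed area is
analytically `πab(1 + irregularity²/2)` to first order — which the tests
verify to 5%. Lesions are dark brown on lighter skin with per-region
Gaussian texture (σ = 6), sensor noise (σ = 5) and 2% salt-and-pepper by
default; optional dark Bézier hair strokes are off by default. A sample
is labelled malignant when the boundary is strongly irregular
(amplitude ≥ 0.12) *and* the ellipse strongly asymmetric (axis ratio
≥ 1.3) — the border-irregularity and asymmetry cues of clinical scoring.
The battery generator draws benign specs from mild ranges
(irregularity 0.02–0.08, ratio ≤ 1.25) and malignant specs from strong
ranges (0.14–0.22, ratio 1.35–1.7).

What the generator does **not** emulate: pigment networks, dots/globules
and other dermoscopic microstructures; multi-lesion scenes; vignetting and
illumination gradients; hair occlusion at realistic density. Passing the
synthetic battery therefore demonstrates that the chain is implemented
correctly and behaves as designed on images with the assumed
figure-ground structure — it does not certify clinical performance on
real dermoscopy archives.

# Problem sizes and numerical choices

The test suite and acceptance battery use sizes chosen to exercise every
code path at desk scale: 128×128 images with 400 superpixels for the
20-lesion segmentation battery; 100-sample/19-feature tables with 2
planted informative features for 20 seeded selection runs; population
100 × 100 generations × dimension 30 × 20 seeds for the optimizer
validation. Key tolerances: weight-column stochasticity and membership
normalization to 1e-9; KFCM stopping at 1e-5 membership change; spectral
oracle agreement to 1e-6; Hu-moment rotation invariance to 1e-9. Ties in
`binarizeSolution()` resolve to the largest coordinate; k-means uses 10
seeded restarts; zero-degree graph nodes receive ε = 1e-12.

# Known limitations

* The lesion/background decision assumes a single dominant pigmented
  region; multi-lesion instance separation is out of scope.
* The Gabor bank is a stand-in surface for any multiscale directional
  texture backend; its two default scales are tuned to the 128-pixel
  synthetic scale and should be re-examined for 768×560 clinical frames.
* The optimizer's exploration decay (0.99 per generation) is calibrated
  to budgets of a few hundred generations; for very long runs a faster
  decay or a floor would be preferable.
* The selection fitness is undefined when a marginal of the confusion
  matrix is empty; it is defined as 0 with a warning, which is the
  conservative choice for degenerate folds.
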