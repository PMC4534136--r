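---
title: "Deriving hybrid color spaces for pixel-wise skin detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving hybrid color spaces for pixel-wise skin detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sknspace)
```

## The problem

Pixel-wise skin detection classifies every pixel of an RGB image as skin or
non-skin from its color alone. Because human skin occupies a compact region
of color space while backgrounds do not, the choice of coordinate system
matters: a representation in which the skin cluster is compact and well
separated from typical backgrounds makes even simple per-pixel classifiers
accurate. Conventional spaces (YCbCr, HSV, CIELAB, normalized RGB, ...) each
capture part of this structure; *hybrid* color spaces combine individual
components from several conventional spaces, and can be tuned to the task.

`sknspace` implements a complete derivation pipeline for such spaces:

1. **Transform**: every image is mapped through seventeen color-space
   transforms (HSI, HSV, LAB, LUV, nRGB, RGB, TSL, XYZ, YCbCr, YCgCr, YES,
   YIQ, YPbPr, YUV, i1i2i3, RIQ, YQCr), yielding a registry of 32 unique
   color components per pixel.
2. **Feature matrix**: pixels become rows of an `n x 32` matrix with 0/1
   skin labels taken from ground-truth masks.
3. **Selection**: a genetic algorithm searches the \(2^{32}\) component
   subsets for the one that maximizes cross-validated skin F-score of a
   random-forest pixel classifier.
4. **Reduction**: the selected components are centered, their covariance
   eigendecomposed, and the leading three principal components become the
   axes of a new 3-dimensional hybrid space.
5. **Evaluation**: pixel classifiers trained in the derived space are scored
   per image (TPR, FPR, precision, F-score, 50-threshold ROC/AUC).

The published end product of this derivation — the **SKN** space — ships as
a canonical built-in ([skn_space()], [rgb_to_skn()]):

\[
\begin{aligned}
S &= 0.088\,g - 58.89\,G - 30.014\,R - 11.952\,B - 7.24\\
K &= 0.62\,g + 14.859\,G + 6.921\,R + 2.122\,B + 1.744\\
N &= 0.342\,g - 3.698\,G - 2.25\,R - 0.103\,B - 0.464
\end{aligned}
\qquad g = \frac{G}{R+G+B}
\]

## Conventions and dialects

**Input scale.** All RGB channels live in \([0,1]\); 8-bit files are divided
by 255 at load. The SKN coefficients' native scale is not fixed by their
source, so the \([0,1]\) convention is a documented package choice — using
0–255 inputs scales the affine terms differently and is not supported.

**Degenerate pixels.** Chromaticities use \(g = 1/3\) at the black pixel
(the achromatic limit), so normalized RGB always sums to exactly 1. Hue is 0
on achromatic pixels for HSI/HSV; TSL's angular component is 0 when its
denominator vanishes; LUV's \(u, v\) are 0 at black.

**Transform dialects.** Where the literature has several variants, the
package fixes one and documents it: BT.601 luma with full-range chroma
centered at 0.5 for YCbCr/YCgCr/YUV/YIQ/YPbPr (the center is an argument of
`color_transform()`); CIE XYZ/LAB/LUV with sRGB primaries, D65 white, 2°
observer, applied to the stored (nonlinear) RGB values — gamma linearization
is deliberately out of scope; Terrillon's TSL; Xerox's YES; Ohta's i1i2i3.
RIQ and YQCr are composed from RGB/YIQ/YCbCr planes.

**The registry.** The default component registry is the published printed
32-name list (`H_HSI` ... `i3_i1i2i3`). That list omits the HSV planes and
`T_TSL`, yet the published optimal subset references `V_HSV`; which
duplicates its authors removed is not fully recoverable. The package
therefore exposes three views without asserting they coincide: the printed
list (default), an extended list appending `V_HSV`, and
`deduplicated_registry()`, which rebuilds the list from all 51 planes by
removing numerically identical columns (it keeps 37 on this package's
dialects — e.g. `CR_YCGCR` duplicates `CR_YCBCR` and is dropped).

Relatedly, the SKN equations are linear in \(R, G, B, g\) while
\(V_{HSV} = \max(R,G,B)\) is not; how the published algebraic simplification
eliminated it is not explained in the source. The package treats the printed
equations as the canonical SKN definition and does not attempt to re-derive
them from the GA + PCA pipeline; both paths are available separately.

## The genetic algorithm

Fitness of a component subset is the skin-class F-score of a 15-tree random
forest under stratified 10-fold cross-validation, averaged over folds; the
error rate is carried alongside. Three design points deserve notice:

* **Fitness subsample.** Benchmarks at the scale this pipeline targets have
  \(10^8\)–\(10^9\) pixels; per-candidate 10-fold cross-validation on that is
  not tractable. Fitness is therefore evaluated on a stratified subsample
  (default 20,000 pixels) drawn **once per run**, so every candidate is
  scored on identical data and fitness is a pure function of the genome.
  `run_ga()` memoizes it per genome.
* **Reproduction.** The source describes both classic GA operators and a
  "Bayesian network formed by the fittest individuals" without reconciling
  them. The package realizes the latter as a univariate marginal
  (UMDA/PBIL-style) model — an edge-free Bayesian network — fit to the top
  `elite_fraction` of the population, and mixes: 1 elite carried unchanged,
  `model_sample_fraction` sampled from the marginals, `random_fraction`
  fresh immigrants, and the remainder via fitness-proportional parents with
  uniform crossover (probability 0.55) and per-bit mutation (0.035;
  per-bit vs per-genome is unstated in the source — per-bit is this
  package's reading).
* **Termination.** Hard cap of 500 generations plus a stall window (default
  100 generations without improvement), mirroring the observed plateau of
  the original search without hardcoding its generation count.

### What the planted-matrix benchmark can and cannot show

The GA is tested on planted matrices: 3 informative columns whose class
means differ by 6 within-class standard deviations, 29 label-independent
noise columns, n = 2,000. At that separation the world is *almost too easy*:
subsets containing only two of the three informative columns already reach
cross-validated F-scores around 0.9994, and — because 10-fold CV on 2,000
pixels resolves fitness only to about \(5\times10^{-4}\) — occasionally
reach exactly 1.0. An elitist best-ever record can then lock onto such a
subset, since nothing can strictly improve on F = 1. A reference
random-forest implementation (scikit-learn) shows the same ceiling, so this
is a property of the stated benchmark, not of this implementation: strict
recovery of all three planted columns in a large majority of seeds is at the
mercy of these ties. The acceptance suite runs the experiment at the stated
scale and reports the outcome honestly; the per-module tests use smaller,
unambiguous configurations.

## PCA numerics

Covariance PCA only (mean centering, no variance scaling), with the sample
covariance (denominator \(n-1\)) eigendecomposed by a symmetric solver on
the \(d \times d\) matrix (\(d \le 32\)); this follows the explicit
covariance path of the derivation rather than an SVD of the data. Because an
eigenvector's sign is arbitrary, each is flipped so its largest-magnitude
entry is positive (ties: lowest index), making serialized spaces
reproducible. Repeated eigenvalues keep the solver's ordering after the
descending sort. `explained_variance()` guards the all-zero spectrum (0/0
is defined as 0). The default output dimension is `k = 3`, following the
published choice of keeping the top three principal components.

## Classifiers

No random-forest, SVM or neural-network package is assumed; the four pixel
classifiers are implemented in the package with the published parameters:

* **Random forest** — 15 Gini trees, bootstrap bagging, \(\sqrt{k}\)
  features per split, unlimited depth. Split search is histogram-based
  (64 quantile bins per feature), the standard trick that keeps thousands
  of wrapper-fitness fits tractable; thresholds are stored as real bin-edge
  values. The skin posterior is the fraction of trees voting skin. Remaining
  settings follow common defaults, as the cited parameter source is not
  reproduced in the original text.
* **Kernel naive Bayes** — per-feature FFT kernel densities (Gaussian
  kernel, Silverman bandwidth) on a class-stratified subsample (default
  5,000/class), interpolated in log space at prediction time; skin color is
  not Gaussian, hence the kernel estimate.
* **SVM** — polynomial kernel of degree 3, complexity \(C = 1\), tolerance
  0.001, round-off epsilon \(10^{-12}\). The dual is solved with `quadprog`
  on a stratified subsample (default 500/class; the dense solver is cubic in
  the sample count). Posteriors come from Platt-style sigmoid calibration on
  a held-out quarter of the training subsample; an uncalibrated
  single-threshold decision value is what the calibration wraps.
* **MLP** — five layers: input(k), three tanh hidden layers, softmax(2).
  Hidden width is `round((k + 2) / 2)` — the rounded mean of input and
  output sizes; the formula yields 2.5 for k = 3 and the package rounds
  half up to 3. Full-batch Adam with early stopping on a validation split.

Features are standardized inside the SVM and MLP fits (stored with the
model); the forest and the KDE are scale-equivariant as implemented.

## Evaluation policies

Confusion counts are per image; metrics follow the standard definitions
(TPR = TP/N_S, FPR = FP/N_NS, precision = TP/(TP+FP), F = 2TP/(2TP+FP+FN)).
Averages over a test set are **image-weighted** (unweighted mean of
per-image metrics), matching the stated protocol. Zero denominators follow a
fixed policy: an image with no skin pixels contributes no TPR/F-score terms
(exclusions are counted in the result's `n_used` attribute rather than
fabricated from 0/0), and precision is 0 when nothing was predicted
positive. ROC curves use 50 equally spaced thresholds on \([0,1]\) inclusive
(spacing unstated in the source; equal spacing is the package's choice), and
AUC is the trapezoidal integral over (FPR, TPR) with (0,0) and (1,1)
anchors. Error overlays color false negatives red, false positives blue,
true negatives white, and keep true positives in their original colors.

## The synthetic world

Real skin-detection benchmarks are licensed externally, so the package ships
a seeded scene generator whose structure mirrors them: elliptical "skin"
regions whose colors are drawn from a compact Gaussian cluster in the
(Cb, Cr) chroma plane — centered at (0.42, 0.58) with standard deviation
0.02, inside the classic skin locus — over heterogeneous backgrounds, with
hard-rasterized (never anti-aliased) masks so the ground truth is exact.
Defaults: 128 x 128 scenes, 3 regions, target skin fraction 0.25 (real
benchmarks run roughly 17–29% skin pixels), placement retried until the
achieved fraction is within ±0.1 of target.

Three background regimes: `textured` (smooth luma gradients colorized with a
chroma at least 0.15 away from the skin-cluster mean) is the default and
constitutes the *separable* world that end-to-end tests assume;
`uniform_noise` draws iid random colors; `skin_like_distractor` adds patches
whose chroma approaches the cluster, exercising false positives the way
skin-like furniture and sand do in real scenes.

What a green end-to-end test establishes is therefore limited: the pipeline
wiring, determinism, and that a classifier in SKN space separates a
compact-chroma world. It does **not** establish robustness to illumination
variation, shading gradients across a face, camera transfer curves, or
ethnic skin-tone diversity — none of which the generator models. The
published real-data numbers (average F-score/TPR 0.953, FPR 0.0482 with the
random forest) are quoted here only as context; nothing in this package
recomputes them.

## Reproducibility

Every stochastic stage draws from a named substream derived from one master
seed (`derive_seed(seed, "ga")`, `"split"`, `"synth"`, ...), so stages are
independently reproducible and library calls never disturb the caller's RNG
state. The random forest uses its own splitmix64 generator, making fits
bit-reproducible across platforms. Identical seed + config + data reproduce
GA histories, trained forests, masks and serialized JSON artifacts exactly;
this is asserted by the determinism tests.

## Known limitations

* Transform dialects are reasonable defaults, not a claim about the exact
  formulas the original derivation used (its formula table is external).
* The SVM subsample cap (for the cubic QP solver) means very large training
  sets are represented by at most `2 * max_per_class` pixels.
* The scene generator's color model is piecewise-constant-plus-noise; no
  photometric realism is attempted.
* Only binary (skin / non-skin) classification is supported.
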