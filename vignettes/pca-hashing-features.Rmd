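---
title: "Two-stage PCA-filter hashing features for imbalanced image classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage PCA-filter hashing features for imbalanced image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PCAHashNet)
```

## The model

PCAHashNet implements a two-stage convolutional feature extractor in the
PCANet family, followed by a hashing/pooling layer and a class-weighted
linear SVM protocol for two-class problems with strong class imbalance
(the motivating application is tongue-image screening, where abnormal
cases outnumber normal ones roughly 85:15).

**Filter learning.** All overlapping $s_1 \times s_2$ patches (stride 1)
are collected from every training image, each patch has its own mean
subtracted, and the patches are pooled into one matrix $T$. The stage-1
filter bank is the top $V_1$ eigenvectors of the scatter matrix
$T T^\top / (N p V_1)$, reshaped back to $s_1 \times s_2$ kernels. The
scalar prefactor is applied for fidelity to the learning rule as usually
written, but eigenvectors are invariant to positive rescaling, so it has
no effect on the filters; a unit test asserts this. Stage 2 repeats the
construction on the pooled patches of all $N V_1$ stage-1 output maps.

**Cascade.** Each image is zero-padded by
$\lfloor s_1/2 \rfloor, \lfloor s_2/2 \rfloor$ and convolved (correlation
convention) with every kernel; per-patch mean removal is applied at
convolution time too, so each output pixel is the projection of the
mean-removed local patch onto an eigenfilter, squashed by $\tanh$. The
padded ring takes part in the patch mean like any pixel. After each
convolution an elementwise nonlinear transform makes responses positive:
$a = 1$ selects the smoothed absolute value $\sqrt{\varepsilon + C^2}$,
$a = 0$ the softplus $\log(1 + e^C)$ (evaluated in its overflow-safe
form). Stage 2 convolves every stage-1 map with all $V_2$ stage-2
kernels, so an image yields $V_1 V_2$ maps, each of the input's size.

**Pooling.** For each stage-2 filter $j$, the $V_1$ maps that share it
are binarised by a strict Heaviside step and combined pixelwise into an
integer word $\sum_k 2^{k-1} B_k \in [0, 255]$ for $V_1 = 8$. Each word
image is min–max rescaled to $[0, 255]$ (per map, rounding half away
from zero; a constant map becomes all zeros), then summarised by a
spatial pyramid: at level $l = 0 \ldots L$ the map is split into a
$2^l \times 2^l$ cell grid and each cell contributes a 256-bin word
histogram, giving $G = \sum_l 4^l$ cells (21 at $L = 2$). Each per-filter
feature is rescaled to a fixed Euclidean norm $\sigma$ ("high
dispersal"), normalised across neighbouring filter maps by local response
normalization
$\bar f_j = \tilde f_j / (\gamma + \alpha \sum_{j' \in W(j)} \tilde f_{j'}^2)^\beta$
with a window of $n$ maps, and concatenated: $V_2 \cdot G \cdot 256 =
43008$ features at the defaults.

**Classifier.** A linear SVM with per-class misclassification weights
(majority weight 1, minority weight swept over 1..9), evaluated by
repeated stratified k-fold cross-validation (default 10 rounds of
5-fold). Reported metrics are ACC/SEN/SPE/PPV/NPV/F1 with abnormal
(label 1) as the positive class, plus a balance metric $g$ of
sensitivity and specificity.

## Parameters

| parameter | default | meaning |
|---|---|---|
| $\varepsilon$ | $10^{-8}$ | smoothing of the absolute-value transform (dimensionless) |
| $a$ | 1 | transform selector: 1 = smoothed abs, 0 = softplus |
| $\gamma, \alpha, \beta$ | 2, $10^{-4}$, 0.75 | LRN offset, scale and exponent |
| $\sigma$ | 2.238 | target norm of each dispersed per-filter feature |
| $n$ | 5 | LRN window width in filter maps |
| $V_1, V_2$ | 8, 8 | filters per stage (8 bits per hashed word) |
| $s_1 \times s_2$ | $5 \times 5$ | filter size (odd, for a defined centre) |
| $L$ | 2 | pyramid depth, $G = 21$ cells |
| working size | $32 \times 32$ | network input after resizing |

The grid-search helper (`gridSearchHyperParams`) searches the customary
ranges: $\varepsilon$ over decades $10^{-10}..1$, $a \in \{0,1\}$,
$\gamma \in \{0,2,\dots,10\}$, $\alpha$ over decades $10^{-6}..10^2$,
$\beta \in \{0, 0.25, \dots, 1\}$, $\sigma = 315t/84$ for
$t \in \{0.59, 0.60\}$, and the LRN window on an integer grid. Only the
step of the window grid is conventionally stated, not its range; this
package uses 1..9, symmetric around the default 5. Note that the
$\sigma$ grid cannot produce the default 2.238 (it yields 2.2125 or
2.25); the printed default is adopted verbatim and the generating
formula is kept only as the documented search range.

## Design choices at genuinely open points

* **Heaviside source.** Binarising the post-transform maps would be
  degenerate: both transform branches are strictly positive, so every
  bit would be 1 and every word 255. The default therefore binarises the
  pre-transform tanh convolution maps at zero (the PCANet convention);
  `binarizeSource = "nt_centered"` instead thresholds the post-transform
  map at its own mean, for users who want the transform inside the
  hashing path.
* **Pyramid cell count.** The feature-length contract 43008
  $= 8 \times G \times 256$ forces $G = 21 = \sum_{l \le 2} 4^l$, i.e. a
  standard $2^l \times 2^l$ spatial pyramid (a $\sum 2^l$ reading would
  give $G = 7$ and 14336 features).
* **High dispersal.** Implemented as division by the Euclidean norm,
  which gives the testable fixed-norm property ("dispersal to norm
  $\sigma$"); dividing by the bare sum of squares is available via
  `hdSqrt = FALSE`.
* **Balance metric.** `balanceMetric` defaults to the product
  sen $\times$ spe, which is what reference class-weight tables of this
  protocol tabulate; the square-root form (the usual g-mean) is one
  argument away. The product is never larger than the g-mean.
* **Single channel, working size.** The pipeline is single-channel;
  colour rasters are reduced with ITU-R 601 luma weights
  (0.299, 0.587, 0.114). The network consumes $32 \times 32$ inputs;
  larger "normalised" sizes sometimes quoted for display are treated as
  presentation artifacts.
* **Conventions frozen for reproducibility.** Patch corners and patch
  flattening are row-major; eigenvector signs are fixed so the
  largest-magnitude entry is positive (ties by earliest row-major
  index); numerically tied eigenvalues are ordered by the lexicographic
  order of their sign-fixed vectors; min–max rescaling rounds half away
  from zero; rescale statistics are per map and per image, never
  dataset-global; prediction at decision value exactly 0 goes to the
  positive (abnormal) class; grid-search ties keep the first point in
  grid order.

## Degenerate inputs

Constant images are handled end to end without error: mean removal
annihilates them, all words hash to 0, the constant-map rescale guard
returns zeros, and the all-zero feature passes through dispersal
unchanged. Filter learning on all-constant patches has no principal
directions and fails with an explicit error. Metrics with zero
denominators (e.g. specificity when no negatives are evaluated) are
reported as `NA`, never silently 0.

## The synthetic-image generator

Clinical tongue datasets are private, so `generateDataset` emulates the
study conditions: 48 normal and 267 abnormal images by default (15.2%
minority). Each image is an elliptical bright "tongue body" (centre,
axes and rotation mildly jittered; the body fills most of the frame, as
a segmented bounding-box crop does) on a flat dark background, playing
the role of the region outside a segmentation mask. Both classes carry a
Gaussian-correlated intensity texture (amplitude 30, correlation length
`size/6.4` so the apparent grain survives resizing to the working size)
plus pixel noise on the body. Class 1 differs in two contrast-scaled
ways: its texture correlation length shrinks by $1/(1+\text{contrast})$
(finer grain, like a coated surface) and it receives high-frequency
coating spots ($3 \times 3$, amplitude $\min(60\,\text{contrast}, 100)$,
density $0.03\,\text{contrast}$ per body pixel). At `contrast = 0` the
class-1 generative path reduces exactly to the class-0 one, so the
class-conditional distributions coincide — the null case used to check
that the pipeline does not hallucinate signal.

These correlation-length and spot scales were chosen once, to place the
class difference at the spatial scale the $5 \times 5$ eigenfilters
resolve at the $32 \times 32$ working size; a texture contrast much
smoother than the filter scale is nearly invisible to word histograms.

What passing the synthetic benchmarks does **not** show: the generator
has no colour, no illumination gradients, no specular highlights, no
segmentation errors and no label noise, and its class difference is a
single texture axis. Results on it demonstrate that the implementation
recovers planted texture signal under the study's imbalance, not that
the method reaches any particular clinical accuracy.

## Problem sizes used in the test suite

The end-to-end checks run on 15 normal + 85 abnormal images generated
directly at $32 \times 32$ (keeping the study's minority fraction), with
banks learned on a 50-image subset and 2 rounds of stratified 5-fold
cross-validation; high contrast is `contrast = 4`, the null case
`contrast = 0`, and the weight-monotonicity check runs at
`contrast = 2`, where weighting genuinely changes the operating point.
The full 48/267, 10-round protocol is the package default and runs in a
few minutes on one core.

## Known limitations

* Exactly two cascade stages; stride is fixed at 1.
* $V_1 > 8$ would exceed the 256-word alphabet (the hash exponent wraps
  at 256 by construction, but the histograms assume 256 bins).
* The SVM wraps `e1071::svm` (libsvm); with many more samples a
  dedicated linear solver would be preferable.
* Tongue segmentation, colour-space transforms and illumination
  correction are out of scope; inputs are assumed to be already-masked
  single-channel crops.
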