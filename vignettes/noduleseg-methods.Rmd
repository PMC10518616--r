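---
title: "Methods: lung-nodule segmentation with cuckoo-search thresholding and an encoder-decoder network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lung-nodule segmentation with cuckoo-search thresholding and an encoder-decoder network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`noduleseg` implements a complete 2-D lung-nodule segmentation pipeline for
CT slices, together with the synthetic study material needed to validate
every stage against exact ground truth. This vignette is the package's own
account of the science: the models, the parameters that matter, the
numerical choices, and what the validation on phantoms does and does not
establish about real data.

## The segmentation problem

A lung nodule appears on an axial CT slice as a small, roughly circular
bright blob inside the dark air-filled lung fields, which are themselves
surrounded by brighter body tissue. Segmentation means producing a binary
per-pixel mask $S$ comparable to a gold-standard mask $G$. The package
offers two segmenters over a shared preprocessing front end:

* a *threshold path*: multilevel Otsu thresholding whose cut points are
  selected by a cuckoo-search metaheuristic, followed by connected-component
  filtering; and
* a *network path*: a SegNet-style convolutional encoder-decoder trained by
  backpropagation, which reuses the encoder's max-pooling argmax indices to
  unpool in the decoder.

Both paths are exposed by the CLI (`segment-csa`, `train`/`infer`); neither
is privileged, and the evaluation module treats them identically.

## Preprocessing

Intensities are first brought onto a common $[0,1]$ scale with the min-max
map $\bar\mu = (\mu - \mu_{\min})/(\mu_{\max} - \mu_{\min})$; Hounsfield
inputs are first windowed to a configurable range (default $[-1000, 400]$,
standard lung windowing — the windowing choice is ours, as CT calibration
handling is site-specific). Slices are resized to the $128 \times 128$
working resolution by separable bilinear interpolation with pixel-centre
alignment and edge clamping. Noise is tempered by *clip-weighted histogram
equalization*: the 256-bin histogram counts are clipped at `weight_clip`
(default 3) times the uniform bin count before the CDF remapping, which
limits the noise amplification of classical equalization;
`weight_clip = Inf` recovers the classical method, and the mapping is
monotone in the input value either way. Finally a fixed $3\times3$
edge-enhancement kernel
$$\begin{pmatrix}-1&0&-1\\0&5&0\\-1&0&-1\end{pmatrix}$$
is correlated over the image with reflect padding. Its weights sum to 1, so
flat regions are untouched while nodule boundaries are sharpened; because
the kernel is symmetric under a half-turn, correlation and convolution
coincide. The stage order (normalize, resize, equalize, edge) is a package
choice — the relative order of equalization and edge enhancement is not
dictated by the method, and each stage can be toggled in the configuration.

Luma/chroma (YUV, BT.601) conversion with 2x chroma downsampling is
provided for color inputs. For single-channel CT a grayscale-to-RGB-to-YUV
round trip would be a no-op, so the default grayscale path skips it.

## Multilevel Otsu thresholding by cuckoo search

For a gray-level histogram with $L$ levels, probabilities $p_\ell$ and
global mean $\mu$, a threshold vector $t_1 < \dots < t_k$ partitions the
levels into $k+1$ half-open classes $[t_c, t_{c+1})$. The fitness of a
candidate is the **between-class variance**
$$\sigma_B^2(t) = \sum_c \omega_c (\mu_c - \mu)^2,$$
with $\omega_c$ and $\mu_c$ the class mass and mean. Maximizing
$\sigma_B^2$ is the multilevel Otsu criterion: since
$\sigma_B^2 + \sigma_W^2 = \sigma^2$ (a decomposition the tests verify to
$10^{-9}$), it equivalently minimizes the pooled within-class variance, and
a larger value means a wider gap between the intensity populations. The
objective is evaluated in $O(k)$ from prefix sums of $p_\ell$ and
$\ell\,p_\ell$.

**Cuckoo search (CSA).** Candidate threshold vectors are "eggs in nests".
Each generation, every nest $m^s_j$ proposes
$m^{s+1}_j = m^s_j + \sigma \odot \mathrm{Levy}(\delta)$, with $\odot$
entry-wise multiplication; the proposal replaces a *randomly chosen* nest
when its fitness is higher; the worst $\lceil Q\,m\rceil$ nests are
abandoned and re-initialized uniformly at random; and the best solution
ever seen is retained (elitism), so the best-fitness trace is
non-decreasing by construction. Defaults: $m = 25$ nests, discovery
fraction $Q = 0.25$, $N = 100$ generations with early stop after 25
stagnant generations, step scale $\sigma = 10$ gray levels, and $k = 2$
thresholds for CT slices (background / lung / nodule).

*Levy steps.* Heavy-tailed steps are drawn by Mantegna's method with
stability index $\alpha = \delta - 1$, mapping the exponent range
$1 < \delta \le 3$ onto the valid stability range $(0, 2]$; the default
$\delta = 2.5$ gives the $\alpha = 1.5$ flight commonly used with cuckoo
search, and $\delta = 3$ is handled exactly as the Gaussian limit (where
Mantegna's $\sigma_u$ formula degenerates). Occasional large jumps let the
population escape local optima while most steps refine locally.

*Solution repair.* Real-valued proposals are rounded, clipped to
$[1, L-1]$, sorted, and de-duplicated by nudging, so every evaluated
candidate is a valid strictly-increasing integer vector. Ties between
equal-fitness candidates are broken toward the lexicographically smallest
vector, which makes every run deterministic under a fixed seed.

*Validation.* `exhaustive_otsu()` enumerates the global optimum (any $L$
for $k \le 2$; $L \le 16$ otherwise) and serves as the oracle: under the
suite's conditions the optimizer attains the exhaustive single-threshold
optimum and reaches $\ge 0.999$ of the two-threshold optimum on tri-modal
histograms in at least 99% and 95% of seeded runs respectively.

*Mask extraction.* The highest-intensity class of the thresholded label map
is taken as the nodule candidate; 8-connected components smaller than
`min_area` (default 4 px) are discarded, which removes residual salt noise
while keeping any plausible nodule.

## The encoder-decoder network

The network performs pixel-wise two-class (front/background)
classification. The encoder stacks blocks of $3\times3$ convolution +
batch normalization + ELU, each block ending in $2\times2$ stride-2 max
pooling whose per-window argmax indices are stored. The decoder mirrors
the encoder: *index unpooling* places each pooled activation back at its
recorded argmax position (zeros elsewhere) before deconvolution, so edge
localization survives upsampling without learned upsampling weights — the
decisive parameter saving of this architecture family. The `vgg19` preset
uses the full VGG-19 convolutional layout (16 conv layers, 5 pooling
stages) mirrored by 16 deconvolution layers; the `tiny` preset (2 blocks,
8/16 channels) is the same design at validation scale. A $1\times1$
convolution maps to the class channels and a log-sum-exp-stabilized
softmax yields per-pixel probabilities.

The ELU activation is $f(i) = i$ for $i > 0$ and $\beta(e^i - 1)$
otherwise ($\beta > 0$, default 1): continuous at zero, saturating at
$-\beta$, with the convenient derivative identity $f'(i) = f(i) + \beta$
on the negative branch (verified against finite differences in the
tests). Dropout (rate 0.5) is applied after the deepest encoder and
decoder stages at training time only; inference is deterministic.

**Objective and training.** The loss is the mean per-pixel cross-entropy
between the softmax output and the one-hot target, plus a weight penalty
$\tfrac{\chi}{2}\sum \psi^2$ over the convolution weights (default
$\chi = 10^{-4}$; $\chi = 0$ disables it). Optimization is Adam with
learning rate $10^{-3}$ and batch size 4 — the method itself does not fix
an optimizer, and these are robust defaults for small networks. Batch
normalization keeps running averages (momentum 0.9) for inference. All
randomness (initialization, shuffling, dropout) flows through a single
seed, so training is bit-reproducible. Every gradient is hand-derived and
checked against central differences (relative error below $10^{-4}$ at
step $10^{-4}$; observed around $10^{-8}$).

Two numerical conventions worth noting: pooling ties resolve to the first
window position in row-major order, and inference ties (probability
exactly $1/2$) resolve to background, so an uninformative network predicts
an empty mask rather than a full one.

## Texture features and classification

The local binary pattern (LBP) code at a pixel thresholds a ring of $n$
neighbors (radius $r$, angle origin east, counter-clockwise, bilinear
interpolation off-grid) against the centre value $q_d$:
$$\mathrm{LBP} = \sum_{t=0}^{n-1} s(q_t - q_d)\,2^t, \qquad
s(v) = \begin{cases}1 & v \ge 0\\ 0 & v < 0\end{cases}.$$
Ties count as 1 — the printed rule is followed even though some classical
LBP variants use strict inequality — so a perfectly flat neighborhood
codes to $2^n - 1$. Codes are pooled into per-cell histograms of $2^n$
bins ($grid\times grid$ cells, default one cell), restricted to the
segmented region when a mask is supplied. Histograms are *not* normalized
by default, so the coded-pixel count — and hence region size — remains in
the descriptor; LBP codes themselves are invariant to constant intensity
shifts, and a 90-degree image rotation permutes codes by a two-bit
rotation (both properties are tested).

Two classifiers consume the descriptors. The *sign-unit* mode implements
the hard threshold unit: weights constrained to $\{-1, +1\}$, bias fixed
at 1, decision $\hat y = 1 \iff \sum_j w_j x_j + 1 \ge 0$ (the $\ge$
boundary goes to class 1). Training runs perceptron updates on real-valued
shadow weights and projects to signs after each epoch. The *logistic* mode
is the practical default: L2-penalized logistic regression via glmnet
ridge ($\lambda = 10^{-2}$), chosen because LBP descriptors have $2^n$
dimensions — usually more than the number of training images — where an
unpenalized maximum-likelihood fit is rank-deficient and separable.

## Synthetic phantoms: what they emulate, and what they do not

No public CT cohort ships with this package; all validation runs on
generated phantoms with exact ground truth. A phantom is a tri-modal
$128\times128$ slice: a bright "body" background, two dark elliptical lung
fields (centred at 30% and 70% of the width, spanning 64% of the height),
and zero or more bright circular nodules placed by rejection sampling so
that every nodule pixel lies inside a lung field. Additive Gaussian noise
(default $\sigma = 0.03$) is clipped to $[0,1]$.

Default intensity means are lung 0.10, background 0.50, nodule 0.95. The
ordering lung < background < nodule makes the histogram tri-modal; the
specific values were chosen so the two inter-mode gaps are comparable
(0.40 and 0.45), which keeps the $k=2$ Otsu objective well-posed even for
the smallest admissible nodules. This matters: a nodule of radius 3 px
occupies under 0.2% of the image, and with a materially smaller
nodule/background gap the variance objective provably prefers splitting
the broad body mode over isolating the nodule mode — the thresholding
problem itself, not the optimizer, becomes ill-posed. Nodule radii are
drawn uniformly from $[3, 9]$ px (the radius is drawn once and only the
position is re-sampled on placement rejection, keeping the radius
distribution uniform). The default label rule proxies malignancy by size:
label 1 when any nodule radius reaches 6 px, which yields roughly balanced
classes under the default radius range; a pure presence rule is also
available, under which label 1 is exactly equivalent to a non-empty mask.

What passing on phantoms shows: the optimizer finds global optima of its
objective; the network can represent and learn the segmentation map; the
metrics and their identities are computed correctly; the whole pipeline is
deterministic under seeds. What it does not show: performance on real CT,
where nodules are not homogeneous discs, lung fields contain vessels and
airways of nodule-like intensity, tissue textures are structured rather
than Gaussian, and scanner calibration varies. In real slices the
intensity separation that makes thresholding exact here largely collapses,
and the network path (or substantial post-processing of the threshold
path) carries the burden. Phantom results are a correctness floor, not a
clinical claim.

## Evaluation

Per-image metrics: signed volume error $VE = 2(S-G)/(S+G)$ on
positive-pixel counts (reported as $|VE|\times100$ percent), Dice
$2|G\cap S|/(|G|+|S|)$ and Jaccard $|G\cap S|/|G\cup S|$ (related by
$DSC = 2\,JSS/(1+JSS)$, with $JSS \le DSC$ always). Degenerate pairs use
fixed conventions, flagged by warnings: both masks empty gives $DSC = JSS
= 1$ and $VE = 0$. Classification adds accuracy $s/m \times 100$ and
$F1 = T_+ / (T_+ + \tfrac12(F_+ + F_-))$, the harmonic mean of precision
and recall. Aggregates are mean ± *population* standard deviation. The
cross-validation harness builds seeded balanced partitions (fold sizes
differ by at most one); both a 70/30 split and k-fold plans are
expressible, with 10 folds as the configuration default. The left/right
ventilation imbalance coefficient $(L-R)/(L+R)$ ships as a standalone
physiological utility; it has no role in the segmentation pipeline.

Per-item wall-clock time is logged in reports for information only; it is
hardware-dependent and never an acceptance quantity.

## Problem sizes used in validation

The shipped validation suite works at deliberately modest scale, chosen so
the full pipeline — including network training — exercises every code path
on a single CPU: the optimizer oracle comparisons use 100 seeded runs each
of $k=1$ (random histograms) and $k=2$ (phantom histograms); the network
contracts run on the `tiny` preset at $32\times32$ with a 16-phantom
200-epoch overfit run; the end-to-end threshold path is scored on 50 noisy
phantoms; the classifier on 100 phantoms under 5-fold cross-validation.
The `vgg19` preset is constructed and run forward at the full
$128\times128$ working resolution to validate shapes and plumbing, but is
not trained in the suite — training a 40-million-parameter network is a
GPU-scale undertaking out of scope for a correctness suite, and phantom
discs would not exercise its capacity meaningfully anyway.

## Known limitations

* The threshold path assumes the nodule class is the brightest; calcified
  or cavitated nodules and contrast-enhanced vessels violate this on real
  data.
* Phantom nodules are homogeneous discs; texture features learn size and
  boundary statistics, not the internal heterogeneity radiologists use.
* The package is 2-D throughout; volumetric (3-D) context is out of scope.
* The sign-unit classifier is a faithful implementation of a very rigid
  decision rule; it is provided for completeness, with logistic mode as
  the recommended default.
* DICOM support covers single-frame explicit-VR little-endian monochrome
  objects — the common case for CT slice exports — and rejects everything
  else loudly rather than guessing.
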