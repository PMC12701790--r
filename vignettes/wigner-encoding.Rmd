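---
title: "Wigner-Ville image encodings for feature-vector classification"
author: "wvdimage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wigner-Ville image encodings for feature-vector classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wvdimage)
```

## The problem

Much of molecular-biology machine learning starts from a fixed-length
real-valued feature vector per sample: a protein-language-model embedding of a
peptide (a few hundred dimensions), physicochemical descriptors of an
aptamer-protein pair, or k-mer-derived features of a DNA barcode (thousands of
dimensions). Support vector machines remain a strong default on such tables.
Convolutional networks, by contrast, expect images - but they bring powerful
inductive biases and pretrained weights if the vector can be turned into one.

`wvdimage` implements a vector-to-image route built on time-frequency
analysis: treat the feature vector as a discrete signal, compute a smoothed
pseudo Wigner-Ville distribution (SWVD) three times with three randomly drawn
Kaiser window sizes, and stack the three magnitude matrices as the RGB
channels of an image. An ensemble of image classifiers is trained on such
encodings - each member seeing its own feature permutation and its own window
draw - and the averaged ensemble scores are finally fused with an optimized
SVM via a z-normalized weighted mean rule.

## The time-frequency core

For a discrete signal $x(1),\dots,x(N)$ the package forms the instantaneous
autocorrelation over integer lags,

$$A(n, m) = x(n+m)\,x(n-m), \qquad m = -(N-1), \dots, N-1,$$

with out-of-range indices contributing zero (feature vectors are not
periodic, so no wrap-around). The plain Wigner-Ville distribution is the DFT
of the lag axis,

$$\mathrm{WVD}(n, k) = \sum_m A(n, m)\, e^{-2\pi i k m / N},$$

which is real because $A$ is even in $m$. The smoothed variant applies two
independent windows before the transform: a centred, unit-sum time window $g$
(a weighted moving average over $n$) and a lag window $H$ that multiplies
$A(n, \cdot)$ at centred lags - equivalently a smoothing of the frequency
axis. The package returns the point-wise absolute value of the result, so
every entry of an encoded channel is nonnegative.

Numerical conventions, all asserted by tests:

* **Frequency axis.** The lag variable advances the signal by two samples per
  unit, so bin $k$ corresponds to normalized frequency $k/2N$
  cycles/sample: a sinusoid occupying signal-DFT bin $k_0$ concentrates at
  time-frequency bin $2 k_0$. `tfArgmaxBins()` reads localization off the
  positive-frequency half excluding DC, because the WVD of a *real* signal
  carries a known interference line at DC (between its positive- and
  negative-frequency components) that oscillates in time. Plain-WVD
  localization is best read from the analytic signal (`analytic = TRUE`);
  the smoothed transform suppresses the oscillating line by time-averaging,
  which is precisely why smoothing is used.
* **Marginal.** Summing a plain WVD over frequency bins returns
  $N\,x(n)^2$ at each time - the constant is exactly $N$ under this
  convention.
* **Windows.** Kaiser windows with shape $\beta$ (default $0.5$,
  configurable; $\beta = 0$ is rectangular). Even window sizes are bumped to
  the next odd integer so the window has a centre sample. Windows longer
  than the signal are rejected.
* **Imaginary residue.** The lag DFT of a symmetric lag array must be real;
  a relative imaginary residue above $10^{-9}$ raises an error rather than
  being silently discarded.
* **Degenerate smoothing.** A size-1 time window and an all-ones lag window
  spanning the full support reduce the SWVD to $|\mathrm{WVD}|$ exactly
  (time smoothing is a convolution, so only the trivial window is the
  identity there).

## The Wigner encoder

`encodeWigner()` draws the three channel window sizes as

$$M_1 \sim U(0.3N, 0.5N), \quad M_2 \sim U(0.5N, 0.7N), \quad
  M_3 \sim U(0.7N, 0.9N),$$

rounded to the nearest odd integer (ties upward), which guarantees
$M_1 \le M_2 \le M_3$. Channel $i$ uses a Kaiser window of size $M_i$ for
*both* the time and the frequency window. The increasing sizes deliberately
break the symmetry between two ensemble members that would otherwise differ
only by a swap of window sizes, enhancing member diversity; `sampleWindowSizes()`
is a pure function of `(N, seed)` so every draw is replayable.

Long vectors (the DNA-barcoding regime, thousands of features) go through
`quadrantCompose()`: the vector is zero-padded to a multiple of four, split
into four equal contiguous segments, each segment is encoded independently,
and the four $N_s \times N_s \times 3$ outputs are tiled as the quadrants of
one $(2N_s) \times (2N_s) \times 3$ composite in reading order (top-left,
top-right, bottom-left, bottom-right). The order is arbitrary but fixed;
determinism is what matters. By default each segment draws its own window
triple (`share_windows = TRUE` shares one).

### Baseline encoders

Three reference encoders share the interface; they are parameterized,
documented variants rather than replicas of any particular implementation:

* `encodeReshape()` - zero-pad to the next perfect square, fill row-major,
  replicate to three channels. A bijection up to padding.
* `encodeCwt()` - Morlet magnitude scalogram over $L$ log-spaced scales;
  the three channels use centre frequencies $\omega_0 \in \{5, 6, 8\}$
  rad/sample, trading time against frequency resolution.
* `encodeDwt()` - maximum-depth orthonormal discrete wavelet decomposition
  (periodic extension, zero-padding to a power of two), coefficients tiled
  level-by-level into a square; channels use the Daubechies-4, Haar and
  Daubechies-6 families. The transform pair is exactly orthonormal, so
  reconstruction is exact to rounding - a tested invariant.

Other feature-to-image maps (e.g. neighbourhood-organizing projections) can
be plugged in as additional encoders behind the same batch interface; they
are intentionally out of scope here.

## Ensemble protocol

`trainEnsemble()` trains `n_members` independent members. Each member, from
its own seed: (1) draws a uniform feature permutation applied identically to
every partition; (2) fits the per-feature 0-255 normalization *on training
rows only* (the convention of the SGD-momentum training path; disable with
`normalize_0_255 = FALSE` for the path that skips it to increase diversity);
(3) draws one window triple and encodes every sample; (4) trains the backbone,
keeping per-epoch snapshots and a training-set metric trace. The deployed
model is the epoch state maximizing the *training-set* metric (AUC for two
classes, accuracy otherwise), ties resolved to the earliest epoch. Members
whose training diverges (non-finite loss) are dropped with a warning and
recorded in the ensemble object. Ensemble prediction is the unweighted mean
of member score matrices - linear and order-invariant, which the tests
assert.

The reference configuration of the method uses fifteen members and
ImageNet-pretrained backbones at 30 epochs, learning rate 0.001, batch 30.
The package's tested default backbone is a small three-conv-block CNN
(channels 4/8/16, 3x3 kernels, 2x2 max pools, a dense softmax head on the
flattened final feature map) trained with SGD momentum 0.9 at learning rate
0.01 for 8 epochs, batch 30. The larger step and shorter schedule suit a
from-scratch small network; the head is dense rather than globally pooled
because an energy ridge at a particular frequency column is *positional*
information that global pooling would erase. Any object implementing the
backbone contract (`train(images, labels, seed)` with snapshots and a trace,
`predict(model, images)` returning class scores) can replace it, e.g. an
adapter around a pretrained network. Scores are post-softmax probabilities;
averaging probabilities is the usual mean rule.

## SVM reference and fusion

The SVM protocol (`fitSvmOnDataset()`): per-feature $[0,1]$ min-max
normalization with parameters from training rows only (test values
extrapolate, unclipped; constant features map to 0); radial kernel;
grid search over cost $2^{-5} \dots 2^{15}$ and width $2^{-15} \dots 2^3$
(log-step 2) maximizing stratified inner 5-fold cross-validation on the
training partition; ties prefer the smallest cost, then the smallest width;
refit on the full training partition. Two-class score matrices carry the
signed decision values - the same quantity the grid search ranks by; Platt
probability calibration can be degenerate at small-cost optima, so it is
reserved for multi-class problems. Since rank metrics and z-normalized
fusion are invariant to the score scale, this choice only affects
readability of the raw scores.

`fuseScores()` combines shape-aligned score matrices as $\sum_i w_i S_i$
(weights default to 1). With `normalize = TRUE` each component is first
z-normalized to overall mean 0 and sd 1 - the convention for cross-family
fusions such as the weighted SVM + CNN-ensemble rule `"2*svm+cnne"` parsed
by `parseFusionRule()`. The plain mean rule over encoder ensembles skips
normalization because the members already share the softmax scale.
Normalization statistics are computed over the whole matrix being fused
(per-class optional); note this means test-time statistics when fusing test
scores - a leakage-sensitivity caveat inherent to the convention, as the
statistics are label-free. Affine invariance ($S \mapsto aS + b$, $a > 0$,
leaves the normalized fusion unchanged) is a tested property.

## Synthetic data: what it does and does not show

`generateSynthData()` provides two desk-scale regimes:

* **spectral** - class $c$ is a unit sinusoid at bin `class_freqs[c]` with
  uniform random phase plus Gaussian noise (`noise_sd`, default 0.5). The
  classes differ *only* in spectral content, so time-frequency encodings are
  discriminative by construction; an independent periodogram-peak oracle
  (`classifyByPeriodogram()`) quantifies the attainable separability
  (about 0.99 accuracy at the default noise; degrading monotonically as
  noise grows - a tested property).
* **mean_shift** - unit Gaussian vectors, with `effect_size` (default 1)
  added on a random 20% feature subset per non-reference class; the natural
  habitat of the SVM baseline.

Defaults (200 samples/class, length 64, bins 5 and 12, noise 0.5, stratified
50/50 split) define the package's desk-scale study conditions: large enough
that test AUC is meaningful, small enough that the full pipeline - encoding
800 tensors and training two 3-member ensembles - runs in a few minutes on
one CPU. The generator emulates the *lengths and class structure* of real
feature tables, not their statistics: real embeddings are correlated,
heavy-tailed and label-noisy, and real effect directions are not axis-aligned
subsets. Passing the desk-scale checks therefore validates the machinery
(encodings are faithful, ensembling and fusion never hurt, no leakage), not
any claim about performance on a particular biological dataset.

## Numerical choices and limitations

* All randomness flows through seeded draws (`withr::with_seed`,
  Mersenne-Twister); member seeds derive from the master seed, and every
  draw (permutation, window triple, fold assignment) is recorded in run
  manifests, so deterministic replay is the default in tests.
* The SWVD of an $N$-vector costs $O(N^2)$ memory and $O(N^2 \log N)$ time;
  quadrant composition keeps long vectors tractable by encoding four
  quarter-length segments.
* The lag-DFT represents lags $|m| \le \lfloor (N-1)/2 \rfloor$ on the
  $N$-bin grid; boundary-limited support means the first and last few time
  rows are low-resolution - the localization tests therefore speak about
  interior times.
* The pure-R CNN is deliberately small. It demonstrates the pipeline and
  passes the desk-scale discrimination checks; it is not a substitute for a
  modern pretrained backbone on real data, and the backbone contract is the
  intended extension point.
* Constant features normalize to 0 by definition in both normalizers; test
  values outside the training range are extrapolated, never clipped, and the
  documentation of each normalizer states so.
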