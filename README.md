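# wvdimage

Wigner–Ville image encodings for classifying molecular-biology feature
vectors in R.

Many classification problems in computational biology start from a
fixed-length real-valued feature vector per sample — protein-language-model
embeddings of peptides, descriptors of aptamer–protein pairs, k-mer features
of DNA barcodes. `wvdimage` turns each vector into a 3-channel image so that
convolutional classifiers can be applied, trains an ensemble of them, and
fuses the ensemble with an optimized SVM:

1. **Encoding.** The vector is treated as a discrete signal `x(1..N)`. Its
   smoothed pseudo Wigner–Ville distribution (SWVD) is computed from the
   instantaneous autocorrelation `A(n,m) = x(n+m)·x(n−m)` smoothed by a time
   window `g` and a frequency window `H` before the lag DFT, taking the
   point-wise absolute value. Channel *i* of the image uses a Kaiser window
   of size `Mi` for both `g` and `H`, with

   `M1 ~ U(0.3N, 0.5N)`, `M2 ~ U(0.5N, 0.7N)`, `M3 ~ U(0.7N, 0.9N)`,

   rounded to odd integers, so `M1 ≤ M2 ≤ M3`. The random increasing sizes
   break the symmetry between ensemble members and increase their diversity.
   Long vectors are split into four equal segments, encoded independently,
   and tiled as quadrants of one composite image. Reshape, Morlet-scalogram
   (CWT) and Daubechies (DWT) baseline encoders share the interface.
2. **Ensemble.** Each member draws its own feature permutation and window
   triple, fits 0–255 per-feature normalization on training rows only,
   encodes, and trains an image classifier keeping per-epoch snapshots; the
   epoch with the best *training-set* metric is deployed. Member scores are
   averaged. The tested default backbone is a small pure-R CNN; any object
   implementing the backbone contract can replace it.
3. **SVM + fusion.** A radial-kernel SVM is tuned by grid search with
   stratified 5-fold cross-validation internal to the training data, after
   `[0,1]` train-anchored normalization. Score matrices are combined with
   (optionally z-normalized) weighted mean rules such as `"2*svm+cnne"`.

## Worked example

```r
library(wvdimage)

## two classes that differ only in spectral content (sinusoids at bins 5 and
## 12 with random phase + Gaussian noise), 200 samples/class, 50/50 split
se <- generateSynthData(n_per_class = 200, len = 64, mode = "spectral",
                        class_freqs = c(5, 12), noise_sd = 0.5, seed = 7)

ens <- trainEnsemble(se, n_members = 3, method = "wigner", seed = 11)
ens
#> WvEnsemble: 3 member(s), encoder = wigner
#>   backbone: cnn4-8-16
#>   classes: class1, class2

scores <- predictScores(ens, se)          # scores the test partition
round(head(scores, 3), 4)
#>      class1 class2
#> [1,] 0.5710 0.4290
#> [2,] 0.5399 0.4601
#> [3,] 0.5205 0.4795
evaluateScores(scores, sampleLabels(se, "test"))$value
#> [1] 0.998                               # test AUC of the 3-member ensemble

sv <- fitSvmOnDataset(se, seed = 2)       # grid-searched radial SVM
c(cost = sv$fit$cost, gamma = sv$fit$gamma)
#>    cost   gamma
#> 0.03125 0.50000

fused <- fuseScores(list(svm = sv$test_scores, cnne = scores),
                    rule = "2*svm+cnne", normalize = TRUE)
evaluateScores(fused, sampleLabels(se, "test"))$value
#> [1] 1
```

The ensemble reads the class difference straight off the time–frequency
ridge (AUC 0.998 on 200 held-out samples); the weighted fusion with the SVM
matches the stronger component. A run takes a couple of minutes on one CPU;
results are deterministic given the seeds.

A thin command-line front end over the same functions lives at
`inst/cli/wvdimage.R` (subcommands `synth`, `encode`, `train-ensemble`,
`svm-baseline`, `fuse`, `evaluate`, `run`, `show-config`).

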