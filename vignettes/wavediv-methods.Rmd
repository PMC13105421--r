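---
title: "Wavelet texture features and divergence-based classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet texture features and divergence-based classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavediv)
```

This vignette documents the model behind `wavediv`, the tunable parameters
and their defaults, the numerical conventions, and the design choices made
where more than one reasonable construction existed. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## The classification model

The unit of classification is a square grayscale patch (side a power of 2;
256 for full-resolution frames, 128 in the default synthetic pipeline) with
intensities normalized to $[0,1]$ by the image bit depth. A 512×512 source
frame contributes four non-overlapping quadrant patches.

**Texture representation.** Each patch is decomposed with a 4-level 2-D
Daubechies db4 DWT. Detail subbands $CH_l, CV_l, CD_l$ are kept at every
level $l = 1..4$ and the approximation $CA_4$ at the deepest level — 13
subbands. Per subband we compute energy, Shannon entropy, mean, standard
deviation, skewness, kurtosis and normalized energy
$NE = \sum |C(x,y)|^2 / \sum |I(x,y)|^2$, giving a 91-attribute vector in a
fixed, documented order (`attribute_names()`); the order matters because
weights index into it.

**Class references.** For each modality, each attribute's three class
distributions are discretized on *shared* bin edges — common support is
what makes divergences between them well defined. Separately, an
exponential likelihood model is fitted per class and attribute,
$\lambda = 1/\overline{x'}$ on values shifted to the positive half-line
(attributes such as skewness are signed, so we subtract the pooled training
minimum and add a small $\delta$; the exponential family was chosen as a
deliberately simple, monotone-hazard lesion-likelihood model). The
likelihoods drive the reported posteriors $P(C\,|\,f)$, not the d-score.

**Attribute weighting.** The average separability of attribute $i$ under
divergence $D$ is the mean of $D$ over the three unordered class pairs of
its distributions. Dividing by the Shannon entropy of the attribute's
pooled distribution down-weights attributes that are merely diffuse rather
than discriminative, and the weights are normalized to sum to one. Two
degenerate cases are handled explicitly: if no attribute separates the
classes, weights fall back to uniform; an entropy floor of 0.1 bit keeps
near-deterministic attributes from dominating through a vanishing
denominator.

**The d-test.** A test patch's attribute value is represented as a smoothed
point mass on the attribute's bins (same kernel and floor as training) and
scored by its weighted divergence *from the normal reference* — normal
patches score low, malignant high, benign in between because the texture
parameters are ordered. The raw score scale depends on dataset, divergence
and weighting, while the decision bands are fixed at 0.4 and 0.6; the
bridge is a monotone piecewise-linear calibration anchored so that the
training-class median raw scores map to $d = 0.2, 0.5, 0.8$, extended
linearly outside the anchors and clipped to $[0,1]$. This anchored
calibration is the minimal construction that makes fixed bands meaningful
on any dataset. Band boundaries are half-open, $[0, 0.4)$, $[0.4, 0.6)$,
$[0.6, 1]$, so the partition is total and disjoint.

**Consensus and fusion.** The three divergences can vote independently
(`per_divergence`, used for rate tables) or through the band of their
median (`median`, the default consensus). SEM and AFM results of the same
subject fuse by averaging d per divergence and multiplying-renormalizing
the posterior vectors; the fused label is the band of the median fused d.
Averaging keeps the fused score on the calibrated scale; the posterior
product is the independent-modality likelihood combination.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `wavelet_name` | db4 | — | 4 vanishing moments; standard texture choice |
| `levels` | 4 | — | 13 subbands from a 256 (or 128, 64) patch |
| `entropy_bins` | 64 | bins | resolution vs. patch size (16×16 deepest band) |
| `n_bins` | 64 | bins | balances resolution against ~tens of training samples per class |
| `bandwidth` | 1.0 | bins | mild smoothing; 0 disables |
| `h_floor` | 0.1 | bits | entropy floor in the weighting |
| `band_edges` | 0.4, 0.6 | d units | fixed decision bands |
| `calibration_anchors` | 0.2, 0.5, 0.8 | d units | class medians centered in their bands |
| `bootstrap_n` | 10 000 | resamples | percentile CI stability ≪ 0.1 point |

## Numerical conventions

- **Boundary mode.** The DWT uses periodization, not the common symmetric
  extension: it is the boundary mode that yields exact dyadic subband sizes
  and an orthogonal transform, so subband energies sum to the patch energy
  and $\sum NE = 1$ — which is what makes normalized energy interpretable
  as an energy *fraction*. The operators are decimated circulant matrices;
  orthogonality holds at any even size because the filter's even-lag
  autocorrelations vanish.
- **Degenerate bands.** A band whose standard deviation is below $10^{-12}$
  (on the $[0,1]$ intensity scale) is treated as zero-variance: skewness,
  kurtosis and entropy are defined as 0. Kurtosis elsewhere is the raw
  standardized fourth moment (Gaussian → 3), not excess.
- **Entropy.** Base-2, from a 64-bin histogram over the band's own range.
- **Histogram smoothing.** The Gaussian kernel acts in bin space with
  *reflecting* boundaries, making the smoothing matrix doubly stochastic:
  mass is conserved and a uniform histogram stays uniform (a truncated
  kernel would attenuate edge bins). Probabilities are floored at $10^{-9}$
  and renormalized, so no divergence ever meets a true zero.
- **Divergence ranges.** JSD uses base-2 logarithms (maximum 1 at disjoint
  support); Hellinger is the squared distance; triangular discrimination is
  halved from its native $[0,2]$. All three therefore share $[0,1]$ and one
  set of bands. The convention $0 \log(0/x) = 0$ applies throughout. A
  binary-coordinate JSD variant (`jsd_variant = "binary"`) is retained for
  comparison; it is unbounded and not used by the default pipeline.
- **Calibration degeneracy.** If class medians do not increase (no signal),
  they are made weakly increasing before fitting so the map stays defined;
  predictions then collapse toward chance, which is the correct behavior on
  null data.
- **Ties and boundaries.** Band edges belong to the upper band; values
  outside the trained bin range are clipped into the end bins (training
  edges already carry a 5% margin over the pooled range).

## The synthetic generator

No public corpus of labeled SEM/AFM cervical-cell images exists, so the
package ships a seeded generator that emulates the *statistical* structure
the classifier consumes: a Gaussian random field whose correlation length
shortens and whose contrast rises with malignancy, plus Poisson-placed
bright blobs whose density and size grow with malignancy (a stand-in for
nuclear enlargement and surface irregularity), a modality filter
(high-frequency grain for SEM, low-pass smoothing for AFM), and additive
sensor noise. All class parameters are `base + separation × offset` with
monotone offsets, so `separation = 0` makes the classes exchangeable and
larger values pull them apart; parameters were frozen once (correlation
length 8/6/4 px, contrast 0.06/0.08/0.10, blob density 1/5/9 per $10^4$ px,
radius 2/3/4 px, amplitude 0.20/0.25/0.30, noise sd 0.02) to give
held-out accuracies in the mid-90s at the default conditions — calibrating
the *fixture*, not the method.

The default study conditions are 30 frames per class per modality at side
256, split into four 128-pixel patches, with the train/test split at the
source-frame level (all four quadrants of a frame stay together, avoiding
quadrant-leakage; `split_train_test(by = "patch")` reproduces a patch-level
split). That yields 360 training and 360 held-out patches per run, which
keeps a full end-to-end run in the tens of seconds on one core; the
generator scales to 512-pixel frames and 256-pixel patches unchanged.

What passing tests on this generator do **not** show: robustness to real
acquisition physics — charging artifacts, probe convolution, drift,
illumination gradients, stain variability — nor calibration transfer
across laboratories. The generator makes no attempt at physical SEM/AFM
contrast realism; results on it demonstrate the pipeline's statistical
machinery, not clinical performance.

## Design choices on open points

- **Patch as the classification unit.** Frames are split 2×2 and each
  patch is classified independently; reported rates are per patch.
- **All 13 subbands enter the feature set**; the entropy-normalized
  weighting is left to down-weight uninformative ones rather than
  pre-selecting "ideal" bands by hand.
- **Distributions are estimated on attribute values**, not raw pixel
  intensities: the divergence classifier consumes per-attribute
  distributions, so that is where kernel estimation is applied.
- **Stage ranges** (per-class 5th–95th percentile intervals per attribute)
  are computed and stored as diagnostics but do not enter the decision; no
  principled decision rule over them is defined, and the d-bands already
  provide the ordinal structure.
- **Posteriors are computed from the exponential likelihoods,
  independently of the d-score** — the two mechanisms answer different
  questions (calibrated malignancy ordering vs. relative class support)
  and are reported side by side.
- **Equal class priors** in the softmax, matching the balanced design.
- **Evaluation rounding.** When aggregating published per-group percentage
  rates into totals, fractional implied counts are rounded to the nearest
  integer (rates in print are themselves rounded); averages are reported to
  two decimals. Bootstrap CIs use the plain percentile method (2.5th and
  97.5th percentiles, linear interpolation), macro-averaged F1.

## Known limitations

- The exponential likelihood is a one-parameter model per attribute and
  class; attributes whose class-conditional distributions differ in shape
  but not scale are poorly served by it (the d-score, which uses the full
  histograms, is the primary decision mechanism for exactly this reason).
- Attribute independence is assumed both in the likelihood product and in
  the weighted divergence sum; correlated subband statistics (e.g. energy
  and NE of the same band) are double-counted to a degree.
- The calibration is anchored at training medians; under severe class
  imbalance or drift between training and deployment the fixed bands
  inherit that drift.
- Held-out accuracy at the default synthetic scale varies by a few points
  across seeds (n = 360 test patches); conclusions should average over
  seeds, as the test suite does.
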