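# wavediv

Wavelet texture features and divergence-based classification of multimodal
microscopy cell images.

## The problem

Scanning electron microscopy (SEM) and atomic force microscopy (AFM)
resolve sub-cellular surface texture that changes as cervical epithelial
cells progress from normal through benign to malignant states — membrane
roughening, nuclear enlargement, loss of regular fine structure. `wavediv`
implements a lightweight, fully interpretable pipeline that classifies
256×256 (or any power-of-2) grayscale image patches into
**normal / benign / malignant**, separately per modality (six groups:
nSEM, bSEM, mSEM, nAFM, bAFM, mAFM) and fused across modalities. It is
aimed at small-data settings where deep networks are impractical and the
decision must be traceable to explicit texture statistics.

## Method

1. **Features.** Each patch `I(x, y)` is decomposed with a 4-level 2-D
   Daubechies db4 discrete wavelet transform under periodized boundary
   handling, giving 13 subbands `CA4, CH1..4, CV1..4, CD1..4`. Per subband,
   seven statistics are computed — energy `Σ C(x,y)²`, Shannon entropy of
   the coefficient histogram, mean, standard deviation, skewness, kurtosis,
   and normalized energy `NE = Σ|C(x,y)|² / Σ|I(x,y)|²` — for 91 attributes
   per patch. Because the periodized transform is orthogonal, `Σ NE = 1`
   over the 13 subbands.

2. **Class references.** Per attribute, the three class distributions are
   estimated as kernel-smoothed histograms on shared 64-bin support
   (Gaussian kernel in bin space, reflecting boundaries, probability
   floor), plus an exponential likelihood model `λ = 1/mean(x′)` on shifted
   attribute values.

3. **Weights.** Attribute `i` gets weight
   `W(i) ∝ W_av(i) / max(H(i), 0.1)` where `W_av(i)` is the mean divergence
   between the three class-pair distributions — Jensen–Shannon (JSD, base
   2), squared Hellinger (HD), or triangular discrimination (TD, halved to
   `[0,1]`) — and `H(i)` is the entropy of the pooled distribution; weights
   are normalized to sum 1.

4. **d-test.** A test patch scores
   `raw = Σᵢ W(i)·D(testᵢ, normal_refᵢ)` — its weighted divergence *from
   the normal class* — which a training-anchored piecewise-linear
   calibration (class medians ↦ 0.2 / 0.5 / 0.8) maps to `d ∈ [0, 1]`.
   Decision bands: **normal** `[0, 0.4)`, **benign** `[0.4, 0.6)`,
   **malignant** `[0.6, 1]`. Posteriors `P(C|f)` come from the exponential
   likelihoods via an equal-prior softmax.

5. **Fusion and evaluation.** SEM and AFM results of the same subject are
   fused (mean d, product-renormalized posteriors). Evaluation reports
   per-group correct-classification rates, totals, average success rate,
   and 95% percentile-bootstrap CIs (10 000 resamples).

A seeded synthetic generator (Gaussian random fields + Poisson-placed
blobs, with monotone class parameters and SEM/AFM modality filters)
provides fully reproducible data for every stage.

## Worked example

```r
library(wavediv)

r <- run_end_to_end(seed = 1)   # 30 frames/class/modality, side 256
print(r$report)                 # held-out patches, both modalities
#> JSD: 346/360 correct, average success rate 96.11% (macro P 0.964 R 0.961 F1 0.961)
#> HD: 347/360 correct, average success rate 96.39% (macro P 0.966 R 0.964 F1 0.963)
#> TD: 342/360 correct, average success rate 95.00% (macro P 0.952 R 0.950 F1 0.950)
print(r$fused_report)           # SEM+AFM fused per subject patch
#> JSD: 176/180 correct, average success rate 97.78% (macro P 0.979 R 0.978 F1 0.978)
#> HD: 176/180 correct, average success rate 97.78% (macro P 0.979 R 0.978 F1 0.978)
#> TD: 176/180 correct, average success rate 97.78% (macro P 0.979 R 0.978 F1 0.978)
```

Each line gives, per divergence, the number of held-out patches assigned
to their true class by that divergence's d-band, the average success rate
(100 × correct/used), and macro precision/recall/F1 over the three
classes. Fusing the modalities lifts accuracy above either alone.

Individual stages are exposed: `dwt_decompose()`, `extract_features()`,
`train_reference()`, `compute_weights()`, `d_test()`, `classify_bands()`,
`fuse_modalities()`, `score()`, `bootstrap_ci()`. A command-line front end
with `synth / extract / train / classify / fuse / evaluate / run-all`
subcommands lives at `inst/scripts/wavediv.R`.

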