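---
title: "dryspec: models, synthetic data and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dryspec: models, synthetic data and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dryspec)
```

This vignette is the package's account of its science: what each model
assumes, what the synthetic generator does and does not emulate, why the
numerical defaults are what they are, and which design questions were
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The measurement model behind the generator

A dried-mushroom ATR-FTIR absorbance spectrum is modelled as a sum of
Gaussian bands distorted by the usual bench artefacts. For a sample of
temperature class $k$,

$$ x(v) \;=\; a \sum_i \big(\beta_i + \delta_{ik}\big)\,
   e^{-(v - c_i)^2 / 2w_i^2} \;+\; b \;+\; p(v) \;+\; \varepsilon(v), $$

with multiplicative scatter $a \sim 1 + N(0, 0.03)$, additive scatter
$b \sim N(0, 0.02)$, a per-sample degree-2 polynomial baseline $p(v)$
(coefficient sds 0.03/0.012/0.005 on the grid normalised to $[-1,1]$),
and iid detector noise $\varepsilon \sim N(0, 0.004)$ absorbance units.
The grid is the instrument convention: 4000 down to 400 cm⁻¹ in 4 cm⁻¹
steps, 901 points.

The band library holds fifteen peaks at the characteristic positions of
dried porcini powder — the O–H/N–H broadband (3200), aliphatic CH₂
(2928/2840), amide I/II/III (1620/1554/1228), carboxylate (1400), the
polysaccharide complex (1147/1100/1017/918), glucan markers (890/760) and
ring modes (620/526). Base amplitudes (0.06–0.5 AU, strongest at the
polysaccharide 1017 band) are realistic for powder ATR spectra.

**Class structure.** Each band carries a 5-vector of class offsets
$\delta_{ik}$ built from four temperature-response motifs that targeted
metabolomics of dried mushrooms actually shows: monotone fall (water/N–H,
amide II), monotone rise (amide I, glucans), a peak at the mild 45 °C
treatment (aliphatics, carboxylate), and a mid-range plateau. Two bands
(918, 760 cm⁻¹) are temperature-inert on purpose, so tests can assert that
class differences appear exactly where deltas are non-zero and nowhere
else.

**Calibration of the class separation.** The source study reports
*outcomes* (a first-derivative PLS-DA reaches 100 % training accuracy;
a CNN on 2DCOS images classifies an external set perfectly) but neither
within-class variances nor absolute band-shift magnitudes — the real data
are confidential. The generator's separation scale is therefore calibrated
once so the stated world exhibits those reported qualitative outcomes:
adjacent classes differ by 0.02–0.06 AU at discriminating bands (5–15
noise-sd, comfortably above the ≥ 5σ floor the acceptance setup assumes),
and artifact scales are realistic rather than flattering — baseline drift
is strong enough that derivative pretreatments, which remove it, are the
sensible choice. One honest consequence: the synthetic classes are *more
linearly separable* than the real powders (where raw-spectrum PLS-DA
reached only ~79 %/64 % train/test accuracy). A green discrimination test
here establishes that the pipeline is correct, not that real mushrooms are
this easy.

**Concentrations.** Taste-compound concentrations are linear functionals
of the 1800–1200 cm⁻¹ band: $y_j = \mathbf{w}_j^\top \mathbf{x}_{band} +
\mu_j + \eta_j$, with Gaussian-bump weight profiles centred on amide and
carboxylate bands (plus a weak secondary lobe so compounds are not
collinear). Noise is parameterised by signal-to-noise ratio,
$sd(\eta_j) = sd(\mathbf{w}_j^\top \mathbf{x}_{band}) / \mathrm{SNR}$ with
SNR = 10 by default — the stated floor of the quantification design.
Negative draws are clipped at zero (physical non-negativity) and counted.
The true $\mathbf{w}_j$, intercepts and noise sds ride along as an
attribute for recovery tests.

**Seeding.** One run seed fans out to per-stage streams
(`stage_seed(seed, "spectra")`, `"concentrations"`, `"permutation"`,
`"cnn_init"`, `"cnn_shuffle"`) through a fixed Lehmer-style map, so any
stage can be re-run in isolation and still reproduce the full-pipeline
draws.

## 2. Pretreatments

All pretreatments are strictly row-wise. The only cross-sample state is
the MSC reference (the calibration mean spectrum), which is learned on
calibration data only and reused on held-out data — using the full-data
mean would leak test information into the correction.

Savitzky–Golay filters implement smoothing and both derivatives; plain
finite differences are deliberately not offered (unacceptable noise
amplification at 4 cm⁻¹ spacing). Defaults: window 15 points (56 cm⁻¹),
polyorder 2 for smoothing/first derivative, 3 for the second. Edge points
are evaluated off-centre from a polynomial fitted to the boundary window,
so the output grid equals the input grid and band windows stay
addressable. Derivatives are scaled by the signed grid step: units are
AU · cm (first) and AU · cm² (second), negative step on the descending
grid.

Chain strings follow the comparison-table names (`"FD+MSC"` etc.) and are
applied left to right; the printed order is taken literally since no order
is stated anywhere.

## 3. Kennard–Stone partitioning

K-S is deterministic: seed with the most distant pair (ties to the lowest
index pair), then repeatedly add the sample maximising its minimum
distance to the selected set (ties to the lowest index). Partition sizes
use largest-remainder rounding, which reproduces the intended 59/30/10 for
99 samples at 60/30/10. Distances are Euclidean in whatever feature space
the caller supplies; the pipeline uses raw spectra.

The PLS splits are global; the CNN 60/30/10 split is run per class
(stratified). Whether the original workflow stratified is unknowable from
the text; stratification is the package's choice so that the external set
contains every temperature and per-class SEN/SPE/EFF are defined.

## 4. PLS, PLS-DA, VIP, permutation testing

The core is NIPALS PLS2 on column-mean-centred data. Spectra are *not*
autoscaled (band intensity is the signal); concentration tables *are*
autoscaled wherever they enter PCA, clustering or screening, the
convention for metabolite matrices. With all `min(n−1, p)` components on
full-rank data the predictions equal ordinary least squares — the test
suite asserts this to 1e-8, which pins down the deflation algebra.

Component count is chosen to minimise RMSECV over 7 venetian-blind folds
laid along the K-S order (component ceiling 10). PLS-DA regresses one-hot
class membership and assigns by row argmax. Reported metrics: R²X, R²Y,
cross-validated Q² and RMSECV, held-out RMSEP, train/test accuracy. VIP
uses the standard weight-normalised form; $\sum_j VIP_j^2 = p$ is asserted
on every fitted model.

The permutation test refits the *entire* pipeline (component selection
included) under uniformly permuted labels; reporting the permuted
(R²Y, Q²) pairs, the intercepts of their regressions on label correlation,
and a flag: the model is called overfit when ≥ 5 % of permuted Q² values
reach the true Q². On pure-noise inputs this flags overfitting in ≥ 90 %
of simulated datasets (acceptance criterion); on the default synthetic
design the true Q² exceeds all permuted ones.

PLSR calibrations report R²c, R²p, RMSEP and RPD = sd(reference values of
the prediction partition) / RMSEP — the common chemometrics definition;
the source never defines RPD. A numerically zero RMSEP caps RPD at 1e6
with an explicit flag rather than returning Inf. Chain search fits every
chain on identical splits; classification ranks by test accuracy (ties:
lower RMSECV, then lower RMSEP — the stated basis of the original model
choice), regression by R²p (ties: higher RPD), then listing order.

## 5. Synchronous 2DCOS and the image pipeline

`synchronous_map` is $\Phi = S^\top S/(m-1)$ for mean-centred dynamic
spectra — the covariance across the perturbation axis; symmetry and
non-negative auto-peaks are enforced/asserted, and a brute-force
double-loop oracle pins the implementation to 1e-10.

For supervised learning one image per sample is required; the package's
convention is the rank-1 map $\Phi = s s^\top$ of the sample's deviation
from the global mean (how the original 450 images map to 99 samples is not
derivable from the text; group-level maps are available for figures). Two
measured facts shaped this stage:

* **Scatter correction before imaging.** Rank-1 maps of *raw* deviations
  are dominated by multiplicative/additive scatter — a per-sample offset
  contributes a constant of norm comparable to the entire class signal —
  and carry almost no class information (nearest-neighbour external
  accuracy ~0.6 in our world). Images are therefore computed from
  SNV-corrected spectra by default (`scatter_correct = FALSE` restores raw
  deviations).
* **Anti-aliased downsampling.** At 64 px the pixel pitch is ~56 cm⁻¹;
  point-sampled bilinear interpolation can miss a sharp (σ = 8 cm⁻¹) band
  entirely, which measurably destroys class information. Downsampling
  therefore bin-averages. Bin averaging commutes with the outer product
  (resample the deviation vector, then take $s s^\top$ — exactly
  equivalent), so per-sample images never materialise the 901 × 901 map.

Rendering min–max normalises each map to [0, 1] and applies a jet-style
colormap; a constant map renders uniformly mid-scale; everything is
deterministic. Figure rendering defaults to 224 px; the CNN pipeline uses
64 px — rank-1 maps are smooth outer products, and 224 px would cost ~12×
CPU for no information gain.

## 6. The residual CNN

Input 64 × 64 × 3 (RGB in [0, 1], centred at 0.5 internally); stem 3 × 3
convolution to 32 channels; two residual blocks (two 3 × 3 convolutions
with an identity shortcut each) separated by 2 × 2 max-pools; a 4 × 4
average-pool; flattened softmax head; cross-entropy loss; Adam
(lr 2 × 10⁻³, batch 8, ≤ 30 epochs — the reported training stabilises by
epoch 24). Everything is seeded: initialisation and batch shuffling derive
from the run seed, so training is bitwise reproducible, which the tests
assert.

Two architecture decisions came from measurement, not taste. A fully
global average pool — the textbook ResNet head — plateaued near 50 %
training accuracy here: the class signal of a rank-1 correlation map is a
*spatial sign pattern*, and spatially blind channel means cannot encode
it; the 4 × 4 average-pool head retains coarse layout at trivial cost.
And with only ~60 training images, batch 16 at lr 10⁻³ yields ~120
optimisation steps in 30 epochs, which demonstrably underfits; batch 8 at
lr 2 × 10⁻³ converges to perfect train/test/external accuracy on probe
seeds. The implementation is plain base-R im2col matrix products with
analytically derived gradients, finite-difference-checked in the test
suite; training the default configuration takes a few CPU minutes.

Evaluation is one-vs-rest per class: SEN = TP/(TP+FN), SPE = TN/(TN+FP),
EFF = SEN × SPE exactly as printed in the source (many authors use
√(SEN·SPE); both equal 1 for a perfect classifier, so the reported results
cannot disambiguate — the geometric variant is available via
`classification_metrics(..., variant = "geometric")`). Zero denominators
yield an explicit `undefined` flag, never silent NaN.

## 7. Metabolite screening

Differential compounds satisfy VIP > 1 (from one global PLS-DA on the
autoscaled concentration table) *and* P < 0.05 (one-way ANOVA across the
five classes), both strict, no multiple-testing correction — matching the
printed criterion; Benjamini–Hochberg is available but off by default.
Which test produced the original P values, and whether VIP came from one
global model or pairwise models, is unstated; the global-model/ANOVA
choice is documented here as the package's, not inferred as the source's.
Autoscaling makes screening invariant to per-compound affine rescaling,
which the tests assert. Clustering defaults are Euclidean distance,
complete linkage, autoscaled values; `hclust` merges are deterministic
with ties resolved by observation order.

## 8. Known limitations

* The generator draws iid Gaussian noise and Gaussian band shapes; real
  ATR spectra have correlated noise, Voigt-ish bands, water-vapour lines
  and penetration-depth effects. None of these are emulated.
* Class structure is a pure mean shift: real within-class chemistry varies
  (drying time, specimen) in structured ways, which is why the synthetic
  discrimination task is easier than the reported one (every pretreatment
  chain reaches 100 % training accuracy here; the reported raw-spectrum
  models did not).
* Concentration–spectrum coupling is exactly linear by construction, so
  PLSR recovery tests validate the algebra, not the chemistry.
* The CNN recipe is tuned for ~100 samples on one CPU; it makes no claims
  at scale, and uses no augmentation or pretraining.
* No asynchronous (Hilbert–Noda) 2DCOS, no moving-window variant, no
  OPLS-DA/sparse PLS, no EMSC/detrending/OSC, no instrument file formats
  (JCAMP-DX/SPC).
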