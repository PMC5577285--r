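---
title: "Methods: discriminating sulfur-fumigated material by NIR/LC-MS correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminating sulfur-fumigated material by NIR/LC-MS correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moca)
```

## The problem and the model

Sulfur fumigation of botanical material converts steroidal saponins into
sulfate (+SO₃) and sulfite (+SO₂) derivatives. Two consequences make the
treatment detectable. First, the sulfur-bearing groups (S–H, S–OH) absorb
in the near infrared around 5,000–5,200 cm⁻¹, superimposing a
class-specific band on an otherwise shared spectrum. Second, the LC-MS
feature table of a fumigated sample contains derivative features displaced
from their parent saponins by the exact adduct masses (79.9568 Da for SO₃,
63.9619 Da for SO₂), elevated at the expense of the parents. `moca` treats
the discrimination problem as supervised two-class modelling of the NIR
layer, the mechanism question as marker screening of the MS layer, and ties
the two together by correlation.

The classifier is PLS1 regression of a 0/1 class code on the predictor
matrix (NIPALS; the fumigated class is coded 1, predictions thresholded at
0.5). Key assumptions: two classes; predictors linearly related to class
membership after preprocessing; sample sizes small enough that
leave-one-out cross-validation is appropriate (the default for n ≤ 30-ish
designs this package targets). NIR matrices are centred only; feature
tables are centred and unit-variance scaled (spectroscopy vs metabolomics
convention). Both are configurable.

## Model diagnostics

* **R²Y / Q²** — explained response variance in fit and in cross-validation
  (Q² = 1 − PRESS/SS, with SS about the training-fold means). Q² ≤ R²Y per
  component on the same data.
* **RMSEC / RMSECV / RMSEP** — root-mean-square error of the continuous
  prediction on the calibration fit, in CV, and on the held-out validation
  set.
* **Se / Sp / accuracy** — thresholded confusion-matrix rates with the
  fumigated class positive.
* **Permutation test** (default 200 relabellings): the model is refit under
  permuted labels with the same component count and CV scheme; the R² and
  Q² intercepts come from least-squares lines through all (label
  correlation, statistic) points including the original at correlation 1. A
  valid model has a negative Q² intercept and an original R² above every
  permuted one. On genuinely uninformative data the original statistics sit
  inside the permuted distribution instead.
* **CV-ANOVA**: F-test of the cross-validated residuals of the model
  against those of the training-mean null on identical folds, with
  `df_model = n − 1 − n_lv`. Degrees-of-freedom bookkeeping for this test
  differs between published software implementations; the formulation here
  is documented, not claimed identical to any of them. If the model does
  not beat the null, p = 1 by construction.

One property of the cross-validated Q² deserves a note: on pure-noise data
the *maximum* of Q² over a scan of 5–10 component counts is positive in a
non-trivial fraction of random datasets (roughly a quarter at n = 26,
p = 72; each individual component count is positive only ~5–7% of the
time). This is a property of the statistic, not of the implementation — an
independent scikit-learn cross-check reproduces it — and is why the test
suite asserts a bound on the pooled positive fraction rather than
seed-by-seed negativity, and why the permutation test (which compares
against a null *distribution*) is the recommended validity check.

## Preprocessing bank

Eight method families are provided; the comparison utility ranks all of
them on a shared Kennard–Stone split by RMSECV, then accuracy.

| method | action | notes |
|---|---|---|
| `raw` | identity | baseline for comparison |
| `msc` | regress each spectrum on a reference, correct `(x − b)/a` | reference = mean **calibration** spectrum, recorded so validation data are corrected with calibration parameters |
| `snv` | centre/scale each row | errors on constant rows; idempotent |
| `baseline` | subtract per-row linear fit | detrending |
| `normalization` | unit Euclidean norm | |
| `st` | `log10(1/x)` absorbance transform | the "spectroscopic transformation" of the comparison bank is not defined in the chemometrics literature with any precision; this package documents its choice and errors on non-positive input rather than guessing further |
| `wds` | Daubechies-4 wavelet denoising | periodic transform after symmetric padding to a power of two, decomposition level ⌊log₂ n⌋ − 4, soft universal threshold (σ from the MAD of the finest detail band) |
| `sg` | Savitzky–Golay | least-squares polynomial smoothing/derivatives |

Savitzky–Golay edge handling: output points near the edges are fitted on
truncated one-sided windows, so the output length always equals the input
length and polynomials up to the fit order are preserved exactly
everywhere, not just at interior points. Derivatives are returned per cm⁻¹
(divided by the grid step to the derivative order). The central-point
weights reproduce the classical published coefficient tables, e.g.
(−3, 12, 17, 12, −3)/35 for a 5-point quadratic smooth.

## Waveband selection

**SiPLS.** The grid is cut into `n_intervals = 20` contiguous equal
intervals (remainder points to the last one) and every union of
`n_combine = 3` intervals is cross-validated over 1–10 latent variables.
The partition count 20 is a package default — the synergy count 3 is the
standard choice, while partition counts vary across applications — and is
exposed as an argument and reported in the output. Ranking is by RMSECV
with ties broken toward fewer components and then lower interval indices.
An exhaustive search is C(20,3) = 1140 cross-validated models; the compiled
PLS1 kernel keeps this to a few seconds.

**2D-COS.** Generalized two-dimensional correlation spectroscopy over a
perturbation series: dynamic spectra are deviations from the mean spectrum
(Noda convention), the synchronous matrix is Φ = ỸᵀỸ/(m−1), and the
asynchronous matrix uses the Hilbert–Noda transform N_jk = 1/(π(k−j)) off
the diagonal. The autocorrelation curve diag(Φ) localizes
perturbation-driven intensity change.

The perturbation variable matters. For the fumigation question the natural
series is fumigation *progression* (time or dose) measured on one sample:
there the only varying feature is the sulfur band, and the difference
between the autocorrelation curves of a fumigated series and an untreated
control series peaks at the band essentially always. Differencing
per-class autocorrelation curves of two 13-batch *collections* instead is
statistically ill-posed: both curves are dominated by between-batch
constituent variance whose sampling noise at n = 13 exceeds the band's
variance contribution by more than an order of magnitude, so the argmax of
the difference is essentially random. The package therefore applies
`autocorrelation_difference()` to series (as in the validation experiments
that motivated it); class collections remain available for the synchronous
map itself.

## MS marker screening

A feature is a marker when it passes all three criteria simultaneously:
S-plot position (|p| > 0.05 in model-scaled covariance units and |p(corr)| >
0.3), VIP > 1.5, and Welch t-test p < 0.05. The covariance threshold's
scale depends on the variable scaling of the model, so it is configurable;
the defaults reproduce the conventional screen. t-test p-values are also
reported Benjamini–Hochberg-adjusted, flagged separately, because the
conventional screen applies no multiplicity correction. Features missing in
more than half the samples are dropped; remaining gaps are imputed with
half the minimum positive area (both logged).

These three criteria are strongly dependent: all are increasing functions
of a feature's class correlation. At n = 26 the raw t-test (p < 0.05 ⟺
|r| ≳ 0.39) is the binding criterion, so on null data the three-way
intersection usually *coincides with* the t-test hit set rather than being
strictly smaller — a structural fact verified against an independent
implementation. The real value of the intersection is on informative data,
where the model-based criteria (VIP, S-plot) suppress features that are
class-associated but carry negligible model weight.

Mass arithmetic uses IUPAC monoisotopic masses at ≥9 decimals. Three charge
conventions are explicit: neutral, deprotonated ([M−H]⁻ = neutral − proton)
and *anion composition* (the printed composition already lacks the proton's
H; one electron mass is added). Printed high-resolution m/z values in
reports of this chemistry often disagree with every convention at the
~1 ppm level, so the package checks agreement at ≤2 ppm and documents its
own convention rather than chasing a particular report's error column.

M+2 fine structure: the ³⁴S line (+1.99580 Da) against ¹³C₂ (+2.00671 Da)
and ¹⁸O (+2.00424 Da), with abundances n_S·r_S, C(n_C,2)·r_C² and n_O·r_O
(r = heavy/light abundance ratio). The reported resolving power is
m/Δm for ³⁴S vs ¹³C₂ — at high carbon counts ¹³C₂ dominates the non-sulfur
cluster (for C₅₀ compositions it is ~3× the ¹⁸O line), so it is the line
the sulfur signal must be split from; at m/z ≈ 1129 this needs ≈1.0×10⁵.

Neutral-loss ladders are annotated by depth-first search with backtracking
over the built-in loss table (rhamnosyl 146, glucosyl 162, glucose 180,
xylosyl 132, water 18, SO₃ 80, SO₂ 64; nominal and exact masses), where
every step must land on an observed peak within tolerance (0.5 Da for
nominal peak lists, ~10 ppm for exact ones). The objective is maximal
matched-peak count, ties toward fewer steps, then smaller total |error|.
Note that a 180 Da step (intact glucose) equals glucosyl + water
(162 + 18); both entries are kept because the ladder peaks disambiguate
them — a two-step route requires the intermediate fragment to be present.

## The synthetic study

The generator's defaults define the study conditions used throughout the
tests: 13 batch pairs (26 samples), 4,000–10,000 cm⁻¹ at 8 cm⁻¹ (751
points), an SF band at 5,100 ± 100 cm⁻¹ with peak absorbance 0.05 over
instrument noise of 0.001 AU, multiplicative/additive scatter (sd 0.05 /
0.02) — exactly what MSC/SNV are designed to remove, which makes the
preprocessing comparison meaningful — and eight shared constituent Gaussian
bands in the combination/first-overtone regions with per-batch
concentration variation, giving the collinear structure PLS expects.
Feature tables hold 12 saponins (each with a derivative at the exact adduct
shift), 12 homoisoflavone-like and 36 unrelated features (72 total);
conversion moves 30% of each saponin to its derivative in fumigated
samples, with multiplicative log-normal noise (chromatographic convention).

Choices the underlying chemistry does not pin down, decided once:

* **Untreated background** of sulfur markers (they are never exactly zero
  in practice — environmental sulfur): 5% of the fumigated conversion
  level, applied as a background conversion so that parent + derivative
  mass balance is exact before noise.
* **Time-course kinetics**: first-order saturation A(t) = A_max(1 −
  e^(−kt)); only a plateau beyond 24 h is established behaviour, not a
  functional form. k = 0.13 h⁻¹ puts A(24)/A_max ≈ 0.956 (≥ 0.95, i.e.
  plateau by 24 h) and A(36)/A(24) ≈ 1.037 (≤ 1.05).
* **Repeated-measurement scatter**: a time-course re-measures one
  progressively fumigated sample, so the scatter gain/offset is drawn once
  per series; detector noise is fresh per time point.
* **Seeding**: the constituent-band layout and all draws derive from the
  config seed (feature tables and time-courses use fixed offsets of it), so
  identical configs give bit-identical outputs.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: retention-time drift and peak-alignment
artifacts, ion suppression, correlated (pink) instrument noise, water-band
interference, class-correlated confounders such as geographic origin, and
matrix effects that make real fumigation chemistry batch-dependent. The
pipeline's statistical machinery is validated here; analytical validation
on real sample sets remains the user's task.

## Numerical choices and degenerate inputs

* NIPALS stops when ‖Xᵀy‖ or the score norm falls below 1e−13; requesting
  more components than the rank truncates with a warning.
* Kennard–Stone ties resolve to the lowest row index, making the split
  deterministic.
* Cross-validation folds that lose a class are an error, not a silent
  renumbering; LOO avoids the issue for n ≥ 4 with both classes ≥ 2.
* Zero-variance features: SNV and S-plots error/exclude them loudly
  (excluded features are flagged and logged, never dropped silently).
* `plateau_time` requires the plateau to contain at least two sampled
  points; otherwise any strictly increasing curve would "plateau" at its
  final sample. Larger tolerances never give later plateaus. On
  noise-bearing band-absorbance curves the 24-vs-36 h decision margin is
  only ~1.5× the band-averaged noise sd at the default settings, so the
  detected plateau of a noisy NIR curve can occasionally slip by one
  sample; total marker areas (≈30× less relative noise) are deterministic
  in practice.
* Band absorbance averages a configurable closed interval (default
  5,000–5,200 cm⁻¹) rather than reading a single grid point; a degenerate
  interval gives single-point mode.
* Problem sizes in the test suite (LOO on 16–26 samples, SiPLS at 20/3,
  permutation tests at 100–200 relabellings, 8–50 seed replicates per
  Monte-Carlo property) were chosen to exercise every claim at the scale
  of the study design itself.

## Known limitations

Binary classification only (no multi-class, no OPLS-DA); no orthogonal
signal correction or EMSC in the preprocessing bank; no vendor raw-file or
mzML ingestion (CSV/JCAMP-DX/MGF only); ladder annotation stops at
mass-shift/sequence evidence and does not attempt structure elucidation;
the CV-ANOVA degrees of freedom follow one documented convention among
several in circulation.
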