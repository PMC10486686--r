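---
title: "Methods: simulation and chemometric workflow in strawnir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and chemometric workflow in strawnir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strawnir)
```

`strawnir` reproduces, on simulated data, the complete chemometric
workflow used to phenotype strawberry cultivars from FT-NIR spectra:
laboratory quality panel → ANOVA/Tukey comparison → spectral
preprocessing → PCA exploration → multiblock data fusion → PLS-DA
classification. This vignette documents the generative model, the
numerical conventions of every stage, the design choices made where the
design was genuinely open, and what a green test does and does not
establish. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The generative model

### 1.1 Laboratory panel

Each cultivar `c` is described by a `cultivar_profile`: a mean vector
`μ_c` over the five quality parameters (soluble solids content in
°Brix, titratable acidity in % citric acid, vitamin C, anthocyanins and
phenolic acids in mg/100 g FW), a vector of coefficients of variation
`cv`, and a within-cultivar correlation matrix `R`. Fruits are drawn
from

> v ~ N(μ_c, D R D),  D = diag(cv · μ_c)

truncated at zero by **resampling** whole fruits (not clipping), which
keeps the means essentially unbiased for CVs up to about 0.3. The four
default profiles carry the reference means (e.g. Sibilla: SSC 7.66
°Brix, TA 0.75%; Romina: vitamin C 31.84, anthocyanins 93.81 mg/100 g).

Defaults chosen where the reference design is silent:

- `cv = 0.12` on every parameter — typical fruit-to-fruit variability
  for field-grown strawberries. Configurable; see §6 for a consequence.
- `R`: SSC–TA correlation 0.4 (both track maturity),
  anthocyanin–phenolic 0.3 (shared biosynthesis), all other pairs 0.
- 54 fruits per cultivar split evenly over two harvests; missingness
  (default 19 of 216 fruits, taking the complete-case cohort to 197) is
  completely at random over fruits, each affected fruit losing one to
  five records — the loss mechanism of a single-fruit study (too little
  material, failed extractions) is not knowable, so MCAR is the neutral
  choice.

### 1.2 Spectra

A fruit's clean spectrum on the default 10,000→4,000 cm⁻¹ grid (1557
points, 4 cm⁻¹ nominal step) is a sum of Gaussian absorption bands on a
broad water baseline:

> s(ν) = Σ_b A_b · exp(−(ν − c_b)² / 2w_b²) + water · baseline(ν)

with bands at 5188, 6860 and 8580 cm⁻¹ (widths 180, 220, 260 cm⁻¹).
Band amplitudes are affine in the fruit's lab values:
`A_b = base_b · water_b + Σ_j link_bj v_j`. The default links are

- 6860 cm⁻¹ (O–H/C–H combination): +0.015 AU per °Brix SSC, +0.08 AU
  per % TA — the band associated with sugars and acids;
- 5188 cm⁻¹ (O–H combination, water): rides on a per-fruit latent water
  term (N(1, 0.03)) and is linked **negatively** to vitamin C
  (−0.002 AU per mg/100 g). This reproduces the empirically observed
  pattern that the water band is higher for the low-vitamin-C pair
  (Cristina, Silvia) than for the high-vitamin-C pair (Sibilla,
  Romina), and is what gives the spectra a MODE 1 class signal at all:
  SSC/TA alone do not align with that pairing (Sibilla is high in SSC
  but Romina low);
- 8580 cm⁻¹ (C–H second overtone): compositionally inert by default.

Each fruit yields two replicate rows (the fruit rotated 180° between
scans): identical composition signal, replicate-specific multiplicative
(sd 0.05) and additive (sd 0.02) scatter draws, and iid noise (sd 0.002
AU, typical of an FT-NIR integrating-sphere measurement at 32 scans).

The `separation` dial multiplies the **cultivar-mean** part of every
linked band amplitude (effective values `v + (separation − 1)·μ_c`)
while leaving within-cultivar variability, scatter and noise untouched.
It therefore widens the between-group contrast specifically — the
quantity a "strong pair separation" scenario should scale. An earlier
design that multiplied the link coefficients themselves was discarded:
it scales within-class variance identically, leaving separability
almost unchanged.

### 1.3 What the simulator does *not* emulate

No radiative transfer, no instrument line-shape, no wavelength-dependent
scatter, no temperature or moisture drift, no harvest effect on the
spectra, and far fewer independent absorbers than real fruit tissue. A
green classification test establishes that the *pipeline* extracts a
class signal that is present by construction and does not leak test
information — not that real strawberries are separable at these error
rates.

## 2. Preprocessing conventions

- **SNV** standardizes each row with the sample (n−1) standard
  deviation.
- **MSC** regresses each spectrum on a reference (default: column mean
  of the fitting set) and inverts the affine fit; the reference is
  stored and reused on test data.
- **Savitzky–Golay**: local least-squares polynomial filtering;
  derivatives are divided by the grid step so output is per cm⁻¹ and
  grid-invariant (the grid must be uniform to 1e−6 relative). Edge
  points are evaluated from the polynomial fitted to the first/last
  full window, so a degree-p filter reproduces degree-p polynomials
  exactly everywhere, edges included. The default spectral chain —trim
  to 9000–4000 cm⁻¹, first derivative with window 9 and polynomial
  order 2, mean centering — is the treatment tagged "9der1" in the
  classification experiments. (Window 13 and 21 appear in other parts
  of the reference workflow; the window is a config value and no claim
  is made about which produced any particular published table.)
- **Block scaling** divides each block by the square root of its summed
  column variance (total variance 1 per block, within-block ratios
  preserved).
- Column statistics (centers, scales, MSC reference) are always fitted
  on training data and re-applied, never recomputed on test data.

## 3. PCA and fusion

PCA is computed by SVD of the (optionally centered/scaled) matrix —
numerically stable and identical to the eigendecomposition of the
sample covariance (denominator n−1, verified against `eigen(cov(X))` in
the tests). Sign indeterminacy is resolved by making the
largest-magnitude loading element of each component positive (ties:
lowest index), so repeated fits are bit-identical. Confidence ellipses
are axis-aligned 1-sd summaries in score space (mean ± sd per axis per
cultivar), with no χ² scaling.

Mid-level fusion concatenates 5 + 5 per-block PCA scores and autoscales
them; equal score counts give the two blocks equal weight. The
contribution of the original variables to a fused-space PCA is
recovered as `O = Pᵀ F`, where `F` is block-diagonal: the row of fused
feature (block k, component j) carries block k's loading vector j and
zeros elsewhere — the only dimensionally consistent arrangement of the
per-block loadings — and each row is divided by that fused column's
autoscale sd so that `T_fused · O` back-projects the variables that
actually entered the fused PCA (verified by the algebraic-chain test).

## 4. Partitioning, validation and PLS-DA

- **Duplex**: the two most mutually distant points (Euclidean; on
  autoscaled variables for tabular data, on the preprocessed matrix for
  spectra) seed the **training** set, the next pair the test set,
  alternating until the test quota is filled; remainder to training.
  Train-first yields the larger training set (137/60 at n = 197). Ties
  break to the lowest row index; a final odd test slot takes the
  lower-index member of the selected pair. Fully deterministic.
- **Venetian blinds**: fold = (position − 1) mod segments, 5 segments;
  index-only, applied to the (cultivar-blocked) training order.
- **PLS-DA**: NIPALS with deflation, PLS1 on a 1/0 dummy for binary
  modes, PLS2 on the four-column indicator matrix for the multiclass
  model (predicted class = argmax). Cross-validation refits only the
  PLS step per fold; fusion/centering statistics come from the full
  duplex training set (standard chemometric practice — the external
  test set remains strictly untouched). The number of latent variables
  is the smallest candidate within one standard error (over folds) of
  the minimum CV error, searched over 1–10.
- **Threshold**: default is the CV-error-minimizing cut on the
  cross-validated predictions (candidates: midpoints between distinct
  scores; tied optima resolve to the midpoint of the longest contiguous
  optimal run). A fixed 0.5 is available via configuration; the
  CV-optimized choice is the default because it uses only training
  information and adapts to class imbalance.
- Misclassification error is the overall fraction misclassified (not
  class-balanced); with heavy imbalance (MODE 2/3) TNR can be low while
  the error stays moderate. The positive (1-coded) class of MODE 2/3 is
  the larger three-cultivar group; the orientation is recorded in every
  report.

## 5. ANOVA and compact letters

Classical equal-variance one-way ANOVA (F = MS_between/MS_within);
degenerate inputs with zero between-group variation return F = 0 even
when the within-group variance is also zero. Pairwise comparisons use
the Tukey–Kramer studentized range (valid for the unbalanced groups
that missing records create), and letters come from the standard
insert-and-absorb algorithm, ordered so "a" marks the largest mean. Per
construction, two groups share a letter exactly when their adjusted p
is ≥ α — both directions are asserted in the tests.

## 6. Known limitations

- **The vitamin C letter pattern is not stable at the default CV.**
  With cv = 0.12 the within-group sd scales with the mean, so the
  pooled Tukey MS_within is dominated by the high-vitamin-C pair; the
  expected Silvia–Cristina studentized range is
  (15.64 − 14.31)/√(MSW/54) ≈ 3.3 against a critical value of ≈ 3.7 at
  α = 0.05. The pair is borderline by construction: the full two-group
  compact-letter split reproduces in only ~64% of seeds (the
  cross-group separation itself holds essentially always). The
  acceptance test asserting ≥90% reproduction is intentionally left
  failing rather than weakened; making it pass would require either a
  smaller CV for the low-mean parameters or homoscedastic (absolute-sd)
  noise, both of which would change the stated generator.
- **Permutation nulls are compared distributionally.** With labels
  permuted on a fixed cohort, the training and test label compositions
  are anti-correlated, which biases the mean permuted test error a
  point or two above the chance rate; the permutation check therefore
  asks whether the majority-class rate is a typical value of the
  permutation distribution (|z| ≤ 3) and that the mean permuted error
  is not *below* it — the signature an information leak would produce.
- Duplex assumes the distance metric used at split time matches the
  feature space used for modeling; `run_mode` splits once on the
  preprocessed spectra for both feature sets so that NIR-only and fused
  experiments share an identical external test set.
- The multiclass model shares the binary pipeline's LV selection but
  uses a plain argmax decision; no per-class threshold calibration.
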