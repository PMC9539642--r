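---
title: "Multi-trait NIRS calibration with modified PLS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait NIRS calibration with modified PLS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirscal)
```

## The problem

Near-infrared reflectance spectroscopy (NIRS) predicts chemical
composition from absorbance spectra, `log(1/R)` recorded here on a
400–2498 nm grid at 2 nm steps. For seed germplasm work the goal is a
calibration equation per nutritional trait (protein, starch, total
dietary fiber, phenols, phytic acid; g/100 g) good enough to replace
wet chemistry for screening. `nirscal` implements the full workflow:
diverse-sample selection, spectral pretreatment, modified-PLS
calibration with cross-validation, external validation statistics, and
the applicability checks used when a validated model is turned loose on
new accessions. A synthetic spectra generator makes every stage
testable end to end at desk scale.

## Pretreatment

Scatter correction and derivative "math treatments" are applied per
spectrum before regression.

**SNV.** Standard normal variate centres each spectrum and scales it to
unit SD. We use the population (n-denominator) SD; the choice is
arbitrary but fixed, and affine invariance `snv(a*x + b) = snv(x)`
holds either way.

**SNV–DT.** After SNV we subtract the least-squares quadratic in
wavelength and then re-standardise to mean 0 / SD 1. The final
re-standardisation is deliberate: subtracting the quadratic changes the
per-spectrum scale by an amount that depends on the (sample-specific)
baseline tilt, so without it two spectra differing only by gain,
offset and linear tilt would come out proportional rather than equal.
With it, the correction cancels that nuisance family exactly — the
generator's zero-noise scatter-removal test verifies agreement to
1e−8.

**Gap-segment derivative.** Treatments are coded "d,g,s1,s2"
(derivative order, gap, two smoothing segments, all in data points),
e.g. `"2,4,6,1"`. The exact convention of the commercial software that
popularised these codes is proprietary, so we declare ours and freeze
it with tests: boxcar running mean of segment `s1` (even segments round
up to the next odd width), then `d` applications of the central gap
difference `D[x]_i = x[i + ceiling(g/2)] − x[i − ceiling(g/2)]`, then a
boxcar of segment `s2`. `s2 = 1` means no second smoothing. Edges
without full support are truncated, never padded; the output grid
shrinks by a deterministic margin per edge
(`treatment_margin()` documents and tests the formula). Because the
regression is refit after treatment, any consistent convention yields
an equivalent pipeline; what matters is that it is fixed.

## Modified PLS

The calibration engine is PLS1 with the Shenk–Westerhaus modification:
before each factor is extracted, the current spectral residual matrix
is standardised per wavelength, so the covariance with the trait is
computed on scaled residuals. Per factor `a`: wavelength SDs `s_a` of
the X-residual (floored at 1e−12, below which the scaling is 1);
loading weight `w_a ∝ (X'y)/s_a` normalised to unit length; scores
`t_a = X w_a`; loadings `p_a, q_a` by least squares; deflation of both
X and y. With the scaling disabled this is exactly standard PLS1 — the
central correctness property, tested against an independent
Dayal–MacGregor kernel-PLS oracle (different algebra: no deflation of
X) to 1e−8 on random instances.

**Factor choice.** Cross-validation with 4 systematic groups (index
modulo 4), `SECV(a) = sqrt(sum(e_cv^2)/n)`, chosen `A` at the SECV
minimum with ties to the smaller `A`. `A_max` defaults to
`min(16, floor(n/6))`, and the search stops early if a fold exhausts
the data rank (noiseless mixtures of k constituents are exactly rank
k). The SECV denominator is n, not n−1; nothing downstream depends on
the choice.

**Outliers.** After fitting, residuals are standardised by the SEC;
samples with `|t| > 2.5` are dropped (largest first), at most 2 removal
passes and at most 10 removals in total — the "few outliers" practice
of routine NIRS calibration. Score-space leverage (GH) is reported for
every removal but never triggers one: gross errors here come from
scanning or analytical mistakes, which show up in y-residuals.

## Validation and applicability statistics

External validation reports RSQ (squared Pearson correlation), bias
(`mean(pred) − mean(ref)`; positive = overestimating model), slope
(reference on predicted, `cov/var(pred)`; the direction is a
config flag because the verbal definition in common use is ambiguous),
SEP (bias-corrected, n−1 denominator) with the raw RMSEP alongside, and
RPD = SD(ref)/SEP with the conventional quality bands at 1.5/2.0/2.5/
3.0 (boundaries assigned upward: RPD = 2.5 is "good", 3.0 is
"excellent"). SEP is bias-corrected precisely so that the identity
RPD·SEP = SD holds — which is also how published tables of these
statistics can be checked for internal consistency from print alone.

The paired t-test on reference − predicted uses df = n − 1 and the
two-sided p; the applicability stage adds Pearson correlation (with
its t-transform p-value) and strict-parallel reliability between
predicted and laboratory values on a verification subset (every 11th
of the rank-ordered predictions, positions 1, 12, 23, …, which yields
`ceiling(n/step)` samples — 19 from 202).

**Strict-parallel reliability.** The two "items" (prediction,
laboratory value) are modelled as sharing one mean, one true-score
variance and one error variance; item-mean differences are charged to
error. Writing `M` for the n-denominator second-moment matrix about the
common fitted mean, `m1` for its component along the unit vector and
`m2` for the orthogonal remainder, the ML estimates give scale
reliability `1 − m2/m1` in closed form. Tests verify the closed form
against direct numerical maximisation of the Gaussian likelihood to
1e−6. Published reliability tables of this kind are often produced by
closed-source software whose exact variant (ML vs "unbiased"
small-sample corrections) is unrecoverable; on the bundled study's
verification pairs our ML estimate for protein is 0.89 against a
printed 0.91, and the test asserts the [0.85, 0.95] band rather than
exact agreement.

## Sample selection and splitting

`ward_select_diverse()` emulates the scan-then-select stage of
germplasm campaigns: SNV-normalised spectra, Ward linkage on squared
Euclidean distances, dendrogram cut at a height threshold (default 5,
meaningful on normalised spectra) or a fixed cluster count,
representatives per cluster proportional to size — medoid first, then
max-min distance — fully deterministic.

`rank_order_split()` sorts by trait value and assigns the repeating
pattern C,C,V. The source workflow's verbal description ("every second
value") conflicts with its stated 2:1 ratio and realized 81/40 counts;
the counts are binding, and C,C,V reproduces them exactly. Ties break
by sample id. Splits are per trait, since each trait sorts the samples
differently.

## The synthetic generator

`simulate_concentrations()` draws truncated-normal trait values with
the means, SDs and ranges observed across a diverse cowpea panel
(protein 24.0 ± 1.54 g/100 g in [19.4, 27.9], etc. —
`default_trait_specs()`), by rejection sampling capped at 1000 tries.
`simulate_spectra()` builds clean spectra as Beer–Lambert mixtures of
Gaussian bands at standard assignments (protein 2055/2180 nm in the
C–O/N–H combination region, starch 1934/2100/2482 nm, fiber
1196/1736/2310 nm, phenols 1450 nm, phytate 1600/1468 nm), with widths
of 16–28 nm typical of combination-region bands. Width matters: a
second gap-derivative over an 8 nm span attenuates a band
quadratically in (span/width), so 40 nm-wide bands would lose ~97% of
their signal while white noise passes through unattenuated.

Two modelling choices deserve emphasis:

* **Compositional closure.** A remainder constituent
  (`100 − sum(traits)` g/100 g: moisture, soluble carbohydrates,
  lipids, ash) absorbs through broad matrix bands
  (`default_matrix_bands()`). This is not cosmetic. SNV removes each
  spectrum's intensity scale, so from scatter-corrected spectra alone
  only band-intensity *ratios* are observable; with unconstrained,
  independent concentrations, absolute g/100 g values are
  unidentifiable in principle. Real trait data are compositional —
  closure to the 100 g basis is what ties ratios back to absolute
  concentrations, and the generator reproduces exactly that mechanism.
* **The nuisance model.** Observed spectra are
  `alpha*clean + beta + delta*tilt + noise` with per-sample gain
  `alpha ~ N(1, 0.05)`, offset `beta ~ N(0, 0.02)`, linear tilt
  `delta ~ N(0, 0.02)` and iid point noise defaulting to 2% of the
  median clean absorbance. This is precisely the family SNV–DT is
  designed to remove, which makes the pretreatment stage meaningfully
  testable: at zero noise, removal must be exact.

What the generator does *not* emulate: wavelength-correlated (pink)
instrument noise, nonlinear detector response, particle-size scattering
beyond a multiplicative gain, water-activity band shifts, temperature
effects, and reference-method error in the trait values. Passing the
recovery tests therefore shows the pipeline is correct and
well-conditioned under its stated assumptions — not that any real
instrument will reach the same figures.

## Problem sizes and determinism

The shipped tests run the full design at the study scale where it is
cheap (121 samples × 1050 wavelengths for recovery; 180 × 350 for the
selection stage; 10 000 draws for distribution moments) and at reduced
grids for property sweeps (noise monotonicity at 48 × 350). Every
stochastic step is seeded; `make_study()` under a fixed config is
bit-reproducible, and the pipeline stages rewrite byte-identical
artifacts under the same config and seed.

## Known limitations

* The JCAMP-DX reader accepts only single-block AFFN
  `(X++(Y..Y))` records — enough for instrument exports of single
  spectra, nothing more.
* MPLS wavelength scalings are recomputed per factor from residual SDs;
  no down-weighting by wavelength-error variance estimates from
  replicate scans (the classical extension) is implemented.
* The slope statistic's direction convention differs between software
  packages; ours defaults to reference-on-predicted and is switchable,
  but comparisons across published tables should check which was used.
* `ward_select_diverse()` recomputes a full distance matrix; fine to a
  few thousand samples, not for tens of thousands.
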