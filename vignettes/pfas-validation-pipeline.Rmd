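---
title: "Models and methods of the PFAS quantification and validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the PFAS quantification and validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasval)
```

## What this package models

Targeted PFAS analysis of produce by MRM LC–MS/MS rests on a chain of
deterministic rules applied to integrated peak areas: isotope-dilution
response ratios, procedural-blank subtraction, matrix-fortified calibration,
ion-ratio/retention-time identity confirmation, two alternative limits of
quantification, and recovery/precision validation statistics. None of these
steps needs instrument data to be specified or verified — what they need is a
forward model of the measurement with known truth. `pfasval` implements both:
the rules, and a seeded generator for synthetic batches with the statistical
structure the rules assume.

## The forward model

For analyte $a$ with true concentration $c$ (spike + endogenous + blank
contamination, ng/kg) in a sample of matrix category $m$, the simulated
quantifier area is

$$A_{a} = c \cdot s_a \cdot R_{a,m} \cdot M_m \cdot \varepsilon,$$

where $s_a$ is the detector response slope (area per ng/kg), $R_{a,m} \in
(0,1]$ the absolute preparation recovery, $M_m > 0$ the ionization matrix
effect, and $\varepsilon$ a unit-mean lognormal multiplier with coefficient
of variation `noise_cv`. Qualifier and pseudo transitions are scaled by
their ion-fraction ratio to the quantifier and draw independent noise;
retention times get Gaussian jitter shared by all transitions of one
compound in one sample (they are one physical peak). Internal standards are
generated at 5 ng/kg-equivalent — 50 µL of a 1 ng/mL mix into 10 g of
sample — and share $R$ and $M$ with the sample, which is exactly why the
response ratio cancels both. Injection standards are added after cleanup and
bypass $R$; procedural blanks contain only the contamination level and see
neither $R$ nor $M$ (there is no matrix in them).

A multiplicative (lognormal) error model was chosen because analytical
variability in this field is reported as relative standard deviations, which
is the signature of multiplicative noise. The mean is fixed at 1 so that
recovery statistics are unbiased by construction and any observed bias in
tests is attributable to the rules under study.

Defaults emulate the validation conditions of a produce PFAS method:

* matrix categories `leafy`, `bulb_leek`, `root`, `fruit`, `other`, each
  validated as one batch of a 12-level MFS ladder (0, 0.5, 1, 2.5, 5, 10,
  25, 50, 100, 500, 1000, 2000 ng/kg), six matrices × (unspiked + spikes at
  2.5, 50, 500 ng/kg), and duplicate procedural blanks;
* absolute recoveries between 0.32 and 0.79 with bulb vegetables lowest and
  long-chain compounds (≥ C12) penalized (surface adsorption); matrix
  effects from 0.32 (bulb/leek, suppression) to 1.57 (leafy, enhancement);
* procedural-blank contamination of 5 ng/kg for PFOA and 0.5 ng/kg for PFNA,
  zero elsewhere;
* `noise_cv = 0.10`, retention-time jitter sd 0.01 min, chromatographic peak
  sd 0.05 min, baseline noise sd 20 area units.

The optional `analyte_bias` parameter multiplies analyte signals in the
validation matrices but *not* in the MFS calibrants or blanks. It models a
surrogate-IS mismatch between matrices: a bias shared by calibrants and
samples would be absorbed by the calibration line and is therefore not a
validation failure mode. A bias of 1.4 with a 40 % analyte CV reproduces the
behaviour of an analyte lacking a fitting internal standard, which the
classifier must demote to qualitative use.

What the generator does **not** emulate: chromatographic drift and
carry-over between runs, heteroscedastic detector saturation at the top of
the calibration range, matrix-by-analyte interactions beyond the chain-length
penalty, day effects (each category is one batch), and real blank-level
variation between days. Passing tests therefore demonstrate the correctness
of the rules under the stated measurement model, not method performance on
real extracts.

## Peak processing

Raw traces are rendered as Gaussian peaks of the tabulated area on a white
noise baseline. Integration searches the apex on a 5-point moving average
(smoothing only for apex location; the integral is computed on the raw trace
to avoid area bias), estimates the Gaussian $\sigma$ from the full width at
half maximum, integrates trapezoidally between apex ± 4σ, and subtracts a
straight baseline between the bound intensities. Bounds at ± 3σ were
considered and rejected: together with the baseline chord they clip about 3 %
of a Gaussian's area, while ± 4σ reduces the bias to ≈ 0.1 %, inside the 1 %
agreement with the analytic integral that the test suite enforces. When the
half-height width cannot be bracketed, valley-to-valley bounds are the
fallback. Baseline noise is the sd of the trace outside apex ± 5σ after
median centring; S/N is apex height over that sd, and peaks below 3 × noise
are reported *not found* (absence, distinct from a found zero-area peak).
A coeluting interference inside the bounds is deliberately not deconvolved —
contaminating the area is precisely the failure mode the ion-ratio rule must
catch, and the test suite exercises that path with a TDCA-like peak on the
PFOS 499>80 qualifier while quantification rides on the selective 499>99
channel.

## Quantification choices

**Weighting.** The ladder spans four decades; unweighted least squares would
be dominated by the 500–2000 ng/kg levels. `1/x` weights make relative
errors comparable across levels. The 0 level has no defined `1/x` weight and
enters with weight 1, informing the intercept.

**Segments.** "Lower or higher end of the calibration line" is implemented
as two fixed overlapping segments, 0–100 and 50–2000 ng/kg, selected per
sample from a provisional full-range fit (≤ 100 → low). The overlap
guarantees every concentration is bracketed; above 2000 the high segment is
used with an extrapolation flag.

**Blank correction** operates in response-ratio space (consistent with
correcting by the *average response* of the blanks) and subtracts the
arithmetic mean of the duplicate blanks per analyte. Negative corrected
responses are retained and flagged; clipping at zero would bias apparent
recovery upward at the 2.5 ng/kg level. The subtraction is exact: adding any
constant response to all samples and blanks leaves every quantified
concentration unchanged, which the tests assert.

**Reference values.** The confirmation references (mean ion ratio, mean
relative retention time) are averaged only over calibrants whose qualifier
has S/N ≥ 3; the lowest levels would otherwise corrupt the reference with
ratios of noise.

## Confirmation and limits

The 30 % ion-ratio and 1 % RRT bounds are read inclusively ("should not
deviate more than" taken literally), with a `1e-9` float guard so that
exact-boundary observations such as 1.01/1.00 pass as intended. Whether the
guidance intends inclusive bounds is genuinely open; inclusive is implemented
and documented here. Single-product analytes (PFPeA) are confirmed through
their precursor→precursor pseudo transition and flagged `pseudo-ratio` —
usable, but short of two-diagnostic-ion guidance.

The LOQ branch selector needs a numeric meaning of "substantial blank
signal"; none is standard, so the package uses blank concentration
\> 0.3 × the lowest nonzero calibration level (0.15 ng/kg with the default
ladder), reusing the 30 % idea of the blank-contribution rule. Raw 3.3×-blank
LOQs are snapped *up* to the calibration grid because reported LOQs sit on
the grid (quantification below the lowest supporting calibrant is not
defensible); a 5 ng/kg blank thus yields 16.5 → 25 ng/kg. The LOC is floored
at the LOQ. The reconciliation of a determined LOQ against spiked validation
results ("adjusted accordingly if needed") is interpreted as: if the lowest
spike level at or above the LOQ fails the recovery/precision criteria, raise
the LOQ to the next passing spike level and flag it.

## Validation statistics

RSDs use the n−1 sample standard deviation over the absolute mean. RSDr
pools the six different matrices within a category — an intentional
overestimate of true repeatability, stressing the method across matrix
diversity — and RSD_RL pools all 30 spiked samples per level. Recovery
baseline correction uses the unspiked result of the same matrix when it
exceeds the analyte's LOQ, else the procedural-blank level. Classification
evaluates only spike levels at or above the analyte's largest category LOQ:
levels below the LOQ report absence and carry no quantitative weight (this
is why a blank-contaminated analyte has no 2.5 ng/kg row in its verdict).
The 65–135 % / ≤ 25 % criteria are inclusive. The IS-stability screen is a
fixed-effects one-way ANOVA (`stats::oneway.test`, equal variances) on
per-measurement IS signal RSD groups; the tests verify its F statistic
against hand-computed sums of squares and its type-I error calibration
(0.05 ± 0.02 over 2000 null simulations).

## Problem sizes and determinism

The default test and acceptance workloads are desk-scale by design: one
category batch is 38 samples × 54 transitions, the full five-category
campaign (190 samples, n = 30 per spike level) runs in a few seconds, and
trace-level tests render only the transitions they need. Every stochastic
step flows from an explicit integer seed (`withr::with_seed`); identical
seeds give byte-identical tables, and the pipeline derives one sub-seed per
category from the master seed.

## Known limitations

* LOD is not computed — the two-branch scheme defines LOQ and LOC only, and
  no defensible LOD formula is part of this design.
* Quadratic calibration, standard addition and cross-day calibration
  transfer are out of scope; so are vendor raw files (the extension point is
  the long-format trace schema) and exposure assessment downstream of the
  occurrence tables.
* The transition m/z values, ion fractions and retention times in
  `build_default_panel()` are editable fixture values representative of the
  compound class, not instrument constants; swap in your own panel for real
  work.
* Occurrence frequencies count confirmed detections only; unconfirmed
  above-LOQ results are available in the records but reported separately.
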