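---
title: "Methods: the dermatofluoroscopy analysis model"
author: "dermafluor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dermatofluoroscopy analysis model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermafluor)
```

# The measurement and the diagnostic problem

Dermatofluoroscopy scans a pigmented skin lesion (PSL) point by point with
nanosecond 800 nm laser pulses and records, at every position, an emission
spectrum over 380--680 nm.  Stepwise two-photon excitation makes the
normally ultra-weak melanin fluorescence detectable, so the spectra are
melanin-dominated, with contributions from NAD(P)H, keratin and the
frequency-doubled excitation line (second-harmonic generation, SHG) of
dermal collagen at 400 nm.  A scan collects several hundred spectra; each
is classified into a *spectral type*, and the per-spectrum calls are
aggregated into a lesion score with an excision recommendation above a
fixed cut-off.

The diagnostic difficulty this package models is the differential between
seborrheic keratosis (SK) --- a very common benign lesion that can mimic
melanoma clinically --- and cutaneous melanoma (CM).  Three spectral
phenotypes carry the signal:

* **SK type**: suppressed SHG line (the focus never reaches intact dermal
  collagen through the acanthotic/hyperkeratotic epidermis) and a very
  intense blue-green band at 450--490 nm peaking at 475 nm, dominated by
  keratin with an NAD(P)H shoulder;
* **CM type**: monotonically rising intensity from 430 to 650 nm
  (melanin), low autofluorescence, suppressed SHG;
* **nevus type**: an intense SHG line at 400 nm over weak autofluorescence.

No spectra from the clinical study are deposited, so the package ships a
synthetic-data module that emulates these phenotypes; everything downstream
(preprocessing, typing, unmixing, scoring, evaluation) runs identically on
real spectra supplied in the package's text format.

# The fluorophore forward model

A spectrum is composed as a nonnegative linear mixture of four
unit-maximum basis shapes on the default 380--680 nm, 1 nm grid:

| basis   | shape          | position            | width (default)   |
|---------|----------------|---------------------|-------------------|
| SHG     | Gaussian line  | excitation/2 = 400 nm | sd 5 nm         |
| NADH    | Gaussian band  | 450 nm              | FWHM 75 nm        |
| KERATIN | Gaussian band  | 470 nm              | FWHM 120 nm       |
| MELANIN | logistic tail  | max at 680 nm       | onset 520 nm, softness 60 nm |

The peak positions are measured anchors: the SHG line is observed at half
the 800 nm excitation wavelength, pure NADH (solid phantom) peaks at
450 nm and pure nail keratin at 470 nm.  The *shapes* and *widths* are
model choices --- no bandwidths were measured --- fixed once so that every
documented constraint holds simultaneously.  The keratin width deserves a
note: the SK composite must peak at 475 nm although its dominant keratin
basis peaks at 470 nm, the shift being produced by the rising melanin
tail.  The melanin weight needed for a 5 nm shift is inversely
proportional to the keratin curvature at 475 nm, so a narrow keratin band
(FWHM 70 nm) demands so much melanin that the SK red band (550--650 nm)
grows as large as its blue band, which contradicts the defining
blue-dominance of the SK phenotype.  With FWHM 120 nm the calibrated
melanin weight is modest and the SK blue/red ratio stays near 1.8.  A
margin search over keratin FWHM (100--130 nm), NADH FWHM (60--90 nm) and
the template weights selected the shipped combination as the one
satisfying all constraints with the largest margins.

## Template calibration

The SK melanin weight is the only fitted constant of the forward model.
`calibrateSkMelaninWeight()` performs the documented one-dimensional
bisection: it finds the interval of melanin weights for which the SK
composite argmax over 430--520 nm equals 475 nm both for the raw template
and after the span-40 smoothing used by feature extraction (the two
conditions overlap on roughly [0.68, 0.70]), and returns the midpoint.
The frozen result, 0.6898, is checked against a fresh run of the search by
the test suite.

```{r calibration}
peakWavelength(composeTemplate("SK"), c(430, 520))
templateWeights("SK")
```

Template brightnesses are relative scales: the SK blue band is set to
exactly ten times the nevus blue band --- the upper end of the reported
contrast between SK and nevus/melanoma intensities --- and melanoma sits
between the two.  The hyperkeratotic reference template carries no NAD(P)H
(terminally differentiated corneocytes do not metabolize) and a melanin
weight of 0.60; the latter is what makes the difference-spectrum procedure
(below) isolate an NAD(P)H bump rather than a residual melanin ramp.

# The synthetic cohort generator

`generateLesion()` draws each spectrum's source template from a
per-diagnosis mixture, replaces it with probability 0.05 by a low-SNR
spectrum (the fraction removed in practice), scales by a detector-counts
factor (default 2000) and adds heteroscedastic Gaussian noise with
standard deviation `noiseLevel * sqrt(counts + 1)` --- a Poisson-like
count-noise surrogate, clipped at zero; the true noise process of the
instrument is not described anywhere, so this is an invention.  The
default mixtures (e.g. an SK lesion is 70% SK-template, 20% uninformative
background, 8% nevus, 2% CM) are calibration constants chosen once so that
benign lesions score well below the cut-off and melanomas well above it;
per-lesion compositions of real scans were never published.  The default
cohort mirrors the study: 28 SK, 5 nevi, 24 CM.

Determinism: every lesion is reproducible from its seed, and a cohort
derives per-lesion seeds from the master seed by the fixed counter scheme
`seed_i = (master + 7919 i) mod (2^31 - 1)`.

What the generator does **not** emulate: lesion geometry and scan raster,
melanin concentration gradients, Fitzpatrick skin-type effects, detector
spectral response, cosmic spikes, and any within-lesion correlation
between neighbouring spectra.  Consequently, the package's perfect
end-to-end sensitivity/specificity on synthetic cohorts is a
*generator-calibration consistency check* --- it shows the chain is
internally coherent, not that the clinical accuracies (91.7% sensitivity,
83.0% specificity, 97.0% benign-cohort accuracy) are reproduced; those
require the patients' spectra.

# Preprocessing

* **Smoothing** --- centred moving average with span 40 grid points.  The
  span is read as grid points (40 nm at 1 nm sampling); an even span is
  symmetrized to the odd 41-point window so the filter stays centred, and
  at the edges the window shrinks symmetrically to the largest centred
  window that fits.  Interior sums are preserved to well under 0.5% for
  broad-band spectra; a narrow line within one window of an interior
  boundary (the SHG line at 400 nm) necessarily leaks mass across it.
* **SNR rejection** --- the device removes spectra whose signal-to-noise
  ratio is too low, around 5% of them, but defines neither the statistic
  nor the threshold.  The package defines SNR as the mean smoothed signal
  over 430--650 nm divided by the standard deviation of the smoothing
  residual there (the band excludes the sharp SHG line, whose smoothing
  residual is structural, not noise), with threshold 3.0.  Degenerate
  cases: an all-zero spectrum has SNR 0; a noise-free spectrum with signal
  has SNR `Inf`.  The generator's low-SNR spectra sit near SNR 1, the
  dimmest genuine spectra (nevus) near 11, so the partition is sharp and
  the rejected fraction tracks the 5% contamination rate.
* **Normalization** --- division by the band maximum (the convention used
  for all spectral comparisons), idempotent, error on nonpositive maxima.

# Spectral typing

Features per smoothed, normalized spectrum: mean intensities of the SHG
band (395--405 nm), blue band (450--490 nm) and red band (550--650 nm);
the Spearman rank correlation of intensity versus wavelength over
430--650 nm ("monotonicity"); and the argmax over 430--520 nm.  Rules are
evaluated in order, first match wins:

1. **nevus** --- `shg_band >= 0.75`, `shg_band > blue_band` and
   `blue/red < 1.5`;
2. **SK** --- `shg_band <= 0.45`, `blue/red >= 1.5` and peak in
   450--490 nm;
3. **CM** --- monotonicity `>= 0.95` and `shg_band <= 0.45`;
4. **uninformative** otherwise.

The nevus rule leads because an intense second-harmonic line (intact
dermal collagen within reach of the focus) is the clearest single
discriminator; the `shg_band > blue_band` clause expresses that the line
must be the spectral maximum (without it a featureless flat spectrum would
satisfy rule 1).  The numeric thresholds are calibrated, not measured:
0.45 rather than a lower SHG cut because the broad keratin band itself
contributes ~0.4 at 400 nm in SK spectra; 1.5 rather than a higher blue
dominance because the melanin needed to place the SK peak at 475 nm caps
the attainable ratio near 1.8, while nevus and CM sit at 1.1 and 0.45.
All thresholds are configuration values.

Classification never sees the generator's truth labels: they live in the
scan's column metadata and the classifiers receive only intensities.

A linear SVM (`trainSurrogate()`) can replace the rule backend.  It stands
in for the device's certified classifier, whose feature set and weights
are proprietary; it makes no claim of reproducing the certified device and
is used in the tests as a cross-check that the features separate the
classes (held-out per-class accuracy above 95% at default noise, and over
90% agreement with the rule backend).

# Unmixing and the difference spectrum

`nnlsUnmix()` solves nonnegative least squares onto the basis set
(`pracma::lsqnonneg`).  It operates on raw or smoothed, *unnormalized*
spectra so weights keep the counts scale.  For smoothed spectra the bases
are smoothed with the same span before fitting: smoothing is linear, so a
smoothed mixture is exactly the same mixture of smoothed bases and
noise-free weights remain recoverable to machine precision; fitting
smoothed spectra against raw bases would instead distort the narrow SHG
line's weight by an order of magnitude.  The test suite checks the solver
against an exhaustive nonnegative grid-search oracle on toy instances.

`differenceSpectrum()` reproduces the interpretive subtraction: smooth
target and reference, rescale the reference so its maximum equals the
target's (the maximum is taken over the full wavelength range), subtract.  Subtracting the hyperkeratotic
(keratin-dominated, NAD(P)H-free) reference from the SK template leaves an
excess that peaks at 430--460 nm --- the NAD(P)H contribution --- and a
positive melanin excess over 530--650 nm, the package's in-model
restatement of the fluorophore assignment.

`peakWavelength()` breaks ties toward the shorter wavelength and rejects
bands in which the spectrum vanishes identically.

# Scoring and evaluation

The device documentation fixes only that the score grows linearly with
the count of spectra classified as melanoma-characteristic and that
excision is recommended strictly above 28.  The package defines the score as the
percentage of classified (SNR-accepted) spectra typed CM, on a 0--100
scale: this makes the printed scores (14.4, 16.3, 33.0, 37.5) readable as
percentages and 28 a percentage cut-off, and it is an assumption.
Uninformative spectra stay in the denominator; rejected spectra do not.  A
scan with no accepted spectra is an error, not a score.  The comparison is
strict: a score of exactly 28 is benign.

Cohort evaluation reports per-diagnosis decision accuracy with
percentages recomputed from counts, mean scores with two-sided Student-t
intervals (`n - 1` degrees of freedom --- the conventional interval at
n around 30; no interval is reported for groups of one), and a
dominant-type table: a lesion's dominant type is its most frequent
SK/CM/nevus call, with ties or all-uninformative scans reported as
`NO_DOMINANT`.

# Problem sizes and reproducibility

The test suite exercises the chain at sizes chosen to make the statistics
sharp while keeping a full run around a minute: 10,000-spectrum scans for
the rejection-rate check (binomial tolerance of one percentage point), 500
spectra per class for surrogate training and held-out evaluation, the full
57-lesion cohort at 300 spectra per lesion for end-to-end evaluation, and
1000-replicate Monte-Carlo checks of the noise model.
`scripts/acceptance.R` recomputes the headline quantities from scratch at
the same sizes.

# Known limitations

* The forward model is a four-component linear mixture with fixed shapes;
  real spectra show fluorophore heterogeneity (eumelanin versus
  pheomelanin, FAD, lipopigments) that is absorbed into the broad bands
  rather than modeled.  FAD contributes in this spectral region but has
  no measured peak or bandwidth here, so it has no basis of its own.
* Collagen/elastin fluorescence is omitted (their contribution is argued
  to be minor); only the collagen SHG line is modeled.
* The SNR statistic, the noise model, the per-lesion type mixtures and all
  classification thresholds are package inventions standing where the
  device's proprietary internals are undisclosed; each is a configuration
  value, and conclusions that depend on them should be read as properties
  of this model, not of the instrument.
* Scores of synthetic benign lesions cluster near 2 rather than the
  clinically observed 14--16, because the published aggregate scores do
  not constrain how often benign scans contain isolated melanoma-like
  spectra; only the benign/malignant separation is calibrated.
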