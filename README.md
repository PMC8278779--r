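# dermafluor

Dermatofluoroscopy spectral analysis of pigmented skin lesions in R.

Dermatofluoroscopy excites skin fluorophores *in vivo* with nanosecond
800 nm laser pulses and records, at hundreds of positions per lesion, an
emission spectrum over 380–680 nm. Stepwise two-photon absorption makes
the normally ultra-weak melanin fluorescence detectable, so the spectra
are melanin-dominated, with contributions from NAD(P)H (peak ~450 nm),
keratin (~470 nm) and the second-harmonic (SHG) line of dermal collagen at
half the excitation wavelength (400 nm). The clinically hard case is the
differential between seborrheic keratosis (SK) — a common benign lesion
that can mimic melanoma — and cutaneous melanoma (CM).

`dermafluor` implements the complete analysis chain on synthetic data (no
clinical spectra are deposited), and runs identically on any spectra
supplied in its plain-text format:

* a **fluorophore forward model**: unit-max basis shapes
  (SHG line, NAD(P)H, keratin, melanin rising tail) composed linearly with
  nonnegative weights into the three lesion phenotypes (SK-type, CM-type,
  nevus-type) plus reference spectra (hyperkeratotic skin, healthy
  forearm, pure keratin, pure NADH);
* a **synthetic cohort generator** with Poisson-like count noise, ~5%
  low-SNR contamination and the study's 28 SK / 5 nevi / 24 CM
  composition, fully reproducible from a master seed;
* **preprocessing**: signal-to-noise rejection, span-40 moving-average
  smoothing, maximum normalization;
* **spectral typing** per spectrum — I(400) SHG band, 450–490 nm blue
  band, 550–650 nm red band, Spearman monotonicity over 430–650 nm —
  by an ordered rule set, with a linear-SVM surrogate as cross-check;
* **nonnegative unmixing** onto the fluorophore bases and the
  difference-spectrum procedure (SK minus max-rescaled hyperkeratotic
  reference isolates the NAD(P)H bump at 430–460 nm and the melanin
  excess beyond 530 nm);
* **lesion scoring**: `score = 100 · n_malignant / n_classified`, with an
  excision recommendation iff `score > 28` (strict), and cohort
  evaluation tables (decision accuracy, mean scores with t-intervals,
  dominant spectral types).

## Worked example

```r
library(dermafluor)

## one synthetic seborrheic keratosis, 300 spectra
scan <- generateLesion(lesionRecipe("SK", nSpectra = 300, seed = 42))
parts <- filterLowSnr(scan)          # SNR < 3 is rejected
nSpectra(parts$rejected)
#> [1] 15                             # ~5% low-SNR removals
scoreScan(scan)
#> LesionScore 'SK_seed42': 285/300 classified, 4 malignant, score 1.4 -> BENIGN

## which fluorophores make up the SK phenotype?
nnlsUnmix(smoothSpectra(composeTemplate("SK"), 40))$weights
#>     SHG    NADH KERATIN MELANIN
#>   0.023   0.039   0.771   0.532  # keratin-dominated, melanin shoulder

## a full cohort at the study composition (28 SK, 5 nevi, 24 CM)
ev <- evaluateCohort(generateCohort(cohortRecipe(seed = 1)))
ev$sensitivity; ev$specificity
#> [1] 1
#> [1] 1
ev$typeTable
#>       SK_TYPE CM_TYPE NEVUS_TYPE NO_DOMINANT
#> SK         28       0          0           0
#> NEVUS       0       0          5           0
#> CM          0      24          0           0
```

The lesion score is the percentage of accepted spectra typed as
melanoma-characteristic: the SK scan above keeps 285 of 300 spectra, 4 of
which look melanoma-like, giving score 1.4 — far below the cut-off of 28,
hence `BENIGN`. On the synthetic cohort every melanoma scores ≈45 (mean
45.4, 95% CI 44.1–46.8) and every benign lesion ≈2, so sensitivity and
specificity are both 1.0. That is a consistency check of the generator
calibration, not a reproduction of the clinical accuracies, which require
the patients' in-vivo spectra.

A full pipeline run (simulate → preprocess → classify → score → report,
all tables written to disk) is one call:

```r
runPipeline(defaultConfig(), outDir = "pipeline_output", seed = 1)
```

or from a shell, `Rscript inst/scripts/run-pipeline.R --out out --seed 1`.
Every tunable (grid, basis widths, template weights, noise, thresholds,
cut-off) lives in one YAML config: `writeDefaultConfig("config.yaml")`.

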