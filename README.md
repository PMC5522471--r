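# mibiquant

Quantitative analysis of dual-time-point planar ⁹⁹ᵐTc-sestamibi (MIBI)
thyroid scintigraphy for nodules with indeterminate cytology (Bethesda
III/IV). MIBI washes out of normal thyroid parenchyma faster than out of
nodules, and faster out of benign than out of malignant tissue, so a pair
of planar frames — early (~10 min) and delayed (~60 min) post-injection —
carries diagnostic kinetic information. `mibiquant` implements, tests and
compares the two ROI-based summary indices used for this problem:

- **Wash-out index**, from background-subtracted mean nodular counts
  (background = the nodule ROI mirrored outside the thyroid):

  `WOind = 100 · LR/ER − 100`,  with `ER = n̄_early − b̄_early`,
  `LR = n̄_late − b̄_late`; suspicious when `WOind ≥ −19 %`.

- **Retention index**, from early and delayed nodule-to-normal-lobe
  ratios, each thorax-background-subtracted:

  `R.I. = 100 · (DR − ER)/ER`; suspicious when `R.I. ≥ −11.94`.

The package provides the measurement layer (ROI statistics, ROI mirroring
and early→late copying, physical-decay correction), threshold
classification, diagnostic-performance evaluation with exact binomial
confidence intervals, a packaged 20-patient clinical cohort table, and a
synthetic two-lobe thyroid phantom generator with Poisson counting noise
and closed-form noiseless oracles standing in for the study's
undistributed gamma-camera images.

## Worked example

Classify the packaged clinical cohort with both indices and evaluate
against histology:

```r
library(mibiquant)
reproduce_study()
```

```
Cohort: n=20 (17F/3M), age median 51 (range 20-80), 4 malignant (20%)

Wash-out index, suspicious if >= -19%:
<performance_report> n=20  tp=4 fp=0 tn=16 fn=0
  sensitivity  100.0%  (95% CI 39.8-100.0)
  specificity  100.0%  (95% CI 79.4-100.0)
  accuracy     100.0%  (95% CI 83.2-100.0)
  ppv          100.0%  (95% CI 39.8-100.0)
  npv          100.0%  (95% CI 79.4-100.0)

Retention index, suspicious if >= -11.94:
<performance_report> n=20  tp=4 fp=12 tn=4 fn=0
  sensitivity  100.0%  (95% CI 39.8-100.0)
  specificity   25.0%  (95% CI 7.3-52.4)
  accuracy      40.0%  (95% CI 19.1-63.9)
  ppv           25.0%  (95% CI 7.3-52.4)
  npv          100.0%  (95% CI 39.8-100.0)

Inter-method agreement: 40% of patients
```

The wash-out index separates all 4 cancers from all 16 benign nodules;
the retention index detects every cancer but mislabels 12 benign nodules
as suspicious (it normalises by fast-clearing normal parenchyma, so any
nodule clearing slower than parenchyma drifts positive). The two methods
agree on only 40% of patients. The wide confidence intervals are the
honest price of n = 20.

Simulate a phantom study with known kinetics and quantify it:

```r
ph <- build_phantom(kinetics = kinetic_params(f_nodule = 0.7,
                                              f_parenchyma = 0.5),
                    noise = "poisson", seed = 7)
quantify_study(ph$study)$woind
#> <index_result> WOind = -30.4 (ER 120, LR 83.49)
analytic_index(ph$kinetics, "WOind")   # noiseless truth
#> [1] -30
```

## Analysis workflow

The `analysis/` directory holds the narrative drivers, each writing its
tables under `results/`:

1. `01_simulate_cohort.R` — simulate a 100-patient cohort (20% malignant,
   class-conditional retention kinetics) and write the ground-truth table.
2. `02_quantify_simulated.R` — run the full ROI pipeline on the simulated
   images, classify, and evaluate recovery of the known labels.
3. `03_reproduce_cohort_results.R` — reproduce the clinical-cohort
   evaluation from the packaged table (performance of both indices,
   agreement, demographics).

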