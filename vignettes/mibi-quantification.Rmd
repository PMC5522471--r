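---
title: "Quantifying dual-time-point MIBI thyroid scintigraphy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dual-time-point MIBI thyroid scintigraphy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibiquant)
```

## The clinical problem

Thyroid nodules with indeterminate cytology (Bethesda III/IV) cannot be
resolved as benign or malignant from a fine-needle aspirate, and most
patients who go to surgery for them turn out to have benign disease.
Tc-99m-sestamibi (MIBI) accumulates in mitochondria-rich cells and washes
out of normal thyroid parenchyma faster than it washes out of nodules, and
faster out of benign colloid nodules than out of neoplastic tissue. Imaging
the neck at two timepoints after injection — an early frame around 10
minutes and a delayed frame around 60 minutes — therefore carries kinetic
information that a single image does not.

Two competing ways of condensing that information into one number per
nodule are implemented here.

**Wash-out index (WOind).** Draw a region of interest (ROI) around the
nodule on the early image, mirror it *outside* the thyroid to sample
background, and copy both ROIs onto the delayed image. With per-pixel mean
counts $\bar n_e, \bar b_e, \bar n_l, \bar b_l$:

$$\mathrm{ER} = \bar n_e - \bar b_e,\qquad
  \mathrm{LR} = \bar n_l - \bar b_l,\qquad
  \mathrm{WOind} = 100\,\frac{\mathrm{LR}}{\mathrm{ER}} - 100 .$$

Negative values mean net nodular wash-out; values at or above the published
cutoff of $-19\%$ (limited wash-out, i.e. retention) are called suspicious.

**Retention index (R.I.).** Mirror the nodule ROI onto the contralateral
normal lobe instead, subtract a rectangular thorax-background ROI from
both, and form the nodule-to-normal ratio at each timepoint:

$$\mathrm{ER} = \frac{\bar n_e - \bar t_e}{\bar c_e - \bar t_e},\qquad
  \mathrm{DR} = \frac{\bar n_l - \bar t_l}{\bar c_l - \bar t_l},\qquad
  \mathrm{R.I.} = 100\,\frac{\mathrm{DR} - \mathrm{ER}}{\mathrm{ER}} ,$$

with the published cutoff $\mathrm{R.I.} \ge -11.94$ for a suspicious call.
Because R.I. normalises by normal parenchyma — the compartment with the
*fastest* wash-out — any nodule whose wash-out is merely slower than
parenchyma drifts toward positive R.I., which is exactly how benign
adenomas become false positives under this index.

All computations use per-pixel ROI means, never totals, so ROI size
differences cannot bias either index, and thorax-background "area
correction" is automatic.

## Decision rules and evaluation

Both cutoffs are implemented as *inclusive*: a value exactly at the cutoff
is suspicious. The only inequality printed alongside either published
cutoff is R.I.'s $\ge$, and no patient in the packaged cohort sits on
either boundary, so the choice is a documented convention, not
data-forced. Positive WOind values (net accumulation between scans) are a
fortiori retention and are classified suspicious.

Histology is the reference standard: malignant means differentiated
thyroid cancer; benign adenomas and colloid goitres are benign.
`evaluate()` reports sensitivity, specificity, accuracy, PPV and NPV as
percentages with exact Clopper–Pearson 95% confidence intervals — at
$n = 20$ an interval-free point estimate is uninterpretable, and the exact
method behaves correctly at 0/20 and 20/20. A metric whose denominator is
empty (e.g. NPV when nothing is called benign) is reported as absent with
a reason, never silently as zero.

### A reporting inconsistency in the source cohort

The packaged 20-patient table gives the retention index 4 true positives,
12 false positives, 4 true negatives and 0 false negatives at its cutoff,
which implies specificity $4/16 = 25\%$ and accuracy $8/20 = 40\%$ — and
those counts are corroborated by the same report's own PPV (25%), NPV
(100%), false-positive count (12) and list of four R.I.-benign patients.
The summary figures of 57.1% specificity and 62.5% accuracy that
accompany the original table cannot be reconstructed from it. This package
reproduces the table-consistent values and flags the discrepancy in
`reproduce_study()$notes`; it makes no attempt to reverse-engineer the
irreproducible pair.

## The synthetic phantom

The study's gamma-camera images were never deposited, so the package
generates its own: a 256×256 two-lobe thyroid (elliptical lobes symmetric
about a midline column, an isthmus band, a disc nodule inside the right
lobe) imaged at 10 and 60 minutes with 600 s frames — the acquisition
protocol of the clinical study.

**Kinetic model.** Planar scintigraphy is a projection, so the phantom is
*additive*: each pixel's expected count rate is body background plus, over
the thyroid, parenchyma or nodule activity, and each compartment retains a
fraction $f \in (0,1]$ of its initial rate over the early-to-late interval
(a single-exponential-equivalent description of the 50-minute window).
Background superimposing on the nodule is precisely why the mirrored-
background subtraction works; under this model it is exact, giving the
clean closed forms

$$\mathrm{WOind}_{\mathrm{true}} = 100 f_{\mathrm{nod}} - 100, \qquad
  \mathrm{R.I.}_{\mathrm{true}} = 100\left(\frac{f_{\mathrm{nod}}}{f_{\mathrm{par}}} - 1\right),$$

which `analytic_index()` evaluates through the full region-mean chain.

**Defaults, with units.**

| parameter | default | meaning |
|---|---|---|
| `a0_nodule` | 0.20 counts/px/s | nodule activity at injection; a ~120-pixel nodule ROI collects ~10^4 counts over a 600 s frame |
| `a0_parenchyma` | 0.15 counts/px/s | normal-lobe activity |
| `a0_body_background` | 0.02 counts/px/s | extra-thyroidal background |
| `f_nodule` | 0.70 benign / 0.90 malignant | retention over 10→60 min; noiseless class means WOind −30 / −10, straddling the −19 cutoff |
| `f_parenchyma` | 0.50 | fastest-clearing compartment |
| `f_background` | 0.50 | body background clearance |
| `f_sd` | 0.05 | between-patient spread (truncated normal on (0,1]) |
| `malignant_fraction` | 0.20 | malignancy rate of indeterminate-cytology series |
| half-life | 360.4 min | Tc-99m physical decay, when `apply_physical_decay = TRUE` |

Pixel pitch is 2 mm at magnification 1, so nodule diameters of 15–50 mm
map to disc radii of roughly 4–12 pixels. Counting noise is independent
per-pixel Poisson; no collimator blur, scatter, attenuation or anatomical
variability is modelled. Simulated cohorts therefore exercise the
*pipeline and the decision rules* under realistic counting statistics —
they do not certify performance on real patients, where ROI placement,
organ overlap and physiological heterogeneity dominate.

With the defaults, the per-patient probability of a benign nodule crossing
the −19 cutoff is about 1.4% and of a malignant nodule falling below it
about 3.6% (the kinetic spread, not Poisson noise, dominates: at the
default count scale the measured WOind tracks its noiseless value to
within ~1 percentage point). Label-recovery rates on simulated cohorts
fluctuate accordingly at small $n$.

## Numerical and I/O choices

- **Noiseless frames are exact.** `build_phantom(noise = "none")` returns
  expected-value (real-valued) images rather than rounded integers, so the
  noiseless pipeline can be asserted equal to `analytic_index()` to a
  relative $10^{-9}$; rounding would cap agreement near $10^{-3}$. Such
  frames are refused by the PGM writer rather than silently rounded.
- **Pixel conventions.** Coordinates are 0-based `(row, col)`, row 0 at the
  top. Polygon ROIs use pixel-center membership with the top/left boundary
  inclusive and bottom/right exclusive; mirrored coordinates round
  half-away-from-zero. Early-to-late ROI copying is the identity on equal
  grids and a declared uniform scale (duplicates collapsed) otherwise —
  an undeclared grid mismatch is an error, since the clinical protocol
  acquired the two MIBI frames at two magnifications/matrices without
  recording which was quantified.
- **Decay correction is off by default** and first-class: R.I. is exactly
  invariant to it (same-timepoint factors cancel in each ratio), and WOind
  shifts by the closed factor
  $(\mathrm{WOind}_{\mathrm{corr}}/100 + 1) = (\mathrm{WOind}_{\mathrm{raw}}/100 + 1)\,2^{\Delta t/T_{1/2}}$
  — both relations are asserted in the test suite. The correction
  reference is injection time; any common reference cancels in R.I. and
  changes WOind only through that same analytic factor.
- **Degenerate inputs.** Early nodular counts at or below background raise
  a `NonPositiveNetUptake`-class error (the nodule is not measurable);
  a late nodular mean below background yields WOind < −100 with a
  `deep_washout` flag rather than an error, since deep wash-out is a
  physically meaningful benign-direction finding. Non-positive R.I.
  denominators raise a `DegenerateRatio`-class error.
- **File formats.** Images travel as 16-bit PGM (ASCII `P2` reference
  dialect, binary `P5` accepted) with a JSON sidecar for acquisition
  metadata; ROIs as 8-bit PGM masks or JSON polygons; cohort tables as
  header-keyed CSV with full schema validation. Plain-text formats keep
  every fixture inspectable and diff-able.

## Problem sizes used in the shipped analyses

The `analysis/` drivers and the acceptance checks use: the full
20-patient clinical table; 100-patient simulated cohorts at the default
count scale; 200 Poisson replicates at 100× count scale for the
bias check; and 100 random kinetic parameter sets for the
noiseless-oracle equivalence. Unit tests use a 96×96 phantom with the same
proportions.

## Known limitations

- The phantom's geometry is stylised; it validates arithmetic and decision
  logic, not segmentation or placement of hand-drawn ROIs (which are
  inputs here, as in the clinical workflow).
- Per-patient index values of the clinical cohort are taken from the
  published table; the underlying count data do not exist publicly, so the
  image pipeline can only be validated against the phantom's ground truth.
- Visual (Hurtado-Lopez) pattern scores are carried as inert metadata; no
  formula exists for them.
- DICOM containers are not read or written; the portable PGM + JSON
  sidecar dialect is the package's interchange format.
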