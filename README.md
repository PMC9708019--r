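# tavicap

Prediction of new conduction abnormalities (CA) after transcatheter aortic
valve implantation (TAVI), combining mechanistic contact-pressure
biomarkers with ensemble machine learning.

New left/right bundle branch block (L/RBBB) and permanent pacemaker
implantation (PPI) are common complications of TAVI. The atrioventricular
conduction bundle runs beneath the inferior border of the membranous
septum (IBMS), so compression of that region by the expanding valve frame
is a plausible mechanistic driver. `tavicap` implements, as a tested R
package plus a numbered analysis workflow, the full pipeline around that
idea:

* **Geometry** — parametric aortic root, IBMS landmarks (P1–P3), annular
  plane, and the conduction-system region of interest (ROI): the wall
  patch between the IBMS (extended 25° toward the right-coronary cusp) and
  the plane 15 mm below the annulus.
* **Device mechanics** — a catalogue of eight devices (CoreValve 26/29/31,
  Evolut R/PRO 26/29, Lotus 23/25/27) and a radial-spring equilibrium
  deployment model. At each wall node the linear wall response
  `p_wall(r) = k_eff (r − r_free)` is balanced against the frame's radial
  pressure curve (force-controlled self-expanding frames) or the wall is
  driven to the nominal radius (displacement-controlled Lotus). The
  resulting field yields the two mechanistic biomarkers:
  **Cpmax** (maximum contact pressure in the ROI, MPa) and
  **CPI** (% of ROI area subjected to contact pressure).
* **Synthetic cohorts** — a generator calibrated to the published
  group-conditional statistics of a 151-patient cohort (moment-matched
  truncated normals for mean±SD targets; quantile-matched log-normal for
  Cpmax and logit-normal for CPI; categorical device frequencies; CA as
  the exact union of L/RBBB and PPI labels), plus a mechanistic forward
  mode and a deterministic 151-row fixture for the categorical counts.
* **Machine learning** — the supervised protocol: one-hot + min-max
  preprocessing (training rows only), correlation screen, stratified 70/30
  split with a device-presence constraint, eight base classifiers tuned by
  5-fold CV (KNN, logistic regression, C-SVC, Gaussian naive Bayes,
  SGD-trained linear SVM, gradient boosting, decision tree, random
  forest), bagging (B = 50) and voting ensembles, accuracy-based
  selection, and full reports (confusion counts, sensitivity, specificity,
  PPV, NPV, F1 = harmonic mean of PPV and sensitivity, ROC, AUC with
  bootstrap CI). Companion analyses: mechanistic-feature ablation and the
  L/RBBB-only sub-cohort (PPI excluded).
* **Cohort statistics** — Shapiro–Wilk-gated Welch-t / Mann–Whitney
  comparisons and chi-square / Fisher tests, producing publication-style
  cohort tables.

See `vignettes/methods.Rmd` for the model assumptions, calibration
details, numerical choices and limitations.

## Worked example

The numbered drivers under `analysis/` run the whole study; each prints
its findings and writes tables under `results/`. A condensed session:

```r
library(tavicap)

# 151-patient fixture: published categorical structure, exactly
fx <- fixture_cohort_from_table1()
summarize_cohort(fx)$header$label
#> [1] "All patients (n = 151)" "CA, N = 89 (59%)"  "No CA, N = 62 (41%)"
compare_categorical(rbind(ca = c(50, 9, 30), no_ca = c(33, 15, 14)))
#> device_type: chi_square test, p = 0.04574

# single-patient mechanistic simulation (CoreValve 29, DOI 6 mm)
geo <- cylinder_root_geometry(12.2, k_wall = 0.5,
                              nodules = data.frame(z = 4, theta = 320,
                                                   half_width_deg = 12,
                                                   half_width_mm = 2.5,
                                                   multiplier = 4))
lm  <- landmarks(p1 = 12.2 * c(cos(345*pi/180), sin(345*pi/180), 0) + c(0,0,-1),
                 p3 = 12.2 * c(cos(310*pi/180), sin(310*pi/180), 0) + c(0,0,2.1),
                 rcc_reference_angle = 30)
roi   <- build_roi(geo, lm)
field <- deploy(geo, device_catalogue()[["CV 29"]], doi = 6)
c(cpmax = cp_max(field, roi), cpi = cpi(field, roi))
#>  cpmax    cpi
#>  0.297   40.4

# synthetic twin cohort and the full protocol
co <- sample_cohort_statistical(5000, seed = 2021)
an <- run_primary(co, seed = 2021)
an
#> TAVI conduction-abnormality prediction protocol
#>   outcome: ca   n = 5000 (train 3500 / validation 1500)
#>   selected model: base_rf (accuracy 0.837, AUC 0.901)
ab <- run_ablation(co, seed = 2021, control = list(split = an$split))
an$selected_report$auc - ab$selected_report$auc
#> [1] 0.137   # AUC cost of removing Cpmax and CPI
```

Reading the numbers: the fixture reproduces the published outcome split
(89/151 CA, 59%) and the device–outcome association (p ≈ 0.046); the
deployment example shows an oversized self-expanding frame loading ~40% of
the conduction ROI at ~0.3 MPa peak; on a 5,000-patient synthetic twin the
accuracy-selected model reaches a held-out AUC of ~0.90 (the generator's
Bayes ceiling is ~0.91), and removing the two mechanistic biomarkers costs
~0.14 AUC on the same split — the mechanistic features carry a large share
of the predictive signal.

The calibration self-check (`analysis/03_synthesize_cohort.R`, n = 20,000)
prints, against its targets: CA-group median Cpmax 0.552 MPa [0.55],
CA-group median CPI 27.9% [28], no-CA median CPI 9.9% [10], CA-group mean
DOI 7.26 mm [7.30].

## Layout

```
R/                  package code (geometry, device mechanics, cohort
                    synthesis, ML protocol, cohort statistics, I/O)
src/                compiled KNN scoring kernel (Rcpp)
inst/extdata/       device catalogue and default calibration (YAML)
analysis/01..05     numbered workflow drivers (fixture/stats, deployment,
                    cohort synthesis, model training, ablation/sub-cohort)
scripts/acceptance.R  headline-quantity reproduction script
tests/testthat/     unit, property and acceptance test suites
vignettes/          methods vignette
```
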