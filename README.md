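# haaquant

Quantitative chest-CT detection of interstitial lung abnormalities (ILA)
by high attenuation areas, with the statistical machinery to evaluate how
well a density threshold agrees with visual radiologist assessment.

## The problem

ILA — nondependent ground-glass, reticular or cystic changes affecting
more than 5 % of a lung zone — are usually identified by radiologists
reading chest CTs. Visual reading is slow and reader-dependent, so a
natural question is whether a fully automatic density metric can stand in
for it. The candidate metric is the **high attenuation area percentage**:

```
HAA% = 100 · |{v ∈ lung : −600 ≤ HU(v) ≤ −250}| / |lung|
```

the share of lung voxels whose attenuation falls between −600 and −250
Hounsfield Units, a window that captures ground-glass and reticular
density while excluding aerated parenchyma (≈ −850 HU), emphysema
(< −950 HU, the standard LAA-950 metric) and blood/vessels (≈ +40 HU).
CT-derived total lung capacity is the lung-mask volume in litres.

`haaquant` provides, for R users working on quantitative imaging
biomarkers:

* **densitometry** — lung segmentation (threshold + 3-D connected
  components + hole filling, with vessels inside the mask), HAA%, LAA-950
  %, and CT-derived TLC from calibrated HU volumes (NIfTI in/out);
* **phantoms** — synthetic chest volumes with exactly known tissue
  composition, the validation oracle for the densitometry;
* **cohort simulation** — subject tables with configurable logistic
  (three-level visual status), linear (TLC) and additive-genetic
  structure, for parameter-recovery testing of the analysis stack;
* **agreement** — 2×2 contingency tables under two policies for
  "indeterminate" visual reads, Cohen's kappa with an asymptotic p-value,
  sensitivity/specificity/PPV/NPV, rank-based c-statistic, and threshold
  sweeps with Youden's J;
* **association** — adjusted odds of ILA per 1 % HAA, TLC slope in ml per
  1 % HAA, stratified effect-modification estimates with an interaction
  test, and single-variant additive genetic models;
* a **pipeline** runner (`run_pipeline()`, YAML-configurable, plus a thin
  CLI in `inst/cli/haaquant.R`) that goes phantom → densitometry → cohort
  → agreement → association and emits CSV reports.

## Worked example

```r
library(haaquant)

# a 128^3 phantom with 6% ground-glass, segment it, measure it
ph   <- generate_phantom(phantom_spec(ggo_fraction = 0.06, seed = 1))
mask <- segment_lungs(ph$volume)
densitometry(ph$volume, mask)
#> <densitometry> HAA 5.73%  LAA-950 1.78%  TLC 4.10 L  (262619 lung voxels)
ph$truth$true_haa_fraction   # ground truth placed in the phantom
#> 0.06

# a cohort of 2093 subjects; agreement of the >=10% HAA rule with
# visual assessment, counting indeterminate reads as controls
co <- simulate_cohort(cohort_sim_spec(seed = 1))
t2 <- build_contingency(co, threshold_pct = 10,
                        indeterminate_policy = "as_control")
k <- cohen_kappa(t2); sprintf("kappa %.2f (p = %.3g)", k$kappa, k$p)
#> "kappa 0.11 (p = 2.36e-28)"

# adjusted odds of visual ILA per 1% HAA (indeterminates excluded),
# and TLC slope in ml per 1% HAA
fit_ila_logistic(co)
#> <association> odds_ratio = 2.442 (95% CI 2.112-2.823), p = 1.78e-33, n = 1318
fit_tlc_linear(co)
#> <association> ml_per_pct_haa = -355.549 (95% CI -375.989--335.108), p = 7.83e-203, n = 2093
```

The kappa of 0.11 despite a strong adjusted odds ratio is the central
phenomenon here: HAA% is robustly *associated* with visual ILA, yet a
hard HAA threshold *agrees* with the visual label only slightly, because
most of the density distribution overlaps between groups.

Printed 2×2 tables from published visual-vs-threshold comparisons can be
fed in directly:

```r
t <- contingency_2x2(a = 5, b = 158, c = 21, d = 1909,
                     indeterminate_policy = "as_control")
round(cohen_kappa(t)$kappa, 2)         #> 0.03
round(100 * diagnostic_panel(t)$ppv)   #> 19
```

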