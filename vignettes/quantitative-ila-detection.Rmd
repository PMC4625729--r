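---
title: "Quantitative ILA detection: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ILA detection: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haaquant)
```

# The measurement model

All quantities are functions of the HU histogram inside a lung mask.
For a calibrated volume $V$ and lung mask $L$:

$$\mathrm{HAA\%} = 100\cdot\frac{|\{v \in L: -600 \le \mathrm{HU}(v) \le -250\}|}{|L|},
\qquad
\mathrm{LAA950\%} = 100\cdot\frac{|\{v \in L: \mathrm{HU}(v) < -950\}|}{|L|}$$

and CT-derived total lung capacity is $|L|$ times the voxel volume, in
litres. Three numerical conventions are fixed here and exposed as
arguments so their sensitivity can be probed:

* **HAA window endpoints are inclusive** on both ends. "Between −600 and
  −250" does not by itself fix the endpoint semantics; with integer HU
  the choice moves the metric by at most the mass of two single HU bins
  (≈ 0.5 % of the window width in our phantoms).
* **Emphysema is strictly below −950 HU**, the conventional LAA-950
  reading of an "at −950" threshold.
* **The lung mask includes intrapulmonary vessels.** Vessels sit at
  blood attenuation (≈ +40 HU), far above the HAA window, so they are
  excluded from the *numerator* by the HU window itself while remaining
  in the denominator. This matches densitometry practice in which the
  segmentation keeps parenchyma plus central vasculature.

## Segmentation

No standard algorithm is mandated for the mask, so the package uses the
simplest pipeline satisfying the contract above: threshold at −320 HU,
6-connected component labelling (compiled code; volumes are a few million
voxels), removal of components touching the volume border (outside air,
and the trachea which enters from the top face), retention of the one or
two dominant interior components, a ball-radius-2 closing, and 3-D hole
filling. Hole filling is what re-includes vessels and dense ground-glass
in the mask; on noiseless phantoms the result overlaps truth at Dice
≥ 0.99. A volume with no interior air component raises an explicit
"no lung detected" error rather than returning an empty mask.

# The phantom generator

`generate_phantom()` builds a soft-tissue torso (elliptical cylinder,
+40 HU) containing two ellipsoidal lungs (−850 HU parenchyma) and a
tracheal air column, then fills requested fractions of lung voxels with
ground-glass blobs (HU uniform in [−600, −250]), emphysema blobs
(uniform in [−1000, −960]) and vessel capsules (+40 HU), in that RNG
stream order, followed by additive Gaussian noise (clipped to
[−1024, 3071], rounded to integer HU). Two properties make it a usable
oracle:

* **Truth is counted, not assumed.** The per-voxel label map is the
  ground truth; rasterisation error in blob placement is absorbed into
  the truth fractions, and the final blob is trimmed centre-outwards so
  the placed count is exact to one voxel.
* **Geometry lives in voxel units**, so truth fractions are invariant to
  voxel spacing at a fixed grid.

The default grid is $128^3$ at 2.5 mm isotropic spacing — large enough
that one rasterised blob is ≪ 0.5 % of the ~300 k lung voxels, small
enough that a 20-phantom validation sweep runs in about two minutes.
Noise is the phantom's proxy for body habitus: higher image noise pushes
−850 HU parenchyma into the HAA window but (in the absence of
ground-glass) never out of it, so measured HAA% is non-decreasing in
noise SD on ground-glass-free lungs. The phantom is *not* anatomically
realistic — no lobes, no airway tree beyond the trachea, no
reconstruction-kernel texture; its contract is only the HU composition,
which is the only thing the densitometry depends on.

# The cohort generator

`simulate_cohort()` produces the study conditions for parameter-recovery
testing. The key choices:

* **HAA% is a shifted log-normal**, $2.0 + \mathrm{LogNormal}(\log 1.6,\,0.6)$:
  right-skewed, floored near 2 % (fully normal lungs still have some
  density in the window), cohort median ≈ 3.6 % with an upper tail to
  ≈ 15 % — the magnitudes seen in population cohorts, where reported
  medians are 3.3 % among visually normal and 4.6 % among ILA subjects.
* **Visual status is a three-level multinomial logit** with baseline
  "no ILA": $\log\frac{P(\mathrm{ILA})}{P(\mathrm{none})} = \alpha_1 +
  \beta_1\,\mathrm{HAA} + \gamma^\top x$ with
  $\beta_1 = \log(\mathrm{OR_{true}})$ (default OR 2.3 per 1 % HAA), and
  $\log\frac{P(\mathrm{indet})}{P(\mathrm{none})} = \alpha_2 +
  \beta_2\,\mathrm{HAA}$ with a deliberately shallower slope (default OR
  1.35). This parameterisation was chosen over sequential logistics
  because it makes the *exclude-indeterminates* analysis exactly a
  logistic model in the generating parameters — conditioning on
  ILA-or-none cancels the indeterminate term — so CI coverage of the
  true OR is a clean correctness check, while counting indeterminates as
  controls mixes the two slopes and attenuates the fitted OR, the
  direction observed in real cohorts (2.3 → 1.3). The indeterminate
  logit carries no covariate terms; nothing downstream depends on them.
* **Intercepts are calibrated to the marginal composition** of a large
  smoking cohort: $\alpha_1 = -5.6$, $\alpha_2 = -1.49$ give ≈ 8 % ILA,
  ≈ 37 % indeterminate, ≈ 55 % no-ILA at n = 2093. (Covariate terms
  enter the ILA logit, so the intercept is set with them in place.)
* **TLC (ml)** is linear: intercept 5800 (female, at covariate means),
  slope −351 ml per 1 % HAA, age/sex/BMI terms, Gaussian error
  (SD 600 ml), floored at 100 ml; the floor binds on ≪ 1 subject per
  cohort and is negligible for slope recovery.
* **Genotype** is a biallelic variant under Hardy–Weinberg equilibrium
  (default allele frequency 0.11, typical of a common promoter risk
  allele); `genotype_haa_beta` shifts log-scale HAA additively per
  allele and defaults to 0, the null structure against which the
  additive-model test's type-I error is checked.
* **Effect modification** is generated as stratum-specific HAA slopes
  (emphysema < 5 % vs ≥ 5 %, or BMI < 30 vs ≥ 30) rather than an
  explicit interaction coefficient, mirroring how stratified estimates
  are reported; the fitted interaction p-value comes from the pooled
  model's product term.

What passing recovery tests on these cohorts shows: the fitting code is
consistent and its CIs have near-nominal coverage *when the model is
correctly specified*. What it cannot show: robustness to familial
correlation (subjects are simulated independent; mixed-model machinery
for related subjects is deliberately out of scope and ordinary GLMs are
used throughout), to unmodelled confounding, or to the visual-read
error structure of real radiologists.

# Agreement statistics

`cohen_kappa()` uses the marginal-based expected agreement and, for the
p-value, the asymptotic z-test with the large-sample *null* variance
(the variance of $\hat\kappa$ under $\kappa = 0$, a function of the
marginals only). Applied to published 2×2 comparison tables this
reproduces the printed kappas (0.03/0.13/0.11/0.08 after 2-dp rounding)
and the p = 0.03 of the slightest-agreement table; an exact permutation
p could be swapped in, but the asymptotic choice is what the printed
values are consistent with. Diagnostic statistics with zero denominators
are reported as `NA`, never 0. The c-statistic is the rank-based AUC
with midrank tie handling, identical to Mann–Whitney $U/(n_1 n_0)$.
Threshold sweeps use a "≥ threshold is positive" rule — so sensitivity
is non-increasing and specificity non-decreasing in the threshold — and
flag the Youden-optimal row, ties resolved to the lowest threshold;
percentile-derived thresholds use the linear-interpolation (type 7)
sample quantile.

For report parity with published tables, indeterminate reads are counted
as controls (`as_control`), which is how such tables absorb them; the
analytic default elsewhere is `exclude`, which is also the policy under
which the generating OR is identifiable.

# Problem sizes and numerical details

The shipped validation uses 20 noiseless $128^3$ phantoms (densitometry
vs truth within 0.005 with the truth mask, 0.01 with the segmenter, Dice
≥ 0.95), 100 cohorts of n = 2093 for OR/slope CI coverage (≥ 93/100),
200 replicates for genetic-null calibration (rejections inside the
99 % binomial band around 5 %), and 10 replicates for the
policy-attenuation direction — sizes chosen so the whole suite completes
in a few minutes on one core while keeping Monte-Carlo error well inside
the tested tolerances. Logistic fits warn on suspected separation
(fitted probabilities at 0/1 or |coefficient| > 15) instead of silently
returning a huge OR; degenerate marginals make kappa error out rather
than return a conventional value.

# Known limitations

* The phantom validates HU bookkeeping, not segmentation difficulty:
  real scans have motion, dependent atelectasis and kernel texture that
  the threshold segmenter has never seen.
* Wald CIs are used throughout (exponentiated on the link scale for
  ORs); profile CIs would behave better at very low case counts.
* Spirometry and percent-predicted reference equations are out of scope;
  COPD status is proxied by percent emphysema in adjustment sets.
* The genetic module handles one biallelic variant, abstractly; there is
  no LD, imputation or genome-wide machinery.
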