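---
title: "Methods: BSA prediction accuracy and its impact on echocardiographic indexing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BSA prediction accuracy and its impact on echocardiographic indexing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaecho)
```

## The problem

Echocardiographic measures of ventricular size (left ventricular
end-diastolic diameter LVEDD, volume LVEDV, and right ventricular basal
diameter RVBD) are indexed to body surface area (BSA) before they are
compared against dilatation cut-points. In clinical practice the BSA in the
denominator comes from a predictive equation, not a measurement. If the
equation systematically overestimates BSA, every relative index shrinks and
early ventricular dilatation — a marker of non-ischaemic cardiomyopathy and
a recognized precursor of sudden cardiac death in athletes — can be missed.

`bsaecho` implements the full comparison pipeline: evaluation of ten
literature BSA equations under strict unit conventions, a criterion BSA
computed from a triangulated 3D body-scan mesh, the method-comparison
statistics that quantify each equation's accuracy against the criterion, and
the downstream dilatation classification whose prevalence depends on which
BSA ends up in the denominator.

## The equation registry

All ten equations take weight in kg and height in cm and return m². Nine are
power laws $\mathrm{BSA} = c\, w^{a} h^{b}$ (three of them — Tikuisis,
Schlich, Ashby-Thompson — with separate male/female parameter sets, and
Livingston with weight only); Sendroy is affine,
$\mathrm{BSA} = 0.0097\,(w + h) - 0.545$. The coefficients are stored exactly
as tabulated in the comparison literature and are deliberately *not*
re-derived from the original publications: the registry is normative, and
`bsa_registry_table()` exposes it as data.

One knock-on effect of that choice is visible in the worked example below:
for a 77 kg / 185 cm athlete the registry's Kuehnapfel coefficients give
1.920 m², whereas applied reports sometimes quote 1.933 m² for the same
subject — a ~0.7% discrepancy consistent with coefficient rounding in the
tabulated registry. We keep the tabulated coefficients rather than tuning
them toward any particular quoted value.

Internally all arithmetic is full precision; 3 decimals (m²) and 1 decimal
(relative indexes) are reporting conventions only.

Because the equations are algebraically defined for any positive input, a
silent unit mistake (grams, meters) would produce a *plausible-looking*
wrong answer. The predictors therefore warn whenever weight falls outside
20–150 kg or height outside 120–220 cm — warnings, not errors, because the
validated human envelope is a soft boundary, but a silent pass is not
acceptable.

```{r}
predict_bsa("dubois", "male", weight = 77, height = 185)
predict_bsa("kuehnapfel", "male", weight = 77, height = 185)
```

## Criterion BSA from a scanned mesh

The criterion is digital anthropometry: a body-scan avatar is a triangle
mesh, and its BSA is the unconditional sum of triangle areas
$\tfrac12\,\lVert (p_1-p_0)\times(p_2-p_0)\rVert$. Orientation and
self-intersection are ignored because that is how scanning software
quantifies avatar BSA; no hole-filling or repair is attempted. OBJ and PLY
(ASCII and binary little-endian) are read natively, polygons are
fan-triangulated, and a `scale` argument handles meshes stored in
millimeters — the avatar unit convention is not standardized across
vendors, so meters are assumed but never enforced silently.

Scan acquisition is duplicated in the emulated protocol, so
`average_replicates()` averages the per-avatar BSAs (a single scan passes
with a warning), and `grubbs_outliers()` runs an iterative two-sided Grubbs
test (default alpha 0.05) on the cohort criterion distribution as
preprocessing QC. The Grubbs critical value is computed from the
$t$-quantile form; the test iterates until no observation is flagged.
Zero-variance samples are reported as untestable rather than error.

Mesh-kernel correctness is anchored on analytic oracles from
`make_test_mesh()`: a cube (area $6s^2$, exact), an icosphere (inscribed, so
area increases monotonically with subdivision toward $4\pi r^2$ from below;
within 1% at subdivision 4), and a capsule ($2\pi r L + 4\pi r^2$).

## Agreement statistics

For each equation and sex, against the criterion:

* **PCC** — Pearson product-moment correlation;
* **RMSE** — $\sqrt{\overline{(p_i - r_i)^2}}$ in m²; the headline ranking
  statistic;
* **relative bias ± SD** — $d_i = 100\,(p_i - r_i)/r_i$, summarized by its
  mean and sample (n−1) SD. The criterion is the denominator, the standard
  convention in method comparison;
* **Bland–Altman** — mean difference, 1.96·SD limits of agreement, and
  proportional bias as the correlation between differences and pairwise
  means with its two-sided p.

The omnibus comparison across the eleven paired distributions (criterion +
ten equations) is gated on normality: Shapiro–Wilk (alpha 0.05) on each
equation's paired differences; if all pass, one-way repeated-measures ANOVA,
otherwise Friedman's rank ANOVA. The gate follows the stated analysis
protocol; which branch fires for a given dataset is recorded in the output
rather than assumed. Post-hoc, each equation is compared to the criterion
with a paired t-test (parametric branch) or Wilcoxon signed-rank test, with
Bonferroni correction across the ten comparisons — the correction procedure
is our choice, made conservative because the source protocol names post-hoc
p-values without naming a procedure. For samples beyond Shapiro–Wilk's
n = 5000 limit the gate subsamples deterministically; this affects only the
branch decision, never the reported statistics.

`rmse`, `relative_bias_sd`, and `bland_altman` are written directly from
their definitions (they are the package's subject matter); the Friedman,
Wilcoxon, Mann–Whitney, Shapiro–Wilk, binomial, and chi-square machinery is
delegated to `stats`, and the tests validate our usage against independent
brute-force oracles (rank-formula evaluation, exhaustive permutation nulls,
binomial-tail enumeration).

## Dilatation classification

Left ventricular dilatation: indexed LVEDD above 30 (M) / 31 (F) mm/m² *or*
indexed LVEDV above 74 (M) / 61 (F) ml/m². Right: indexed RVBD above
22 mm/m² for both sexes. "Above" is strict — a subject exactly at a
cut-point is non-dilated. Classification always uses unrounded indexes.

Subjects flagged on *both* sides are treated as possible athlete's heart
(balanced, training-induced biventricular enlargement) and excluded from
the prevalence numerator but kept in the denominator, so the numerator
always equals left-only + right-only. This makes counted prevalence
non-monotone in BSA even though each per-ventricle flag set is monotone:
with a uniformly smaller BSA in the denominator every index grows, so flags
under a larger BSA are a subset of flags under a smaller one — that subset
property is the invariant the tests assert.

Prevalences under different normalizations are paired observations on the
same subjects, so they are compared with McNemar's test: exact two-sided
binomial on the discordant pair counts when $b + c < 25$, continuity-
corrected chi-square otherwise. The exact/asymptotic switch point is our
choice (the protocol names the test only) and matches common practice.

## The synthetic-data generator

The study's raw data are not deposited, so the generator emulates the two
cohorts' *structure* — it does not attempt to reproduce their records.

* **Anthropometry.** The cohorts are described by BMI quartiles, not weight,
  so each subject is drawn as height ~ truncated normal and BMI ~ truncated
  normal, with weight = BMI·(height m)². Preset medians/spreads follow the
  two cohort descriptions (imaging: 254 M / 115 F, median BMI 21.4 / 20.8;
  echo: 86 M / 25 F, median BMI 23.1 / 22.7; SDs from IQR/1.349). Heights
  (means 177/165 cm imaging, 180/166 cm echo, SD ~6–6.5 cm) are realistic
  for youth soccer players; they are not reported in the cohort
  descriptions and are the one genuinely free choice, fixed once here.
* **Criterion model.** The criterion BSA is anchored to one reference
  equation (default Kuehnapfel): criterion = prediction / f, with f a
  lognormal factor parameterized so the reference equation's percentage
  differences have exactly the configured mean (default +2.2% males, +1.0%
  females) and SD (4.3% / 4.7%) in expectation. Noise is multiplicative
  throughout because BSA is positive and the observed bias structure is
  percent-scale. The other nine equations then inherit the biases implied by
  their algebraic relation to the reference — with a single criterion per
  subject, ten per-equation biases cannot be set independently, and this
  anchored design reproduces the qualitative structure of the real
  comparison (all equations biased high in males, Kuehnapfel lowest RMSE,
  Livingston's weight-only form paying a spread penalty).
* **Scans.** Replicates are truth × mean-one lognormal noise (default CV
  1%, the reproducibility class of consumer 3D scanning), so the replicate
  average is unbiased.
* **Echo.** Each variable is (coefficient · criterion BSA + sex offset) ×
  mean-one lognormal noise; coefficients/offsets are set so the absolute
  medians land at the published echo-cohort values (52/131/39 male,
  49/105/33 female), with residual CVs (4/15/8%) read off the published
  IQR widths. Echo variables are conditionally independent given BSA and
  sex; within-subject correlation beyond BSA is not modeled (unreported in
  the source material) and is a known limitation. An optional calibration
  bisects a single multiplicative factor on a realized draw so the counted
  prevalence under a named normalization hits a target within 2 points.

Everything is deterministic under a fixed seed, with the caller's RNG state
left untouched. What passing tests on these cohorts show is that the
*pipeline* is correct and that its statistics recover known injected
structure; they cannot show that real athletes satisfy the generator's
distributional assumptions (normal BMI, lognormal residuals, conditional
independence).

## Worked example

```{r}
one <- data.frame(id = "athlete1", sex = "male", weight_kg = 77,
                  height_cm = 185, lvedd_mm = 52, lvedv_ml = 147,
                  rvbd_mm = 38)
print(run_dilatation_study(one))
```

The same 147 ml LVEDV indexes above the 74 ml/m² male cut-point under the
smaller (Kuehnapfel-style) BSA and below it under the larger (DuBois-style)
BSA: the dilatation call is an artifact of the denominator, which is the
phenomenon the pipeline quantifies at cohort scale via the McNemar matrix.

## Problem sizes and numerical choices

The test suite and the acceptance script run the imaging-scale study at the
cohort's own sizes (254/115), Monte-Carlo recovery checks at n = 10,000,
permutation-null enumeration at 3×3 (6³ = 216 configurations), the
flag-inclusion property over 1,000 random subjects, and mesh oracles at
icosphere subdivision 4 (5,120 faces). Ties in ranks use mid-ranks;
zero-variance inputs short-circuit to defined results with warnings
(Grubbs, Bland–Altman proportional bias, Friedman on fully tied rows)
rather than NaN. The LoA multiplier is fixed at 1.96.

## Limitations

* No avatar reconstruction: the package starts at the mesh (or at per-scan
  BSA values), never at photographs.
* No Z-score nomogram coefficients are shipped; classification is
  cut-point-based. A user-supplied nomogram function can be applied to the
  per-method indexes the pipeline returns.
* The registry is fixed at the ten tabulated equations; no fitting of new
  BSA equations.
* Mesh QC does not detect self-intersections or non-manifold geometry; the
  criterion is exactly the triangle-area sum.
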