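---
title: "AMH reference ranges and PCOS prevalence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AMH reference ranges and PCOS prevalence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amhref)
```

## The analysis this package implements

Serum anti-müllerian hormone (AMH) declines with age as the antral
follicle pool shrinks, and an elevated AMH is accepted as a surrogate for
polycystic ovarian morphology in adult PCOS diagnosis. Reference
thresholds are population- and assay-specific. The pipeline here derives
empirical AMH reference percentiles for a cross-sectional cohort, models
the age trajectory of log10 AMH, and estimates the prevalence of
suspected PCOS by a two-of-three rule:

* oligo-/amenorrhea (OM/AM): last menses more than 3 months ago, or none
  in 12 months, collapsed into one irregular-cycle flag;
* hyperandrogenemia: free androgen index FAI = 100 × TT / SHBG strictly
  above 8.5;
* AMH strictly above the cohort's 90th (or 95th) reference percentile.

The reference percentiles are deliberately *internal*: they are computed
on the subpopulation with normal FAI (≤ 8.5) and regular cycles and then
applied to everyone, so the "high AMH" criterion is anchored to the
normal stratum of the same population and assay rather than to an
external cutoff. A fixed-threshold mode exists for applying published
thresholds to a new cohort.

## Biomarker conventions

All cutoff comparisons are strict, as is conventional for "above the
limit" flags: FAI > 8.5, HOMA-IR > 3.80, BMI > 32 for obesity; the
overweight band 26–32 kg/m² is inclusive at both ends, so BMI = 32.0 is
overweight, not obese. These are the Polynesian body-composition classes,
not WHO classes.

Left-censored AMH is handled by single-constant substitution: any value
below its assay's limit of detection (LoD) becomes 0.005 ng/mL
(0.036 pmol/L), one step below the picoAMH LoD of 0.006 ng/mL.
Methodological work on LoD substitution supports a single constant when
censoring affects under a quarter of the sample. Two consequences are
worth stating plainly:

* For the ultrasensitive assay (LoD 0.08 ng/mL) the blanket rule replaces
  a value in (0.005, 0.08) with a *smaller* number. This is the rule as
  specified and is applied uniformly; in practice women under 40 on that
  assay almost never sit below its LoD.
* Substituted values participate in logs (log10(0.0357 pmol/L) ≈ −1.447)
  and in all models, matching the primary analysis; a sensitivity refit
  (`sensitivity_excluding_imputed()`) drops them.

Total testosterone below its reported LoD (20, in the assay's reporting
unit) is substituted with 19 before FAI is formed. Those magnitudes are
atypical for female TT in nmol/L (they are plausible in ng/dL); the
package treats the unit label as opaque and applies the printed numbers.
A missing or non-positive SHBG yields a missing FAI rather than an error,
and the record is later removed by the eligibility filter.

Missing hormonal-contraceptive answers are imputed to "no" (HC use is
uncommon in the source population) with a sticky `hc_assumed_no` flag, so
deriving an already-derived table changes nothing.

## Eligibility

The filter retains women aged in the configured window (default
[25, 51), half-open over decimal ages; the observed maximum of 50.8 is
consistent with either convention and the bound is configurable), with no
reproductive surgery, no HC use, and complete AMH/TT/SHBG/insulin/
glucose/menstrual data. Membership in the retained set is precedence-free
— a conjunction of per-record predicates — while the *reported* reason
for each exclusion is first-hit in the order age → surgery → HC →
missing, mirroring how such flowcharts are usually reported. The ledger
partitions the input exactly: retained + excluded = input.

## Quantile convention

The percentile estimator is explicit because reference-interval practice
varies: `linear_interpolation` (the common statistical-computing default,
interpolating between order statistics), `inverse_ecdf`, and
`nearest_rank` are available, and the convention used is recorded inside
the returned `amh_refrange` object for provenance. The default is linear
interpolation. Which convention produced the originally published
thresholds is not recoverable without the raw data; for the n = 518
reference subpopulation the three differ by at most one order-statistic
gap near the 90th percentile.

## The age-trajectory model

`fit_amh_trajectory()` fits ordinary least squares of log10 AMH (pmol/L)
on age polynomials of degree 1–3; `select_best_model()` picks the largest
adjusted R², breaking exact ties toward the lower degree (the more
parsimonious model explains equally well). Degrees above 3 are rejected
by validation: the analysis this implements considered age, age² and age³
only, and higher degrees invite Runge-style artifacts on a 26-year span.

Age is centered internally before polynomial expansion — raw age³
reaches ~1.3 × 10⁵ and makes the normal equations ill-conditioned — and
coefficients are mapped back to the raw-age scale by binomial expansion,
so reported coefficients are directly comparable to published equations.
The model is strictly cross-sectional: it describes the population age
gradient, not any woman's longitudinal decline.

## What the generator emulates — and what it does not

`generator_config()` defaults encode the published structure of the
cohort the package emulates: stratum sizes 148/111/117/135/159 over ages
[25,30), [30,35), [35,40), [40,45), [45,50.8]; uniform ages within strata
(only bin counts are published); mean trajectory
log10 AMH = 4.4356 − 0.1045 · age with per-stratum residual SDs
0.34/0.43/0.52/0.78/0.77; assay switch at age 40 with LoD censoring; an
FAI log-normal with median 2.51 calibrated to P(FAI > 8.5) = 0.090; OM/AM
at 14.6% with the hyperandrogenemia overlap set to 6/670 (published set
arithmetic, below the ~8.8/670 independence would give); BMI
Normal(34.6, 6.9) truncated to [18.0, 59.9]; HOMA-IR log-normal with
median 2.78 calibrated to P(> 3.80) = 0.346, with insulin back-solved
from a truncated-normal glucose; 27.2% smokers; 154/670 missing HC
answers. TT is drawn from a log-normal left-truncated at its LoD and SHBG
back-solved as 100 × TT / FAI, since only FAI's marginals matter
downstream; this keeps the TT-substitution path from perturbing the
calibrated FAI distribution (that code path is exercised by unit tests
and the fixture instead). BMI, smoking and insulin resistance are
independent of AMH by default, mirroring the null associations in the
emulated cohort; `bmi_amh_coupling` exists for power experiments.

Features of the real data the generator does **not** reproduce:

* The real lower tail is heavier than the linear-Gaussian model: the
  model implies ~6% of values below the LoD, while the emulated cohort
  observed 12.5% (46.7% among women 45+). Tests of censoring therefore
  check agreement with the generator's own analytic integral, and the
  12.5% scenario is represented by the deterministic fixture, which
  plants exactly 84 below-LoD rows.
* Excluding substituted values from the refit *raises* R² under the
  Gaussian model (a point mass near the floor is removed), whereas the
  real data showed a drop; the attenuation of the age slope — the
  substantive claim — reproduces in both, and that is what is tested.
* The FAI–AMH correlation is unconstrained (independent draws), so the
  published positive correlation between them is not a generator target.
* Exact stratum medians/ranges are real-data artifacts and not targeted.

Consequently, passing tests demonstrate that the pipeline's *code* is
correct under the published statistical structure, not that the generator
is a faithful simulator of Samoan physiology.

## The deterministic fixture

`generate_table1_fixture()` constructs a 670-row cohort whose derived
margins match the published descriptive table exactly: 60
hyperandrogenemic, 98 OM/AM, 6 in both (so the reference subpopulation is
670 − 152 = 518), 84 below-LoD values, 83 records above the
90th-percentile threshold and 45 above the 95th, 34 and 23 two-of-three
positives (5.1% and 3.4%), stratum sizes, BMI classes 64/190/416, 232
insulin resistant, 182 smokers, 154 missing HC answers. Under
linear-interpolation quantiles on 518 reference values, 52 reference rows
exceed the 90th-percentile threshold and 26 the 95th; the published
totals then force 3 of the 6 dual-criteria women above the 90th threshold
and 2 above the 95th (83 − 52 − 28 and 45 − 26 − 17). All other overlaps
are minimal, AMH decreases with age so stratum medians decline, and
censored rows fall in the picoAMH age range. The fixture's BMI/IR/smoking
assignments are block-structured and carry no intended association with
AMH.

`generate_eligibility_fixture()` appends disjoint groups of 33 surgical,
256 HC-using and 60 missing-measures women (33 + 256 + 60 = 349, which
matches the published exclusion total exactly and motivates the
disjointness assumption), giving 1019 rows of which 670 survive.

## Numerical and testing choices

* Round-trip fidelity: cohort CSVs print numerics with 17 significant
  digits, so write → read reproduces doubles bit-for-bit; missing values
  are empty strings, never zero.
* Oracles: quantiles are checked against a sort-and-formula oracle, OLS
  against raw normal equations, the PCOS rule against full 8-way
  enumeration, ANOVA F against between/within mean squares, correlations
  against the definitional formula, and generator censoring against
  direct integration of Gaussian mass below the LoD over the age
  distribution.
* Stochastic tolerances are 3 standard errors at the stated problem
  sizes; recovery experiments use cohorts of n = 670 (50 seeds for the
  R²/correlation summaries, chosen to make the seed-mean's Monte Carlo
  error an order of magnitude smaller than the ±0.05 acceptance band)
  and a single n = 10⁴ cohort for marginal recovery.
* All randomness flows from one seed; `generate_cohort()` restores the
  caller's RNG state.
* The Wilson confidence interval on prevalence is a labelled extension;
  the emulated analysis printed none.

## Known limitations

Self-reported menstrual history, FAI rather than free testosterone by
mass action (deliberate: no free-T calculation is provided), no
ultrasound morphology, and single-constant LoD substitution are all
inherited from the design this package implements. The generator's
independence assumptions make it unsuitable for studying
adiposity–AMH coupling unless the coupling knob is engaged, and its
uniform within-stratum ages are a convention, not an estimate.
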