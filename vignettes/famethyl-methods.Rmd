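---
title: "Models and design choices in famethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in famethyl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famethyl)
```

`famethyl` analyses targeted CpG methylation in extended families: an
in-silico model of the mass-spectrometric measurement process, QC of
replicate measurements, polygenic variance-component models on pedigree
kinship, and multiple-testing correction, exercised end to end by a
synthetic cohort generator. This vignette records the models, the
parameter choices that matter, and what the package's validation does and
does not establish.

## The measurement model

EpiTYPER-style assays PCR-amplify bisulfite-converted DNA with a
T7-tagged reverse primer, transcribe the reverse strand, and cleave the
transcript base-specifically with RNase A. We model the T-cleavage
reaction only: the transcript is the reverse complement of the converted
amplicon, cut 3′ of every U. Two facts drive everything downstream:

- Cut sites mirror template adenines, which bisulfite conversion never
  touches, so the fragment pattern is *independent of methylation state*.
- An unmethylated CpG cytosine deaminates to T (transcript A); a
  methylated one stays C (transcript G). A and G differ by ~16 Da, so each
  methylated CpG in a fragment adds 16 Da to its mass.

CpG sites sharing a fragment are inseparable and form one *unit*
(e.g. 6/7 or 10/11/12 in the default panel). Distinct CpG fragments whose
entire mass ladders (base mass + 16·k, k = 0..K) coincide within the mass
resolution are flagged `mass_collision` and averaged downstream — the
3a/3b case. Fragments whose methylated masses collide with a CpG-free
fragment are `unresolvable` and dropped. The default mass resolution is
1 Da; instrument resolution is not modelled further, and we use average
(not monoisotopic) residue masses pinned in one constants table. The
testable contract is the exact 16.00 Da shift and mass additivity, not
calibrated absolute masses.

Methylation fractions come from intensity ladders as
`sum(k·I_k) / (K·sum(I_k))`; measurement noise is Gaussian on the
fraction scale with clamping to [0, 1]. No peak-picking, adducts, or
primer design are modelled.

## Quality control

Replicate triplicates aggregate to cell means unless their sample (n−1)
standard deviation exceeds 0.1, in which case the cell is excluded; a
single surviving replicate is kept with sd treated as 0. Subjects are
rejected when their *measurement calling rate* — the fraction of panel
columns, regional average included, with any measurement at all — falls
strictly below 0.95.

The order matters. With an 18-column panel, a 95% rule rejects any
subject missing even one column (17/18 = 0.944), so if sd-based
exclusions counted against the calling rate, a single noisy cell would
reject the subject and cell-level exclusions could never coexist with a
low subject-rejection percentage. We therefore compute the calling rate
on raw measurement availability first and exclude high-variance cells
among retained subjects second, matching the assay workflow in which
whole-sample failures and noisy wells are distinct events.

The regional average is the unweighted mean over a subject's non-missing
units. With unit means spanning 0.015–0.90, this makes the average
sensitive to *which* units are missing: dropping a high-methylation unit
shifts the average by far more than the biological signal. The package
keeps the conventional definition but the limitation is real — in
simulations, the measured regional average correlates only moderately
with the true one once cells are excluded, while per-unit values are
barely attenuated. Analyses that lean on the regional average should
check completeness or restrict to complete rows.

## The polygenic model

All phenotypes — metabolic traits and percent-methylation alike — are
rank-based inverse-normal transformed before modelling,
`z = qnorm((r − 0.5)/n)` with average ranks for ties (Blom and van der
Waerden offsets are available; the choice is exposed because conventions
differ across software and the results are insensitive to it).

The trait model is multivariate normal with mean `Xβ` and covariance
`Ω = 2Φ σ²_a + I σ²_e`, where Φ is the recursive (tabular) kinship matrix
— `φ(i,i) = 0.5(1 + φ(f_i, m_i))`, `φ(i,j) = 0.5(φ(f_i, j) + φ(m_i, j))`
— and the factor 2 converts kinship to the additive relationship. The
standard design is intercept, sex, age, age², sex×age, sex×age², with age
centered at its sample mean so the linear age coefficient is the slope at
the mean age.

Fitting is full maximum likelihood, not REML, because the downstream
tests are likelihood-ratio tests of nested models; the small downward
bias in variance components at n ≈ 517 with 6 fixed effects is accepted
and, because it scales both components nearly equally, barely touches h².
Numerically, the additive kernel `2Φ` is eigen-decomposed once; in the
rotated basis Ω is diagonal in the ratio `h² = σ²_a/(σ²_a + σ²_e)`, so β
and the total variance are profiled analytically and `h²` is found by
bounded one-dimensional search on [0, 1) to tolerance 1e-8, with the
boundary checked explicitly. The `h²` standard error comes from the
numerical second derivative of the profile log-likelihood and is reported
as `NA` on the boundary. Repeated fits on one pedigree reuse the
decomposition (`kinship_eigen`).

Heritability is tested against `σ²_a = 0` with the boundary null — a
0.5 : 0.5 mixture of χ²₁ and a point mass at zero, so `p = 1` at `T = 0`
and `0.5·P(χ²₁ ≥ T)` otherwise. Fixed effects, including the focal
methylation predictor in association scans, use ordinary χ² LRTs with df
equal to the parameters dropped. Wald SEs are reported alongside; the LRT
p-value is the value of record. Variance explained is
`β̂²·Var(x)/Var(y)` on the analysis (z) scale. Raw-scale effects per 1
percentage point of methylation are approximated as
`β_z · sd_raw(trait) · 0.01/sd_raw(methylation)`; this is a declared
approximation — reproducing a published raw-scale change requires the
cohort's raw standard deviations, which are not available per unit.

Missing data are handled complete-case per trait–unit pair. Household and
dominance components, bivariate models, and ascertainment corrections are
out of scope.

## Multiple testing

The default correction is Bonferroni over the raw panel width of 18
(17 units plus the regional average): α = 0.05 and 0.10 give per-test
thresholds 0.05/18 ≈ 0.0028 and 0.10/18 ≈ 0.0056. Šidák
(`1 − (1−α)^(1/M)`) is available by flag, and the Li–Ji eigenvalue
estimator of the effective number of tests
(`Meff = Σ 1{λ_i ≥ 1} + (λ_i − floor(λ_i))`) supports data-driven M.
Expression-probe detection uses BH-FDR at 5% via `stats::p.adjust`;
expression intensities are log₂-transformed and quantile-normalized
(`limma::normalizeQuantiles`) before kinship-adjusted association.

## The synthetic cohort

The generator is the package's test bed: it produces data with exactly
the statistical structure the analysis assumes, which is both its purpose
and its limitation.

**Families.** 40 extended nuclear families: a founding couple, a sibship
of 2 + Poisson(2.3), and for each sib, with probability 0.5, a married-in
spouse and 1 + Poisson(1.1) children. These shapes put the expected
cohort at ~519 individuals; family-shape distributions of the emulated
design are not published, so they are tuned only to the family count and
total size. Ages are generation-structured Gaussians (parents 71, sibs
49, children 27, SD 5; spouses near their partner), giving a cohort mean
near 43.6 y and SD near 15.5 y. Sexes in founding/married couples are
fixed male–female pairs, so the 0.589 female fraction applies only to
sibs and children and the realized cohort fraction is nearer 0.55.

**Methylation.** Each unit is a clamped linear-scale Gaussian:
mean + β_age·(age − mean age) + β_sex·1{female} + g + e, with g drawn
from MVN(0, 2Φ·h²σ²) through the eigen-factorization and e independent.
Unit h², age and sex effects follow the published per-unit estimates
(h² 0.03–0.48, age slopes up to 2.9e-4 per year). Unit means are not
published; defaults follow the region's qualitative profile (promoter
1–12%, first exon 45–90%). Unit SDs are derived from the published
age-effect variance fractions via `sd_u = |β_age|·sd_age/√ve_age` — for
unit 9 this gives 0.031 with sd_age = 15.5, the value that makes the
published slope and variance fraction mutually consistent — capped at
`min(mean, 1−mean)/3` so boundary clamping stays below ~1% (the generator
warns above 5%). Simulation is on the clamped linear rather than logit
scale because the analysis rank-normalizes anyway and published effects
are on the fraction scale.

**Phenotypes.** On the z scale, trait = β·z(methylation predictor) +
polygenic + residual with unit total variance (error if β² ≥ 1), mapped
to raw scale by sex-specific means/SDs. Eleven traits ship by default —
the four published methylation–trait pairs (total cholesterol on the
regional average, β = 0.17; non-HDL particle size on 17/18, −0.15;
diastolic blood pressure on 13, −0.16; insulin sensitivity on 21/22,
−0.16) plus common anthropometric/lipid/adipokine traits with their
published sex-specific scales and heritabilities. Gaussian raw scales are
a simplification: skewed traits (triglycerides, insulin) can simulate
negative values; the analysis is rank-based, so this affects realism, not
calibration. Ascertainment (recruitment through obese probands) is not
modelled in generation or likelihood, matching the emulated analysis.

**Measurement layer.** Triplicates with noise SD 0.02 (consistent with
control-panel deviations well inside the 0.1 sd exclusion rule);
high-variance cells injected at rate 0.048 as symmetric ±0.2 spreads
(sample sd ≥ 0.115 even after clamping); failing subjects at rate 0.025
get two fully-missing units, putting their calling rate at 16/18 = 0.889,
below the 95% rule. All randomness flows through the single config seed;
regeneration is bit-identical.

## Validation: what it shows and what it does not

- Kinship is checked against a gene-dropping Monte-Carlo oracle on small
  pedigrees; the ML fit against an explicit-inverse grid oracle at
  n ≤ 20; BH and Li–Ji against hand and permutation computations.
- Type-I error of the boundary-mixture heritability test and the
  association LRT is verified within the binomial 95% CI of α = 0.05 over
  1000 null replicates at the full cohort scale.
- Parameter recovery runs 200 replicate 40-family cohorts (~60 s on one
  CPU) and recovers the generative h² = 0.48 (unit 9) and β = 0.17
  (total cholesterol on the regional average) within three Monte-Carlo
  standard errors of the replicate means. Recovery fits use the
  generator's true fractions: the measurement layer is validated
  separately (rate recovery, lossless round trip at zero noise), and
  folding it in would estimate the attenuated, not generative,
  quantities.

Because the generator implements the model the estimators assume, these
checks establish internal correctness and calibration — not robustness
to model misspecification (non-Gaussian methylation distributions, batch
effects, shared-household covariance, ascertainment), none of which the
synthetic data contain.

```{r recovery-example, eval = FALSE}
# a smaller version of the recovery study (20 cohorts, ~6 s)
rec <- recovery_study(seeds = 1:20)
colMeans(rec[, c("h2_hat", "beta_hat")])
```
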