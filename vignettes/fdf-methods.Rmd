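---
title: "Methods: Fabry phenotype scoring and carrier association in synthetic biobank cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fabry phenotype scoring and carrier association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Fabry disease (FD) is an X-linked lysosomal storage disease caused by
variants in the *GLA* gene. Hemizygous males carrying a pathogenic variant
are affected; heterozygous females show variable expression attributed to
random X-chromosome inactivation. A long-standing difficulty is that the
hallmark FD features — hypertrophic cardiomyopathy, chronic kidney disease,
stroke, neuropathic pain — are also produced by ordinary cardiovascular (CV)
risk factors, so variants of uncertain significance (VUS) or with
conflicting pathogenicity interpretations can be mistakenly blamed for an FD
phenocopy. Population-scale genotyped cohorts remove the selection bias of
phenotype-first variant collections: carriers can be compared with hundreds
of thousands of wild-type controls of the same sex.

`fdftools` implements that analysis as a reusable pipeline and pairs it with
a seeded synthetic-cohort generator, so the whole machinery is exercised and
validated without access to restricted biobank data.

# The FDF score

The FASTEX-derived Fabry (FDF) score summarizes four clinical domains —
pain, renal, cardiac, cerebrovascular — each on 0–4 points:

* **Cardiac and cerebrovascular** domains are flag domains: ICD-10 codes are
  matched by prefix against an editable registry; each prefix carries a
  severity level and the domain scores the *highest* severity present (a max
  rule, never a sum). Cardiomyopathy (I42) and stroke (I60–I63) sit at
  severity 4.
* **Renal** scores the maximum of an eGFR band and a uACR band
  (KDIGO-style: eGFR ≥ 90 → 0, 60–89 → 1, 30–59 → 2, < 30 → 4;
  uACR < 30 mg/g → 0, 30–300 → 1, > 300 → 4). Missing renal labs make the
  renal score missing — subjects drop out of models that need it; the score
  is never imputed to zero.
* **Pain** scores the highest reported category across the questionnaire
  items. Pain is the one domain with an imputation rule: when *every* item
  is missing, the lowest category (0 points) is inferred and the subject is
  flagged `pain_imputed`. This mirrors how sparse questionnaire data are
  handled in practice and deliberately biases the pain domain downward.

The total (0–16) is dichotomized strictly **above 4**. Because a single
domain can contribute at most 4 points, a high flag logically requires at
least two involved domains; `total_fdf()` is tested exhaustively over all
5^4 domain-score tuples for this property. The ROC-optimal cutoff on real
data (Youden index 4.4) is stored in the scoring map as a reference
constant, not asserted on synthetic data, where the score distribution is a
function of generator calibration rather than of FD biology.

The exact item list and band edges behind the published score derivation are
not publicly deposited; the shipped scoring map and ICD-10 registry are
therefore documented **reconstructions** (standard KDIGO renal staging,
conventional ICD-10 blocks) and are editable through a YAML config
(`inst/extdata/default_config.yaml`, `read_analysis_config()`).

# The CV risk score

The CV risk score is a study-specific logistic regression of the FD
phenotype flag (FDF > 4) on six covariates: age (years) plus ICD-10-derived
diabetes, dyslipidemia, hypertension, obesity and smoking indicators. The
per-subject score is the **linear predictor** (log-odds scale) — the scale
on which the published operating threshold 1.92 is meaningful (a probability
of 1.92 is impossible). Model discrimination is summarized by a rank
(Mann–Whitney) AUC with mid-rank tie handling, verified in tests against the
trapezoidal area under the empirical ROC and against `pROC`.

The fitted outcome deserves a note: the published description both
"calculates a CV risk score" and assesses it "by its power to predict
pathogenic carriers". We fit on the FD phenotype (the score is a CV-burden
summary) and expose carrier-status prediction as the *validation* ROC;
`outcome` is an argument of `fit_cv_model()` so either reading can be run.
In the synthetic cohorts the carrier-status AUC is ≈ 0.5 by construction —
genotypes are assigned independently of risk factors (Mendelian
randomization), so nothing in the generator links CV burden to carrying a
variant. That published value is a property of the real cohort, not a
property this generator emulates.

Stratification assigns `high` strictly above the empirical 75th percentile
of the reference population's scores (ties go to `low`), computed once and
reused for carrier subsets.

# Association models

For each variant group and sex, `build_analysis_set()` forms
carriers-versus-controls rows: hemizygous males (or heterozygous females)
against same-sex subjects with zero variant alleles across *all* analyzed
groups. Homozygous females are counted and excluded — they are too few for
sex-matched comparison and their expected phenotype differs from
heterozygotes.

* Binary outcomes: maximum-likelihood logistic regression (`glm`,
  binomial). The unadjusted OR on a 2×2 table equals the cross-product
  ratio; the test suite holds the implementation to that closed form at
  1e-6.
* Ordered multi-level outcomes: proportional-odds cumulative-logit model
  (`MASS::polr`). With exactly two observed levels the cumulative-logit
  model *is* binary logistic regression and is fitted as such, which also
  makes the logistic fit an exact oracle for the reduction.
* Continuous traits: least-squares regression, with statin use added to the
  covariates for lipid traits.

All adjusted models use the six-covariate CV set. Intervals are Wald:
estimate ± z(0.975)·SE, exponentiated for ORs, reported as the 2.5/97.5
percent endpoints. Profile-likelihood intervals were considered and
rejected: at 10^5–10^6 rows across dozens of models they cost orders of
magnitude more time and differ negligibly at these counts. (Quasi-)
separation is flagged with infinite bounds rather than an error, so rare
strata degrade gracefully.

Multiple testing uses a from-scratch Benjamini–Hochberg step-up
(`bh_adjust()`): adj(i) = min over j ≥ i of p(j)·m/j, capped at 1. It is
tested against both `p.adjust(method = "BH")` and a brute-force enumeration
of the smallest rejection level per hypothesis, over all small p-value
grids. Multicollinearity is checked a priori with `vif()`, the closed form
1/(1−R²) per predictor, cross-checked against `car::vif`.

The CV-stratified analyses compare carriers within a stratum against the
**full** same-sex control population and are deliberately *not* CV-adjusted
— the stratification replaces the adjustment, and adjusting as well would
condition twice on the same construct.

# What the synthetic cohort emulates

`generate_cohort()` draws, per subject: sex; age uniform on 40–70 (the
recruitment window of large adult biobanks); X-linked allele counts (one
Bernoulli draw for males, two for females, so female heterozygosity follows
Hardy–Weinberg 2q(1−q)); risk factors as Bernoulli with age-dependent logit
prevalence; domain events from the logistic liability

> logit P(event_d) = b_d + 0.05·(age−55) + Σ_f β_f·RF_f + β_main·C +
> β_int·C·H

where C is carrier status and H a latent high-CV indicator (top quartile of
the risk-factor liability). Female carrier effects are multiplied by a
single attenuation parameter (default 0.5) — a one-parameter stand-in for
X-inactivation mosaicism, which has no quantitative published model.

Default carrier frequencies are the published sex-relative proportions of
the three variant classes (pathogenic 0.00014, conflicting 0.0075, VUS
0.0005). Default effects encode the study's qualitative findings as the
generating truth: pathogenic carriers get an unconditional OR of 5 on each
flag domain plus a ×4.1 uACR location shift (the ratio of carrier to
control uACR means in the published male tables); non-pathogenic groups get
no main effect and an OR of 3 confined to high-CV subjects. No quantitative
per-domain effect sizes are published — these are calibration choices, fixed
once, chosen so that control FDF>4 prevalence lands at a few percent and
carrier counts at desk scale support estimation.

Labs are calibrated per sex to the published control means ± SDs.
Right-skewed analytes (uACR, urinary albumin/creatinine, triglycerides,
lipoprotein(a)) use moment-matched log-normals; the rest positive-truncated
normals. Urinary albumin is *derived* from uACR × urinary creatinine
(unit-converted, ×exp(N(0, 0.1))) so the three stay internally consistent.
Baseline domain intercepts (cardiac −4.0, cerebrovascular −4.6, pain −1.8)
give control event rates of roughly 4%, 2% and 14% at age 55 — ordinary
population orders of magnitude. Missingness is missing-at-random per field,
heaviest on pain items (70% per item, so ~34% of subjects have all three
missing and exercise the imputation rule).

**What it does not emulate:** linkage between individual variants and their
class groups (groups are simulated disjointly), per-tissue X-inactivation
mosaics, longitudinal follow-up, correlated comorbidity structure beyond
the shared risk-factor liability, informative missingness, or any
association between genotype and CV burden. Passing tests therefore show
that the *pipeline* recovers known generating truths — not that real-data
effect sizes would reproduce.

# Validation experiments and problem sizes

Two seeded experiments validate end-to-end estimation, each on cohorts of
200 000 subjects per replicate, 20 replicates:

* **OR recovery** (`or_recovery_experiment()`): pathogenic β_main = log 5;
  the male cardiac-domain logistic model (whose generating model is exactly
  logistic, so the estimand is exactly 5) is fitted with the six-covariate
  adjustment; we record interval coverage of 5. The experiment uses carrier
  frequency 0.005 (~500 male carriers per replicate): at the study's
  0.00014 a replicate holds ~14 carriers and ~1 event, the coefficient is
  not estimable, and coverage is undefined — the frequency is experimental
  design, not the parameter under test. The composite FDF>4 flag is not
  used as the coverage outcome because its true OR has no closed form under
  per-domain generation.
* **CV-interaction pattern** (`cv_pattern_experiment()`): a
  conflicting-class group at the study frequency 0.0075 with β_main = 0 and
  interaction OR 3; the full scoring + CV-stratification pipeline should
  yield OR > 1 in the high-CV stratum and OR ≤ 1 in the low-CV stratum
  (carriers without CV burden sit below the mixed reference population's
  event rate, which is why the low stratum shows the inverse association).

Unit tests run at 10^3–10^5 rows; the shared test cohort is 20 000 subjects
with boosted carrier frequencies so each group has carriers of both sexes
at desk scale.

# Numerical choices and degenerate inputs

* Youden cutoffs scan midpoints of adjacent distinct score values under the
  rule `score > threshold`; ties break toward the lower threshold.
* `round()` (half-even) is used for printed proportions, matching published
  table arithmetic.
* Truncated-normal labs resample on the rare non-positive draw; a zero SD
  collapses a lab to its mean.
* All-equal CV scores stratify everyone `low` (strict inequality) with a
  warning; subjects missing covariates are unstratified and excluded with a
  message; empty stratum-group cells are skipped, not fatal.
* Determinism: a cohort is a pure function of (config, seed); the
  end-to-end report is byte-stable under a fixed seed. Replicate
  experiments derive per-replicate seeds as `seed·1000 + r` (kept below
  2^31).

# Known limitations

The registry and scoring map are reconstructions, not the unpublished
originals; absolute score distributions and the real-data Youden cutoff are
therefore not reproduction targets. Wald intervals slightly undercover at
very small carrier counts (the pathogenic group at realistic frequency);
the separation flag marks the worst cases. The generator's disjoint-group
simplification means "controls lack variants in any group" and "controls
lack variants in this group" coincide in simulation, whereas in real data
individual variants are subsets of their classes.
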