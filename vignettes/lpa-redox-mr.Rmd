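---
title: "Methods: one-sample MR of Lp(a), vascular superoxide, and cardiovascular death"
author: "lpamr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-sample MR of Lp(a), vascular superoxide, and cardiovascular death}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpamr)
```

## The design this package implements

`lpamr` implements the analysis chain of a one-sample cis-Mendelian
randomization (MR) study in a surgical cohort: seven SNPs in the *LPA*
region instrument plasma Lp(a); arterial superoxide (O2·−) bioassays on
fresh arterial biopsies partition the superoxide sources into NADPH oxidases
(NADPH-stimulated and Vas2870-inhibitable readouts) and uncoupled eNOS (the
L-NAME delta, with the plasma BH4/BH2 ratio as the cofactor-oxidation
index); and Cox survival models link the exposure to cardiovascular death,
with mediation through log basal O2·− assessed by nested models.

Because individual-level cohort data of this kind are not publicly
deposited, the package pairs the analysis code with a seeded synthetic
cohort generator whose *defaults encode the study conditions*: n = 1027
subjects, 20.9% diabetes prevalence, ~20 cardiovascular deaths over a
median ~5-year follow-up, right-skewed Lp(a) that is 90% genetically
determined, lower Lp(a) in diabetics, an Lp(a) effect on eNOS-derived
superoxide present only in nondiabetics, and a survival effect of Lp(a)
fully mediated by arterial superoxide. Every statistical claim in the test
suite is made against that generator or against closed-form/enumeration
oracles.

## The genetic instrument

The GRS is an **unweighted summative carrier model**: for each subject,
`carrier_count` is the number of the 7 instrument variants at which the
subject carries at least one alternative allele. The dichotomy compares
carriers at ≥3 variants ("alternative") with subjects carrying no
alternative allele at any instrument ("reference"); subjects with 1–2
carried variants are unassigned and excluded from the contrast — the only
reading consistent with a reference group of "no alternative alleles" and
an alternative group of "any alternative allele from ≥3 SNPs". Two
readings of "unweighted summative" exist (allele counts 0–14 vs carrier
indicators 0–7); the carrier-indicator form is used because the grouping
rule is itself defined on carried variants. The continuous score is the
carrier count standardized to unit SD *within the stratum of subjects
carrying alternative alleles at more than one variant* (`carrier_count >=
2`), matching the per-SD hazard-ratio interpretation of the continuous
analysis. Missing dosages are handled per subject: counts run over
nonmissing variants with a completeness flag, and only a subject observed
homozygous-reference at all 7 instruments can be "reference".

Linkage disequilibrium between the instruments is estimated from unphased
genotypes by a two-locus EM algorithm (only double heterozygotes carry
latent phase; convergence when the largest frequency change is < 1e-10,
capped at 1000 iterations; an all-double-heterozygote table is flagged
non-identifiable because the likelihood is bimodal). D′ and r² follow the
standard normalizations; allele frequencies are preserved exactly by every
E-step, which is also why a 1-D grid search over the AB-haplotype frequency
is a complete oracle for the EM in the tests.

## The synthetic cohort generator

**Genotypes.** Linkage disequilibrium is induced by a Gaussian copula: per
haploid draw a latent MVN vector with correlation `latent_corr`
(exchangeable 0.6 by default — high D′ with modest r², typical of
low-frequency variants in one locus) is thresholded at the allele-frequency
quantile of each variant; two draws per subject give the diploid dosage.
Marginal alternative-allele frequencies are exact in expectation and no
haplotype reference panel is needed. Published per-variant frequencies and
effects for this cohort are not available, so defaults (frequencies
0.02–0.15, log-scale effects 0.12–0.70) are plausible placeholders chosen
once, not estimates; they produce a median Lp(a) near 11 mg/dL with a long
right tail to a few hundred mg/dL, mean Lp(a) ~5× higher in the alternative
GRS group, and all 7 variants genome-wide significant at n = 1027.

**Lp(a).** log-Lp(a) = intercept + Σ βⱼ·dosageⱼ − 0.25·diabetes + ε. When a
target genetic-variance fraction is configured (default 0.90, the "over 90%
genetically determined" condition), the residual SD is *derived* from the
realized genetic variance to hit the target exactly in expectation; a zero
genetic variance with a positive target is a configuration error. The
diabetes shift encodes the observed lower Lp(a) of diabetics.

**Redox panel.** The NOX component is lognormal (median 150 RLU,
independent of Lp(a)); the eNOS-linked component is
`enos_base + θ·Lp(a) + noise` with θ = 1.58 RLU per mg/dL in nondiabetics
(the magnitude of the reported moderation coefficient) and 0 in diabetics.
Basal O2·− is the sum of both components. One design point deserves
emphasis: the L-NAME delta is defined throughout as
*post-L-NAME − basal* (the published formula), and positive deltas index
uncoupled-eNOS-derived superoxide. For the generator to satisfy both that
sign convention and the observed directions (delta rising with Lp(a) in
nondiabetics, higher basal O2·− with higher Lp(a)), the post-L-NAME
readout is modeled as basal *plus* the eNOS-linked component — NOS
inhibition unmasks the eNOS-linked signal — so the delta equals that
component up to noise. Negative deltas (recoupled / NO-scavenging
physiology) arise from noise and are retained, never clipped. The BH4/BH2
log-ratio declines with Lp(a) (−0.004 per mg/dL); hsCRP and MDA are
generated independent of Lp(a), encoding the absence of systemic
inflammation/oxidation associations.

**Covariates and survival.** Clinical covariates (age, sex, hypertension,
smoking, BMI, family history, prior MI, urgency, ApoB) are generated
independent of genotype — the MR independence assumption holds by
construction, and the instrument-validation screen should be null. Event
times are exponential with hazard
`λ·exp(βo2·log basal O2 + βdirect·log Lp(a) + 0.05·(age−67) +
0.3·diabetes)`; the default `βdirect = 0` encodes *full mediation* (the
"lost significance" structure), with the knob available for
partial-mediation and no-mediation experiments. Censoring is exponential
(0.12/yr) truncated at 10 years, giving a ~5-year median follow-up and
~20–30 events at n = 1027, the reported event scale. λ = 1e-7 looks odd in
isolation; it is calibrated against `exp(2·log basal O2) ≈ basal²` so the
marginal event rate lands at ~2–3%/cohort.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: assay drift and measurement batch effects,
kringle-IV copy-number structure (the actual biological driver of Lp(a)
isoform size), competing risks, informative censoring, genotyping error,
and confounding of the instrument (real covariates are never exactly
independent of genotype). Results on the generator validate the *software
and its statistical calibration*, not the biology.

## The statistical core

These estimators are implemented from scratch (they are the package's
subject matter), each with an independent oracle in the tests:

- **Two-group tests**: each group is screened for normality by the
  Lilliefors-corrected Kolmogorov–Smirnov test at 0.05 (the convention of
  the statistical software the design used); both-normal uses the pooled
  Student t, otherwise Mann-Whitney U with a tie-corrected normal
  approximation, switching to exact enumeration of all group assignments
  when n1 + n2 ≤ 12.
- **Correlation**: Pearson, and Spearman as Pearson on midranks, with
  t-approximation p-values.
- **Linear models**: QR least squares, standardized betas (a univariate
  standardized beta equals Pearson r), and a heteroscedasticity guard:
  Levene's test on absolute residual deviations across terciles of the
  fitted values triggers a seeded percentile bootstrap (2000 reps default)
  of the coefficients. Moderation fits `y ~ x + m + x·m (+ covariates)`;
  the interaction p comes from the OLS t-test and its CI from the
  bootstrap.
- **Cox regression**: Newton–Raphson on the partial likelihood with Efron
  tie handling by default (Breslow by flag; the two coincide exactly
  without ties), step-halving, convergence when the largest score component
  is < 1e-9, Wald inference throughout (matching HR [CI] p reporting). A
  coefficient path passing |β| > 20 is reported as non-identifiable
  (monotone likelihood / complete separation) rather than silently
  returned; a covariate whose levels do not all contain events is dropped
  from pipeline adjustment sets by a positivity screen before fitting, and
  reported.
- **Tertiles**: linear-interpolation quantile cuts at 1/3 and 2/3; values
  on a cut go to the lower group; the default contrast is bottom tertile vs
  the upper two (the form used by the power calculation and figure
  legends; the top-vs-bottom-two reading that appears once in the source
  narrative is available via the contrast flag — the two appear
  interchangeably there, and low-vs-medium/high is taken as authoritative).
  Tie mass that collapses a tertile is an error naming the tied value.
- **FDR**: Benjamini–Hochberg step-up, capped at 1, monotone.
- **Power**: two-sided normal-approximation power for a mean difference
  with unequal allocation; the design calculation (Δ = 0.67 log-RLU,
  SD = 0.28, 33 + 67, α = 5%) exceeds 90% power under either allocation,
  so the package asserts the bound rather than an equality, and natural
  log is used wherever "log superoxide" appears (the base is not stated in
  the source; the lognormal generator makes natural log the consistent
  choice).

## Causal inference choices

This is a **one-sample** MR with an individual-level instrument: per-variant
exposure and outcome associations for MR-Egger are computed in-sample from
the same cohort, which is winner's-curse-prone — documented, and accepted,
because that is the design being implemented. The per-variant associations
feeding Egger are computed on the raw measurement scales (Lp(a) in mg/dL,
outcome in RLU): the structural model is linear in Lp(a) on those scales, so
proportionality of outcome to exposure betas — the no-pleiotropy null — is
exact. MR-Egger itself is weighted least squares of outcome on exposure
betas with inverse-variance weights `1/se_y²` treated as *relative*
precisions: a multiplicative dispersion is estimated from the weighted
residuals and inference uses t on k − 2 df (random-effects MR-Egger). The
fixed-effect alternative is badly mis-calibrated here because in a
one-sample design the per-variant outcome SEs include exposure-mediated
variance and so overstate the dispersion around the Egger line. With the
intercept constrained to zero the slope reduces exactly to the IVW
estimate, which the tests assert.

Instrument relevance uses the single-predictor F = (n−2)R²/(1−R²) from the
first-stage regression of log-Lp(a) on the instrument (F > 10 = pass; an
exact fit reports the +Inf sentinel). The independence screen compares every
supplied covariate across GRS groups with the two-group machinery.

Mediation follows the nested-model procedure precisely — exposure
Cox model with and without log basal O2·− on the same complete-case
subjects, reporting both Wald triples, the log-HR attenuation percentage,
and the exposure–mediator Spearman correlation as collinearity context — and
deliberately *not* a counterfactual natural-effects decomposition, which the
design did not use. Under full mediation the attenuation estimate can
overshoot 100% in finite samples (the adjusted log-HR is a consistent
estimate of 0); the informative statement is the loss of significance, not
the attenuation point value.

## Numerical and reproducibility choices

EM convergence 1e-10 on frequencies; Cox score tolerance 1e-9 with
step-halving and a |β| > 20 divergence guard; bootstrap CIs are percentile
with explicit seeds; the single config seed fans out to fixed per-stage
child seeds, so stage-level reruns reproduce and `report.json` is
byte-identical for identical config + seed. Report numbers are serialized at
full precision; rounding is display-only.

Problem sizes used by the test suite are chosen to make each claim sharp at
desk scale: direction and variance-calibration properties at n = 20 000;
level calibration of the tests and of the Egger intercept at 1000 replicates
(n = 500 and n = 5000 respectively; the Egger calibration uses the
independent-variant generator, since correlated instruments violate the
independence premise of the level check); two-stage MR bias over 200
replicates at n = 2000; mediation patterns at n = 20 000; Cox oracle
equivalence against a 1e-4 grid search on ≤6-subject datasets and against an
independent reference implementation on 50 random datasets at 1e-6.

## Known limitations

The pipeline's survival models, like the design they implement, run ~10
covariates against ~20 events at the default cohort size — expect wide
intervals and occasional sign flips of the hazard ratio in any single
replicate; the cohort-level numbers (F-statistic, correlations, group
medians) are functions of the simulated cohort and are not expected to
reproduce any particular published cohort's values. Weighted-median/mode MR
estimators, multivariable MR, winner's-curse correction, two-sample MR from
external summary statistics, time-varying covariates, frailty and competing
risks are out of scope.
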