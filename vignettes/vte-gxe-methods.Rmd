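---
title: "Methods: two-population VTE association and gene-environment interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-population VTE association and gene-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtegxe)
```

## The analytical setting

`vtegxe` analyses a cross-sectional case-control contrast between two
populations — a general-population reference and a founder-structured
minority — genotyped at six prothrombotic variants: rs121909567
(SERPINC1, the antithrombin Budapest 3 founder mutation), rs1799963 (F2,
prothrombin G20210A), rs2036914 (F11), rs2066865 (FGG), rs6025 (F5,
factor V Leiden) and rs8176719 (ABO, exon-6 deletion). The outcome is
self-reported venous thromboembolism (VTE), a rare event (1.5–3% in the
target setting), which drives most of the statistical design choices
below: exact tests where counts are small, explicit handling of
complete separation, and honest flags instead of pseudo-converged
estimates.

## Population-genetic layer

Risk-allele frequency in a stratum of $n$ typed subjects is
$\hat p = (n_{het} + 2 n_{hom})/2n$; subjects missing a genotype are
excluded pairwise (per SNP), and exclusion counts are carried to the
reports.

**Hardy–Weinberg test.** With allele totals fixed, the heterozygote
count $h$ follows the conditional distribution
$P(h) \propto \binom{n}{n_1,\,h,\,n_2} 2^h$. The two-sided exact
p-value sums $P(h')$ over all $h'$ with $P(h') \le P(h_{obs})$,
evaluated on the log scale; the "$\le$" comparison uses a relative guard
of $10^{-9}$ so that ties in the discrete distribution are included
regardless of floating-point rounding. Monomorphic strata return
$p = 1$ by convention with a message. The test suite checks agreement
with an independently coded enumeration (a different combinatorial
decomposition, normalised directly) to $10^{-12}$ absolute over random
genotype tables with $n \le 500$.

**Allelic association.** The between-population contrast is the Pearson
chi-square (1 df, no continuity correction) on the 2×2 allele-count
table. No continuity correction is used because the corrected statistic
does not reproduce the marginally significant contrasts that the
uncorrected one yields at these sample sizes, and the uncorrected
statistic is the conventional allelic test. Whenever an expected cell is
below 5 *or* an observed cell is zero (the founder allele is entirely
absent from one population), a two-sided Fisher exact p-value is
reported alongside rather than instead — both views are kept. The
multiple-testing level is Bonferroni's $\alpha/m$ (0.05/6 = 0.0083 for
the default panel). Report formatting rounds p-values to two significant
figures by default; full precision is retained internally.

## Genotype-level association

Each genotype is contrasted against the non-risk homozygote. The crude
odds ratio is the 2×2 cross-product with Woolf's log-normal CI; when any
cell is zero the Haldane–Anscombe correction (0.5 to all four cells) is
applied and flagged, which keeps every OR finite and positive. The
age-adjusted OR comes from a binomial GLM fitted by IRLS
(convergence tolerance $10^{-10}$, up to 100 iterations). Separation is
declared when a fitted coefficient exceeds 15 in absolute value on the
log-odds scale: at that point the likelihood is flat and the "estimate"
is an artifact of the stopping rule, so the table reports a sentinel of
0 with `separation = TRUE` instead. A `compat_raw` switch prints the raw
diverged value for display-compatibility with legacy software output
(which renders such strata as numbers like `2.2E-8`), but it is not an
estimate and the flag stays set. Firth or Bayesian rare-event
corrections are deliberately out of scope; the separation flag plus the
Haldane-corrected crude OR are the package's answer.

Age enters all adjusted models linearly in years; no transform is
applied because none is implied by the design.

## Genetic risk scores

Dosages are coded 0/1/2 in copies of the risk allele; at loci whose
nominal risk allele acts protectively (`flip = TRUE`) the coding is
reversed ($d \mapsto 2-d$), making the heterozygote a fixed point. uGRS
is the plain dosage sum (integer, in $[0, 2m]$ for $m$ SNPs); wGRS
weights each dosage by an external natural-log odds ratio. The founder
mutation has no published external weight, so the default weighted panel
is the other five SNPs. The shipped weights are illustrative
placeholders on the scale of published VTE effect sizes (e.g. ln 4.2 for
factor V Leiden, ln 2.8 for prothrombin G20210A); they are configuration,
not results, and live in an editable YAML file
(`inst/extdata/snp_panel.yaml`). All weighted-score testing is therefore
property-based (orientation invariance, arithmetic identities,
distributional convolution) rather than anchored to any published score
summary.

Dichotomization supports two rules. The explicit rule takes a low band
(default scores 0–1) and a high cut (default $\ge 3$); subjects between
the bands are excluded *and counted*, making the silent middle-band drop
of "$\ge 3$ vs 0–1" comparisons transparent. The median rule splits at
the median with ties assigned high, consistent with "$\ge$ median"
phrasing. Subjects missing any panel dosage are excluded from scores
rather than imputed.

## Gene–environment interaction

**Covariate normalisation.** The two-step rank-based inverse-normal
transformation maps fractional ranks (mean rank at ties) to percentiles
$r/(n+1)$, takes standard-normal quantiles, and rescales them to the
original mean and SD. The explicit re-centering/re-scaling of the
quantiles makes the output's first two moments equal the input's exactly
rather than approximately. It requires at least three distinct values
and fails loudly on constants.

**Exposures.** Binary conditions are used as-is; continuous exposures
are dichotomized at the conventional clinical cut-offs: TC $\ge$ 5.2,
LDL-C $\ge$ 3.4, HDL-C $<$ 1.3 (low HDL is the risk direction), TG
$\ge$ 1.7 mmol/L, BMI $>$ 30 kg/m².

**Regression.** The primary interaction fit is a linear-probability
model: OLS of the 0/1 outcome on G (dosage), E, G×E and age, with
standardized coefficients $\beta \cdot SD(x)/SD(y)$ and t-based
p-values. The linear formulation is the primary one because it is the
analysis this package sets out to reproduce and standardized betas are
its reporting currency; a logistic mirror is available through
`fit_logistic()` on the same design for sensitivity. Combined-cohort
fits can include an ethnicity indicator, but per-population stratified
fits are the primary report.

**Stratum odds ratios and verdicts.** G is binarized as carrier
(dominant) by default — the natural choice for rare alleles, where
recessive cells are nearly empty — configurable to recessive or a dosage
threshold. OR01, OR10, OR11 are cross-products against the doubly
unexposed cell with Haldane correction as needed; empty cells flag the
result and the flag propagates through classification rather than being
silently dropped. The multiplicative verdict compares OR11 with
OR01·OR10, the additive verdict takes the sign of
RERI = OR11 − OR01 − OR10 + 1; an optional relative tolerance band turns
near-equalities into "none". Because point verdicts at a few hundred
subjects with ~15 cases are noise-dominated, `bootstrap_interaction()`
adds a seeded percentile bootstrap (default 2,000 resamples) of both
contrasts and reports CI-aware verdicts alongside the point ones. Note
the known scale dependence the framework encodes: data generated under a
logistic (odds-multiplicative) model with positive main effects are
multiplicative-null but additive-synergistic (RERI > 0) — the test suite
asserts exactly this.

No multiple-testing adjustment is applied across the SNP × exposure grid
in the primary output, faithfully to the analysis being reproduced; a
Benjamini–Hochberg column is available via `add_bh = TRUE`.

## The synthetic-cohort generator

The generator emulates the study conditions: two populations of 406 and
395 subjects; HWE genotypes (binomial(2, p), no LD) at the published
per-population frequencies, including the founder allele at 1% vs 0;
female shares 55.4% / 73.9%; covariates normal at the published means
with SDs back-calculated from the published 95% CIs of the means using
the *study* sample sizes (e.g. age SD ≈ 12.3 y, BMI SD ≈ 5.1 kg/m²) —
the SDs are population properties and do not change with the simulated
n. Triglycerides default to a moment-matched log-normal to provide a
realistically right-skewed variable for the inverse-normal transform.
Ages are truncated to the enrolment range 20–64. Condition prevalences
are not published for the cohort, so the defaults (cancer 3%, diabetes
10%, CAD 8%, CKD 3%, migraine 12%, depression 10%, current smoking 35%)
are nominal adult-population values, clearly labelled non-study numbers;
obesity is derived from BMI > 30 rather than drawn, keeping the flag
consistent with the covariate. The VTE outcome is Bernoulli with
probability the inverse-logit of a configurable linear predictor
(default intercept logit(0.02), i.e. 2% baseline); conditions are
generated independently of genotypes unless a coefficient links them,
treating them as exposures rather than mediators.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: linkage disequilibrium between panel SNPs,
correlated comorbidities, covariate measurement error, genotype
missingness patterns, and any population structure beyond the two-label
split. `make_paper_fixture()` is the complement: a deterministic cohort
that reproduces the published genotype × outcome × population margins
exactly, with covariates frozen at population means — valid for
count-level computations only, since between-SNP joint distributions are
arbitrary and covariates carry no variance.

## Numerical choices and problem sizes

Calibration and recovery checks run at sizes chosen to keep Monte Carlo
error far below the asserted tolerances: allele-frequency recovery at
n = 100,000 against a ±0.005 band (binomial SE ≈ 0.001); main-effect and
interaction log-OR recovery at n = 200,000 against ±0.1 bands (Wald SE
≈ 0.03–0.07); and the type-I error of the linear-probability interaction
test over 1,000 replicates at n = 5,000 against a [0.03, 0.07] band.
The type-I calibration generates under the complete null (constant
outcome probability 3%), where the linear-probability model is correctly
specified and homoscedastic and the t-test is exactly calibrated. This
is a deliberate choice: under a null that retains main effects on a rare
binary outcome, the classical (non-robust) OLS t-test on the interaction
term is anticonservative — we measure a size near 0.10 at these settings
— because cell variances $p(1-p)$ differ several-fold while OLS pools
them. That anticonservatism is a genuine limitation of the
linear-probability formulation with classical standard errors and should
be kept in mind when reading interaction p-values from it; the logistic
mirror does not share it.

## Known limitations

- Verdicts from stratum ORs at the real study's size (~800 subjects, 18
  cases) are dominated by sampling noise; use the bootstrap verdicts.
- The ABO locus is modelled abstractly as C/DEL with the deletion as the
  default risk orientation — the only orientation under which the
  published frequency and genotype tables are mutually consistent; the
  orientation is configurable.
- wGRS results depend entirely on the configured weights; the shipped
  values are placeholders.
- The generator draws conditions independently; real comorbidities
  cluster.
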