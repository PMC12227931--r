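---
title: "Methods: autoimmune comorbidity in MS and the cumulative polygenic risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autoimmune comorbidity in MS and the cumulative polygenic risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbprs)
```

## The scientific problem

People with multiple sclerosis (pwMS) carry an excess burden of other
autoimmune diseases (AIDs). Two questions drive the design of this package:

1. **Epidemiological**: how much more prevalent are 14 AIDs among pwMS than
   among MS-free residents of the same region, once age, sex and
   healthcare-contact frequency are accounted for? The data source is not a
   clinical registry but *linked administrative health archives* — hospital
   discharges, pharmacy prescriptions, co-payment exemption certificates and
   long-term-care residence lists — in which diseases are not recorded
   directly but must be inferred by case-finding algorithms.
2. **Genetic**: do pwMS who carry an autoimmune comorbidity have a larger
   burden of known autoimmune susceptibility alleles than pwMS without one?
   The instrument is a *cumulative polygenic risk score*: per disease, an
   unweighted count of risk alleles normalized by the maximum achievable
   count, summed over nine diseases.

Individual-level archive and genotype data of this kind are never public, so
the package is built around a synthetic-data generator that reproduces the
statistical structure the analysis relies on. Every downstream stage is
tested against simulator ground truth.

## The simulator and what it does (and does not) emulate

`sim_config()` + `simulate_population()` draw a population with:

* true MS status at the reference date (default 2017-12-31) with prevalence
  $8850 / (8850 + 4{,}265{,}864) \approx 2.07$ per 1000;
* 14 AID flags, conditionally independent given MS status. The per-disease
  log-odds is $\operatorname{logit}(p_d) + \log(\mathrm{OR}_d)\,[\text{MS}]$,
  with baseline prevalences $p_d$ and odds ratios $\mathrm{OR}_d$ defaulting
  to the values implied by the packaged reference counts
  (`default_disease_table()`). Optional per-disease sex and age terms exist
  but default to zero, so a crude $2\times2$ count on the generated truth
  recovers the configured odds ratio — this is the property the generator
  tests lean on;
* sex (female fraction 0.676 among MS, 0.515 otherwise) and age (normal,
  MS mean 50.0 SD 13.7; non-MS mean 47 SD 19 — the non-MS moments are not
  published and were chosen once as a realistic regional age structure),
  truncated to [0, 100];
* a 5-year hospitalization count, negative binomial (size 1.2) with mean
  multiplied by 2.2 for MS and by a per-disease factor — contact counts in
  administrative data are overdispersed and strongly group-dependent.

`simulate_events()` turns truth into archive rows. The validated MS
case-finding algorithm is characterised at the *algorithm level*
(sensitivity 95.9%, specificity 99.9%). Under independent streams, the
per-stream emission rates that reproduce that union operating point are
$s_k = 1-(1-s)^{1/k}$ and $\mathrm{spec}_k = \mathrm{spec}^{1/k}$
(`calibrate_stream_rates()`). A firing stream emits the algorithm's minimum
qualifying count of coded events at uniform dates in the lookback window;
hospitalizations for any cause are emitted as `HOSP_ANY` discharge rows.
Setting `surveillance_log_or > 0` makes *every* per-stream emission
probability rise with the subject's hospitalization count, which is exactly
the surveillance-bias mechanism the fully adjusted model is meant to absorb.

Deliberately **not** emulated: real ICD-9-CM/ATC code semantics (codes are
opaque tokens shared between simulator and algorithms), within-subject onset
dynamics, mortality, AID–AID correlation beyond what MS induces, and
genotype imputation itself (dosages are generated directly with an `r2`
annotation). Passing tests therefore demonstrate that the *machinery* is
correct under the stated generative assumptions — not that those assumptions
hold in any particular real archive.

## Case finding

`case_algorithm()` is declarative: per-stream code sets and minimum counts,
an any/all combination rule, a lookback window, and an optional exclusion
rule. Design choices where the source material was open:

* **Exclusion anchor.** The thyrotoxic-drug exclusion ("in the 12 months
  prior to diagnosis") needs a diagnosis date that administrative data do
  not contain; we anchor the window at the subject's *first qualifying
  event*, the natural proxy.
* **Combination rule.** Default is *any* qualifying stream, matching the
  union-style enrichment of multi-source case finding; `rule = "all"` is
  available per algorithm.
* **"Same age range".** The MS-free comparison population is restricted to
  the closed integer interval $[\min, \max]$ of ages observed among flagged
  MS subjects — the simplest faithful reading.
* **Lookback window.** The archives cover either 2012–2017 or 2013–2017
  depending on where one reads; the window is an explicit config value and
  defaults to the five full years ending at the reference date
  (2013-01-01 to 2017-12-31).

`evaluate_algorithm()` returns the exact 2×2 ratios; `build_cohort()`
assembles one analysis row per alive subject and errors on duplicate ids.

## Association estimation

* `prevalence_per_1000()` reports the conventional 2-decimal rounding but
  retains the exact ratio (`digits = NULL`); the count round-trip invariant
  only holds for the exact value, which is why both are exposed.
* `crude_or()` is closed-form $ad/bc$ with a Wald interval; the
  Haldane–Anscombe 0.5 correction is applied only when a cell is zero and is
  flagged. It exists chiefly as the analytic oracle for the exposure-only
  logistic fit, which must agree with it to six significant digits.
* `fit_adjusted_logistic()` is binomial maximum likelihood via IRLS
  (`stats::glm`, relative deviance tolerance $10^{-10}$, 100 iterations).
  Covariates enter untransformed: age in years, sex coded female = 1,
  hospitalization count. Wald intervals are reported, matching conventional
  epidemiological software output; profile-likelihood intervals were
  deliberately not used. Perfect separation is detected (fitted
  probabilities at the boundary together with exploding coefficients) and
  flagged with `NA` odds ratios rather than reported as estimates.
* `baseline_tests()` uses Pearson χ² (1 df, no continuity correction —
  samples are large throughout) and one-way ANOVA F tests; zero-variance
  groups raise an error instead of returning `NaN`.
* No multiple-testing correction is applied, mirroring the source analysis.

## Genotype quality control

The cascade order is fixed and recorded in the `QcReport`, each filter
recomputed on the survivors of the previous: duplicates (pairwise
best-guess identity > 0.95 — a deliberate proxy for IBD-based duplicate
detection that tests the same intent without PLINK/KING machinery),
heterozygosity outliers (|rate − mean| > 3 SD), sample call rate (< 0.95;
the source threshold is unpublished, so the default is explicit and
configurable), sex discrepancy (X heterozygosity heuristic, only when X
variants and reported sex exist), PC outliers (> 3 SD on any of the first
three components), then variant filters: call rate ≥ 0.90, MAF ≥ 0.01,
HWE p ≥ 10⁻⁶, and post-imputation r² ≥ 0.6 with MAF ≥ 0.001 (strictly
"below fails": r² = 0.6 survives).

Numerical notes:

* `hwe_test()` is the 1-df χ² goodness of fit with exact rational expected
  counts; the exact test was considered and rejected because at a 10⁻⁶
  threshold with common variants the χ² approximation is adequate — the
  uniformity of its p-values under equilibrium is itself a test.
* `dosage_to_best_guess()` resolves ties at 0.5/1.5 toward the heterozygote
  so the conversion is deterministic.
* `compute_pcs()` standardises each variant by $\sqrt{2p(1-p)}$, mean-imputes
  missing calls, drops constant variants, and fixes each component's sign by
  making its largest-magnitude loading positive, so results are reproducible
  across runs and platforms. PCs are computed on an LD-naive variant set;
  pruning is out of scope because the synthetic variants carry no LD.
* Idempotence: re-running the cascade on its own output removes nothing on
  clean data, and the test suite checks this at a fixed seed. With 3-SD
  rules this is not a theorem — re-estimated standard deviations shrink
  after removals — so pathological inputs can oscillate; the report makes
  any such behaviour visible.

## The cumulative score

For disease $d$ with panel size $n_d$, the raw score is the unweighted
risk-allele count over the panel's non-HLA variants (best-guess genotypes),
normalized by the maximum achievable score $2 n_d$; the nine normalized
scores sum to $\mathrm{PRS_{comorb}} \in [0, 9]$. The nine diseases are MS,
RA, celiac disease, T1DM, Hashimoto thyroiditis, hypothyroidism, SLE,
psoriasis and ankylosing spondylitis; synthetic panel sizes span the
published 23 (AS) to 201 (MS) range. MS's own panel is included even though
both comparison groups have MS: it contributes level but only differential
carriage can move the group contrast.

**HLA integration.** "Complementing each disease score with the HLA burden,
then repeating the normalization" admits two readings. The implemented one
appends the disease's classical HLA carrier counts (each in {0, 1, 2}) to
the raw score and enlarges the denominator to $2(n_d + n_{\mathrm{HLA},d})$;
with empty HLA panels this reduces exactly to the SNP-only score, an
invariant the tests assert. The alternative (a separately normalized HLA
term) was considered; the chosen reading keeps every disease's contribution
in [0, 1], which the "nine normalized scores" phrasing requires.

**Missing data.** Post-QC panels are expected complete. If a panel variant
is nonetheless missing, the score is rescaled by
$n_{\text{panel}} / n_{\text{observed}}$ and flagged; `missing_rule =
"strict"` errors instead, naming the variants. Unweighted counting is the
only scoring mode — effect-size weighting is out of scope.

**Group comparison.** `compare_prs_groups()` is OLS of the score on the
comorbidity indicator plus covariates with a two-sided t test on the group
coefficient. Both reported covariate sets are always fitted: age + sex +
PC1–3 and age + PC1–3. PC outliers are expected to be removed beforehand
(the QC cascade does this); collinear covariates are flagged.

## Calibration of the genotype generator

The enrichment parameter is a per-allele log-odds shift of risk-allele
frequency in comorbid subjects. The default 0.03 was sized once by a delta
argument: with the default panels the expected cumulative-score shift is
$\approx 9 \cdot 0.21\varepsilon$ against a between-subject SD of
$\approx \sqrt{\sum_d 0.1 / n_d} \approx 0.13$, giving a standardized
difference near 0.4 at $\varepsilon = 0.03$ — a moderate, realistic effect
at the study's 65-vs-572 group sizes. Monte-Carlo power checks of the full
pipeline use a supra-threshold calibration ($\varepsilon = 0.06$,
standardized ≈ 0.75) so that a 100-replicate test is informative about the
pipeline rather than about sampling noise at the 80% power boundary; the
unbiasedness of the group-effect estimate is checked separately at the
standardized 0.4 effect planted directly on scores.

## Problem sizes used by the test suite

Simulation sizes were chosen so the whole suite exercises every stage at
meaningful precision: 200,000 subjects for the operating-point recovery
(≈ 400 true MS cases, binomial SE ≈ 1 percentage point), 500,000 for the
odds-ratio convergence regression, 200 replicates of n = 100,000 for
adjusted-OR coverage, 2,000 replicates at n = 637 (65 vs 572) for the
ANCOVA type-I error (Monte-Carlo SE ≈ 0.5 percentage points), 5,000
equilibrium variants for HWE uniformity, and 100 full-pipeline replicates
for power. Tolerances on Monte-Carlo quantities are stated in standard
errors of the corresponding estimator, never tighter.

## Known limitations

* Case-finding algorithms for the 14 AIDs are exercised only against the
  synthetic code vocabulary; nothing here validates real code lists.
* The simulator's conditional-independence assumption for AIDs given MS
  ignores AID–AID clustering; estimates of *joint* comorbidity burden would
  need a richer generator.
* The surveillance-bias mechanism is single-parameter and acts identically
  on true and false positives; real detection processes are more
  heterogeneous, so the attenuation direction — not its magnitude — is the
  reproducible claim.
* HLA alleles are treated as independent diallelic carrier loci; real
  classical HLA alleles are mutually exclusive haplotypes with strong LD.
* The published ANCOVA p-values (0.0078 / 0.015) depend on the real
  genotypes and are not reproducible from synthetic data; the package
  reproduces the *procedure* and its operating characteristics instead.
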