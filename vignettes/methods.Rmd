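---
title: "Methods: allele-score Mendelian randomisation of vitamin D and blood pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-score Mendelian randomisation of vitamin D and blood pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The causal model and its assumptions

`vitdmr` estimates the causal effect of circulating 25-hydroxyvitamin D
(25(OH)D) on systolic and diastolic blood pressure and on hypertension,
using a genetic instrument: the unweighted synthesis allele score, the sum
(0–4) of 25(OH)D-increasing alleles at *DHCR7* rs12785878 and *CYP2R1*
rs12794714. These genes act upstream of 25(OH)D production, so the score
proxies lifelong differences in vitamin D status while being independent of
the behavioural and metabolic confounders that plague the phenotypic
association. The parallel metabolism score (*GC* rs2282679, *CYP24A1*
rs6013897) is carried through the same machinery but, because both genes
have documented pleiotropy and feedback behaviour, it is exploratory and is
never used as the causal instrument.

The estimator is the two-stage Wald ratio. Let $\beta_{ZX}$ be the pooled
score–25(OH)D association expressed as percent difference per allele, and
$\beta_{ZY}$ the pooled score–outcome association per allele (mm Hg, or
log-odds for hypertension). The causal effect per 10% increase in 25(OH)D is

$$\hat\beta_{IV} = \frac{\beta_{ZY}}{\beta_{ZX}}\times 10,\qquad
\widehat{var}(\hat\beta_{IV}) = \left(\frac{se_{ZY}^2}{\beta_{ZX}^2} +
\frac{\beta_{ZY}^2\,se_{ZX}^2}{\beta_{ZX}^4}\right)\times 10^2 ,$$

the variance being the first-order Taylor expansion (delta method) of the
ratio with the numerator–denominator covariance set to zero. The two pooled
coefficients usually come from overlapping samples, so this covariance is
not truly zero, but it is unestimable from summary data; setting it to zero
matches the standard two-stage ratio and the assumption is recorded in the
estimate's metadata. Wald intervals use the normal reference (not t),
consistent with the meta-analytic origin of both inputs. For hypertension
the ratio is formed on the log-odds scale and exponentiated after interval
construction.

The usual IV assumptions apply: the score is associated with 25(OH)D
(testable, via the F-statistic), affects the outcome only through 25(OH)D
(supported biologically for the synthesis genes, untestable in general),
and shares no confounder with the outcome (plausible for germline
genotype). Instrument strength is summarised by
$F = R^2 (n-2) / (1-R^2)$, with $1/F$ the approximate bias of the IV
estimate relative to ordinary least squares.

## Scales and conventions

* 25(OH)D is analysed as its natural log; a log-scale coefficient $b$ is
  reported as $100(e^{b}-1)$ percent per allele. The alternative convention
  $100\,b$ differs by under 2% at the effect sizes involved
  ($b \approx 0.028$); the choice is isolated in `percent_per_allele()` /
  `ln_per_allele()` so the other convention is a one-line change.
* "Per 10% increase" is implemented as division by the percent-per-allele
  effect followed by multiplication by 10 (linear in percent). For
  phenotypic regressions fitted per ln-unit, the pipeline rescales by
  $\ln(1.1)$, the exact log-scale equivalent of a 10% increase; the two
  conventions differ by about 1.5% at these magnitudes.
* Hypertension is classified on *observed* pressure (SBP ≥ 140 mm Hg,
  DBP ≥ 90 mm Hg, both inclusive, or current antihypertensive use); the
  +15/+10 mm Hg treatment correction applies only to the continuous
  outcomes, and is written to new `sbp_adj`/`dbp_adj` columns so it cannot
  be applied twice.

## Meta-analysis

Per-study coefficients are pooled by inverse variance. Fixed-effect
pooling uses $w_i = 1/se_i^2$, with Cochran's $Q$, $df = k-1$ and
$I^2 = \max(0, (Q-df)/Q)\cdot 100$. When the heterogeneity p-value falls
strictly below `alpha_q` (default 0.05 — the rule is stated qualitatively
in the literature, the cut-off is this package's choice; ties stay fixed)
the DerSimonian–Laird random-effects model is used:
$\tau^2 = \max\{0, (Q-df)/(\sum w - \sum w^2/\sum w)\}$, re-pooled with
$w_i^* = 1/(se_i^2+\tau^2)$. DerSimonian–Laird (not REML) was chosen as
the standard estimator of the analysis era this pipeline reconstructs.
Univariate meta-regression uses weighted least squares with a residual
method-of-moments $\tau^2$ folded into the weights, matching the classic
`metareg` behaviour; both pooling and meta-regression are cross-checked
against `metafor` in the test-suite. Every fixed/random decision is logged
in the pipeline's report bundle.

### Score effects from summary statistics

Consortium data arrive as per-SNP rows. After harmonisation, the
per-allele effect of an unweighted score is approximated by
dosage-variance weights $v_j = 2\,\mathrm{EAF}_j(1-\mathrm{EAF}_j)$:
$\hat\beta_s = \sum_j v_j\beta_j / \sum_j v_j$,
$se_s = \sqrt{\sum_j v_j^2 se_j^2}/\sum_j v_j$ under SNP independence.
The original approximation method is not spelled out in the source
literature; dosage-variance weighting is this package's reconstruction. It
is isolated behind `approximate_score_effect()`, which also offers a plain
unweighted mean as the obvious alternative, and both are validated against
individual-level score regression on simulated cohorts (agreement within
three combined standard errors at n = 50 000). Combination with the
cohort meta-analysis is a further inverse-variance step; which studies
overlap a given consortium is configuration, never inferred.

### Harmonisation

External rows are oriented to the 25(OH)D-increasing allele: matching
rows are kept, swapped alleles flip the beta sign and replace EAF by
1 − EAF, and strand complements are resolved the same way. Palindromic
SNPs (A/T, C/G) have no resolvable strand from alleles alone, so they are
excluded with a warning by default — a deliberately conservative rule.
`keep_palindromic = TRUE` treats rows as forward-strand and exists because
the default panel itself contains a palindromic variant (*CYP24A1*
rs6013897 is T/A); it should be used only for tables whose strand
convention is known, such as summary statistics emitted by this pipeline.

## The regression engine

Linear models are ordinary least squares with the covariates partialled in
the same fit; when `age` is among the covariates an age-squared term is
added internally, mirroring the standard adjustment set (age, age², BMI,
sex, plus user-supplied region/principal-component columns; models with
ln 25(OH)D as outcome add month of blood draw and laboratory batch).
Missingness is handled per model by complete-case filtering, with counts
of individuals dropped from score analyses reported. Rank-deficient
designs are an error naming the collinear columns. Logistic models use
iteratively reweighted least squares with convergence tolerance $10^{-8}$
and at most 50 iterations (R's deviance-based criterion, treated as
equivalent to a score-norm criterion at this tolerance); perfect
separation is detected (fitted probabilities pinned at 0/1, diverging
linear predictor) and raised as an error rather than returned as a huge
finite coefficient. Optional adjustment for serum triglycerides and total
cholesterol is provided as a pleiotropy sensitivity switch, since 25(OH)D
is a cholesterol derivative.

## What the simulator emulates — and what it does not

`sim_config()`/`simulate_studies()` generate the multi-cohort structure
the analysis assumes, so that calibration is testable end to end:

* Genotypes: Binomial(2, EAF) per SNP — Hardy–Weinberg, no linkage
  disequilibrium (the panel genes are on different chromosomal regions, and
  the score arithmetic treats loci as independent).
* ln 25(OH)D: baseline mean 4.0 log-nmol/L (≈ 55 nmol/L), additive SNP
  effects, a seasonal cosine over month of blood draw (amplitude 0.15
  log-units, peaking in August — realistic for European latitudes),
  centred age/BMI and sex terms (default BMI effect −0.012 per kg/m²),
  small laboratory batch offsets, residual SD 0.35.
* Blood pressure: confounder terms shared with 25(OH)D (BMI, age, sex),
  optional causal effect of ln 25(OH)D (mm Hg per log-unit; 0 by
  default), residual SDs 15/10 mm Hg with residual correlation 0.6
  between arms so diastolic stays below systolic at physiologic rates.
* Treatment: antihypertensive use drawn from a logistic model on latent
  systolic pressure; observed pressure in treated individuals is lowered
  by exactly 15/10 mm Hg, so the +15/+10 correction is exact in
  expectation and recoverable.
* Multi-study runs derive one random substream per study (seed hashed
  with the study's position), so studies sharing a seed value remain
  independent; a single config reproduces `simulate_cohort()` exactly,
  and a fixed seed reproduces tables byte-identically.

The default per-SNP frequencies and effects were chosen once so the
synthesis score's association with 25(OH)D is about 2.8% per allele and
the metabolism score's about 5.4% — the magnitudes reported in
European-ancestry cohorts; they are simulation defaults, not estimates.
The magnitude of confounding is not documented in the source literature,
so the defaults are illustrative. The simulator does *not* model linkage
disequilibrium, imputation uncertainty, population stratification,
non-European allele frequencies, family structure, or assay differences
between laboratories beyond an additive batch shift. Passing tests
therefore demonstrate the statistical machinery is correct under the
stated generative model, not that real-data complications are handled.

## Numerical and design choices

* `iv_ratio()` refuses a non-positive denominator (a flipped or null
  instrument is misuse, not a number); `taylor_se()` refuses
  $\beta_{ZX}=0$; `f_statistic()` requires $0 \le R^2 < 1$, $n > 2$.
* Non-positive 25(OH)D values are rejected by the log transform with the
  offending records named; a missing treatment flag is an error, never a
  silent "untreated".
* Heterogeneity boundary: $p_Q$ exactly equal to `alpha_q` stays with
  fixed effects (strict inequality).
* The end-to-end recovery experiment in the test-suite defines truth on
  the per-10% scale the estimator targets: the generator's causal effect
  (per ln-unit) is set to
  $c = \beta_{10} \cdot 100(e^{b}-1)/(10\,b)$ for score ln-scale effect
  $b$, making the estimand exactly $\beta_{10}$.
* Problem sizes used by the test-suite were chosen as the smallest that
  give stable Monte-Carlo verdicts: 200 replicates of 20 cohorts of
  n = 1 000 for coverage and bias of the IV estimator; n = 50 000 for the
  summary-approximation identity; $10^5$ draws for the parametric
  bootstrap against the delta-method SE.

## Limitations

The pipeline reconstructs a 2014-era analysis: no pleiotropy-robust
estimators (weighted median, MR-Egger, mode-based), which post-date it;
no REML heterogeneity estimation; no LD-aware proxy search or reference
panel strand inference; principal components are accepted as covariate
columns but never computed. The delta-method interval is known to
undercover when the instrument is weak — the bootstrap comparison in the
test-suite is restricted to the strong-instrument regime (denominator
F > 100) for exactly that reason.
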