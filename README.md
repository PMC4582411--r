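# vitdmr

Allele-score Mendelian randomisation of vitamin D status against blood
pressure and hypertension risk, as a reusable, tested R pipeline.

## The scientific problem

Observationally, low circulating 25-hydroxyvitamin D (25(OH)D, nmol/L) is
associated with higher blood pressure and hypertension risk, but the
association is heavily confounded (adiposity, age, season, health
behaviours) and open to reverse causation. Mendelian randomisation (MR)
sidesteps both: genotypes are allocated at meiosis, so a genetic variant
that raises 25(OH)D acts as a randomised, lifelong "dose" of vitamin D
status. `vitdmr` implements the full analysis for epidemiologists working
with multi-cohort collaborations and published GWAS summary statistics:

* an **unweighted synthesis allele score** (0–4) summing the
  25(OH)D-increasing alleles of *DHCR7* rs12785878 and *CYP2R1* rs12794714
  (variants upstream of 25(OH)D production — the valid instrument), and a
  parallel **metabolism score** (*GC* rs2282679, *CYP24A1* rs6013897) for
  exploratory use;
* per-study adjusted regressions of the score and of ln 25(OH)D on blood
  pressure outcomes, pooled by inverse-variance meta-analysis with a
  heterogeneity-driven fixed/random-effects rule, Cochran's Q, I², the
  DerSimonian–Laird τ², and univariate meta-regression;
* harmonisation of external per-SNP summary statistics to the
  25(OH)D-increasing allele and their combination into score effects via
  dosage-variance weights, v_j = 2·EAF_j·(1−EAF_j);
* the **instrumental-variable (Wald) ratio**: with β_ZX the score–25(OH)D
  association (percent per allele) and β_ZY the score–outcome association
  (per allele),

      β_IV per 10% increase in 25(OH)D = (β_ZY / β_ZX) × 10,
      var(β_IV) = se_ZY²/β_ZX² + β_ZY²·se_ZX²/β_ZX⁴   (first-order Taylor
      expansion, numerator–denominator covariance 0)

  with log-odds numerators for hypertension, exponentiated to odds ratios
  after interval construction;
* instrument diagnostics F = R²(n−2)/(1−R²) and relative bias 1/F;
* a multi-study **simulator** (Hardy–Weinberg genotypes, log-normal
  25(OH)D with seasonal and confounder structure, treatment-masked blood
  pressure) so every stage is testable without access to individual-level
  cohort data.

Phenotype definitions follow the standard conventions: hypertension is
SBP ≥ 140 mm Hg, DBP ≥ 90 mm Hg or current antihypertensive use; treated
individuals' continuous pressures are corrected by +15/+10 mm Hg.

## Worked example

The package ships a small association table on the published scale
(per-allele synthesis-score coefficients for each outcome and the
score–25(OH)D association of 2.83% per allele). Running the pipeline in
load mode triangulates phenotypic, genetic and causal estimates:

```r
library(vitdmr)
bundle <- run_pipeline(run_config(
  mode = "load", assoc_path = worked_example_path(),
  instrument = list(f_stat = 219.7)
))
dplyr::select(bundle$triangulation, outcome, phenotypic, genetic_per_allele,
              iv_estimate, iv_ci_low, iv_ci_high, iv_p)
#> # A tibble: 3 × 7
#>   outcome  phenotypic genetic_per_allele iv_estimate iv_ci_low iv_ci_high   iv_p
#>   <chr>         <dbl>              <dbl>       <dbl>     <dbl>      <dbl>  <dbl>
#> 1 sbp           -0.12              -0.1       -0.353    -0.727     0.0201 0.0636
#> 2 dbp           -0.02              -0.08      -0.283    -0.515    -0.0504 0.0171
#> 3 hyperte…       0.98               0.98       0.931     0.881     0.984  0.0111
bundle$diagnostics
#> <instrument diagnostics> R2 = NA, n = NA, F = 219.7, relative bias = 0.455%
```

Reading: each 10% increase in genetically indexed 25(OH)D lowers diastolic
pressure by 0.28 mm Hg (95% CI 0.05–0.52) and the odds of hypertension by
about 7% (OR 0.93, here computed from the rounded per-allele inputs);
an instrument F-statistic of 219.7 means weak-instrument bias is ~0.5% of
the observational estimate. In simulate mode the same call generates a
20-study collaboration and runs everything from individual-level data:

```r
sim <- run_pipeline(run_config(mode = "simulate", seed = 1))
sim$diagnostics   # instrument strength in the simulated data
# forest plot of the pooled score-25(OH)D association across studies
per_study <- dplyr::filter(sim$associations,
                           exposure == "score_synthesis", outcome == "ln25ohd")
autoplot(run_meta(per_study))
```

A thin command-line wrapper is installed at
`inst/scripts/vitdmr-pipeline.R` (`--config`, `--seed`, `--out`,
`--alpha-q`, `--lipid-adjust`), writing per-study, meta-analysis and
triangulation TSVs plus a JSON log of every model-selection decision.

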