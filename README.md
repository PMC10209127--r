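# chtrace

Clonal haematopoiesis (CH) arises when a blood stem cell acquires a driver
mutation (a **CHDM**, most often in *DNMT3A*, *TET2* or *ASXL1*) and expands
into a detectable clone, measured by the variant allele frequency (**VAF**,
in percent; ≥ 2% defines CHIP). `chtrace` is an R package for analysing CHDM
dynamics from ultrasensitive dual-replicate targeted sequencing, aimed at
groups studying clone growth in longitudinal cohorts and its relation to
metabolic risk factors.

It implements, end to end:

* **Detection** — replicate-aware calling from read-count pairs: detected iff
  alt reads ≥ `min_alt_reads` in *both* technical replicates and mean VAF ≥
  the assay floor; reported VAF is the mean of the replicate VAFs.
* **Trajectories** — per-individual, per-mutation VAF time series: ≥ 3
  detections make a *traceable trajectory*, otherwise an *event*; traceable
  trajectories are *growing* / *static* / *shrinking* by whether the final
  minus first detected VAF is ≥ +0.5, within ±0.5, or ≤ −0.5 percentage
  points; late-appearing clones (events of ≥ 2% VAF at the last visit) and
  disappearances are flagged; each individual's *dominant* trajectory
  (highest VAF at any timepoint) enters the growth analysis, with
  shrinking-dominant individuals excluded (retained in a sensitivity
  analysis).
* **Growth model** — ln *v<sub>ij</sub>* = (β₀+b₀ᵢ) + (β₁+b₁ᵢ) ageᵢⱼ + εᵢⱼ
  with correlated random intercept/slope (REML via `lme4`). The individual
  slope β₁+b₁ᵢ converts to a proportionate annual growth rate
  100·(e^(β₁+b₁ᵢ) − 1) % per year. Cross-sectional companions: logistic
  regression of carrier status on age, OLS of ln(max VAF) on age.
* **Associations** — derived clinical indices (HOMA-IR, Friedewald LDL-C,
  non-HDL-C, hypertension/diabetes flags), covariates averaged over the
  first three follow-up visits, Spearman correlation of growth rates with a
  Bonferroni-corrected 10-covariate primary family plus unadjusted secondary
  covariates.
* **Cohort summaries** — Table-1-style descriptives, prevalence and CHIP
  fractions, t / chi-square / Wilcoxon group comparisons.
* **Synthetic cohorts** — a generator reproducing the longitudinal study
  structure (staggered visits over 20 years with missingness, Poisson
  coverage and binomial read noise, log-normal clone sizes with geometric
  growth, a Gaussian copula tying true growth rank-correlation −0.68 to
  HDL-C), so the whole pipeline is testable without human data.

## Worked example

```r
library(chtrace)

cfg    <- cohort_config(seed = 2024)           # 40 individuals, 0/2/10/15/20 y
cohort <- generate_longitudinal_cohort(cfg)
report <- run_longitudinal(cohort$observations, cohort$clinical)
#> excluding 3 individual(s) with a shrinking dominant trajectory
print(report)
```

```
CHDM trajectories: 49 total; 0 events, 49 traceable ( 34 growing / 12 static / 3 shrinking )
Individuals excluded for shrinking dominant trajectory: 3
Random-intercept/random-slope clone growth model (log VAF)
  individuals: 37  points: 166
  fixed slope: 0.0658 per year  (6.8% per year)
  mean individual rate: 6.91 % per year; range -0.707 to 21.413

Associations with averaged clinical covariates:
            covariate  n spearman_r    p_raw p_bonferroni      family
                  bmi 37   0.142722 0.397979       1.0000     primary
         hdl_c_mmol_l 37  -0.651731 0.000020       0.0002     primary
 triglycerides_mmol_l 37   0.146989 0.383900           NA   secondary
         hdl_c_mmol_l 40  -0.533396 0.000479           NA sensitivity
```

(association table abridged). Reading the output: the cohort was generated
with a true mean growth rate of 7%/yr — the mixed model recovers a fixed
slope of 0.0658 (6.8%/yr) and per-individual rates from −0.7 to +21%/yr;
the generator's planted HDL-C link (Spearman −0.68 between true growth and
latent HDL-C) is recovered as −0.65 from the *estimated* rates, the only
primary covariate surviving Bonferroni correction, and persists (−0.53) in
the sensitivity analysis that keeps the three shrinking-dominant
individuals.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/chtrace.R simulate --config cfg.yaml --out sim/
Rscript inst/cli/chtrace.R longitudinal \
    --observations sim/observations.tsv --clinical sim/clinical.tsv --out out/
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from freshly generated cohorts at the given seed, the two
simulation-calibrated quantities the package is benchmarked on: the mean
per-individual growth rate recovered by the mixed model from 20 replicate
35-individual cohorts generated at a true mean of 7%/yr (`t8`), and the
median Spearman correlation between estimated growth rates and averaged
HDL-C across 20 cohorts generated at a target rank correlation of −0.68
(`t9`), writing both to the JSON file given by `--out`.

## Package layout

```
R/                  synthetic cohorts, detection, trajectories, growth model,
                    associations, cohort statistics, pipeline orchestration
inst/cli/chtrace.R  command-line front end (simulate / single-timepoint /
                    longitudinal)
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (model, assumptions, generator design)
```
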