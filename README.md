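# mrsummary

Two-sample Mendelian randomization (MR) from GWAS summary statistics, built
around a complete analysis of the causal effect of **age at menarche**
(exposure, years) on **time spent in education** (outcome, SD units; 1 SD =
3.6 years).

Observational links between pubertal timing and schooling are confounded by
obesity, family structure and socio-economic factors. MR uses genetic
variants as instrumental variables: for SNP *i* with per-allele effects
γ̂ᵢ on the exposure and Γ̂ᵢ on the outcome, estimated in two
non-overlapping GWAS samples, each valid instrument gives a Wald ratio
estimate of the causal effect β,

    β̂ᵢ = Γ̂ᵢ / γ̂ᵢ,   se(β̂ᵢ) by the Delta method,

and the panel is pooled by fixed-effect inverse-variance weighting (IVW),
with Cochran's Q / I²_MR as heterogeneity (pleiotropy-proxy) diagnostics.
Around that main analysis the package implements the standard sensitivity
battery: MR-Egger regression with the I²_GX dilution diagnostic, the
weighted median estimator with a parametric bootstrap, an exclusion-list
IVW rerun (e.g. instruments shared with BMI), unweighted allele-score
association tests, and the male negative control (men do not undergo
menarche, so the allele score must find nothing in men). It also ships
summary-statistics ingestion with strict validation, allele harmonization
with an auditable per-SNP report, instrument-strength (F statistic)
reporting, a calibrated synthetic two-sample GWAS generator with
configurable pleiotropy, and plot-data builders (scatter with fitted lines,
funnel with a symmetry diagnostic, forest).

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
dataset with the study's geometry (122 candidate SNPs, exposure GWAS of
182,416 women, outcome GWAS of 118,443 women, true causal effect 0.045
SD/year, balanced pleiotropy):

```sh
Rscript analysis/01_simulate.R      # generate the two-sample dataset
Rscript analysis/02_harmonize.R     # align alleles, instrument strength
Rscript analysis/03_main_analysis.R # Wald ratios + fixed-effect IVW
Rscript analysis/04_sensitivity.R   # Egger, weighted median, exclusions, allele scores
Rscript analysis/05_plot_data.R     # scatter/funnel/forest tables
```

Output of the main steps (all tables land under `results/`):

```
harmonized 80 instruments (oriented to the menarche-delaying allele)
F statistics: min 30, median 153, max 1180; 0 below the threshold of 10

IVW (fixed-effect): beta = 0.053 (95% CI 0.035 to 0.072), se = 0.0095, p = 2.15e-08, n = 80
  Q = 115.70 on 79 df; I2 = 31.7% (95% CI 9.8% to 48.3%) [heterogeneity present]
a 1-year later menarche -> 0.19 years (70 days) more education (95% CI 0.12 to 0.26 years)

MR-Egger: slope = 0.002 (95% CI -0.059 to 0.062, p = 0.956)
  intercept = 0.0032 (95% CI -0.0002 to 0.0067, p = 0.0648)
  I2_GX = 96.8%; n = 80
Weighted median: beta = 0.038 (95% CI 0.008 to 0.067, p = 0.0119; normal CI, 10000 bootstraps)
IVW (fixed-effect, BMI-like SNPs excluded): beta = 0.061 (95% CI 0.040 to 0.081), ..., n = 68
Allele score (women): beta = 0.003324, se = 0.0005372, p = 6.13e-10, n = 80
Allele score (men): beta = -0.000718, se = 0.0005372, p = 0.181, n = 80
Negative control (alpha = 0.05): PASS
```

Reading: the IVW estimate (0.053 SD/year here; the generator's true value
is 0.045) says each year of later menarche adds ~0.05 SD of education,
i.e. ~0.19 years ≈ 70 days. The I²_MR of 32% flags between-instrument
heterogeneity, so the sensitivity estimators matter: the weighted median
agrees, the Egger intercept finds no significant directional pleiotropy
(as it should — the simulated pleiotropy is balanced), and the negative
control passes because the male outcome carries no signal. Single-dataset
estimates scatter around the truth by their standard errors, so another
seed gives different (equally honest) numbers.

The same pipeline runs on real GWAS files in one call:

```r
library(mrsummary)
report <- run_full_analysis(mr_config(
  exposure = "exposure.tsv", outcome = "outcome.tsv",
  outcome_male = "outcome_men.tsv", exclusion_list = "bmi_snps.txt",
  n_boot = 10000, seed = 1, out_dir = "results/run1"))
print(report)
```

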