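#!/usr/bin/env Rscript
# Step 4: sensitivity analyses - MR-Egger with I2_GX, weighted median with
# parametric bootstrap, the exclusion-list IVW rerun, and the unweighted
# allele scores in women and men (male negative control).

library(mrsummary)

seed <- 20170809 %% 2147483647L
instruments <- read.delim("results/instruments.tsv")
class(instruments) <- c("mr_instruments", "data.frame")

egger <- egger_fit(instruments)
print(egger)

med <- weighted_median(instruments, n_boot = 10000, seed = seed)
print(med)

exclusion <- readLines("results/data/exclusion_bmi_like.txt")
kept <- exclude_snps(instruments, exclusion, reason = "bmi_overlap")
ivw_excl <- ivw_fixed(wald_ratio(kept),
                      method = "IVW (fixed-effect, BMI-like SNPs excluded)")
print(ivw_excl)

men_raw <- read_summary_table("results/data/outcome_men.tsv")
exposure <- read_summary_table("results/data/exposure.tsv")
men <- harmonize(exposure, men_raw, exposure_name = "age_at_menarche",
                 outcome_name = "time_in_education", population = "men")
common <- intersect(instruments$snp_id, men$snp_id)
nc <- negative_control(instruments[match(common, instruments$snp_id), ],
                       men[match(common, men$snp_id), c("snp_id", "by", "sy")])
print(nc)

summary_tab <- data.frame(
  method = c("mr_egger_slope", "mr_egger_intercept", "weighted_median",
             "ivw_excluded", "allele_score_women", "allele_score_men"),
  beta = c(egger$slope, egger$intercept, med$beta, ivw_excl$beta,
           nc$women$beta, nc$men$beta),
  se = c(egger$slope_se, egger$intercept_se, med$se, ivw_excl$se,
         nc$women$se, nc$men$se),
  pvalue = c(egger$slope_p, egger$intercept_p, med$pvalue, ivw_excl$pvalue,
             nc$women$pvalue, nc$men$pvalue),
  n_snps = c(egger$n_snps, egger$n_snps, med$n_snps, ivw_excl$n_snps,
             nc$women$n_snps, nc$men$n_snps)
)
write.table(summary_tab, "results/sensitivity_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("I2_GX = %.0f%%; negative control: %s\n", egger$i2_gx,
            if (nc$pass) "pass" else "fail"))
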