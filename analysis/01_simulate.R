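#!/usr/bin/env Rscript
# Step 1: generate the study-geometry dataset.
#
# Two-sample GWAS summary statistics emulating the menarche-education
# design: 122 candidate SNPs from a 182,416-woman exposure GWAS with
# genome-wide selection (p < 5e-8), a 118,443-woman outcome GWAS, a true
# causal effect of 0.045 SD/year and balanced pleiotropy calibrated to the
# study's heterogeneity. Also writes a null male outcome table (men lack
# the exposure) and a 12-SNP exclusion list standing in for instruments
# shared with BMI.

library(mrsummary)

seed <- 20170809 %% 2147483647L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- sim_truth_paper(seed = seed)
d <- simulate_gwas(truth)
paths <- write_simdata(d, out)

male <- d$outcome
set.seed(seed + 1L)
male$beta <- rnorm(nrow(male), 0, male$se)
male$pvalue <- pmax(2 * pnorm(-abs(male$beta / male$se)), .Machine$double.xmin)
write.table(male, file.path(out, "outcome_men.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

writeLines(head(d$exposure$snp_id, 12), file.path(out, "exclusion_bmi_like.txt"))

cat(sprintf("simulated %d candidate SNPs; %d passed genome-wide selection\n",
            truth$n_snps, nrow(d$exposure)))
cat(sprintf("true causal effect: %.3f SD/year; pleiotropy: %s (sd %.4f)\n",
            truth$beta_true, truth$pleiotropy_model, truth$pleiotropy_sd))
cat("wrote:", paste(basename(c(paths, file.path(out, "outcome_men.tsv"),
                               file.path(out, "exclusion_bmi_like.txt"))),
                    collapse = ", "), "\n")
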