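#!/usr/bin/env Rscript
# Step 2: read the summary tables, harmonize alleles, report instrument
# strength.

library(mrsummary)

exposure <- read_summary_table("results/data/exposure.tsv")
outcome <- read_summary_table("results/data/outcome.tsv")

instruments <- harmonize(exposure, outcome,
                         exposure_name = "age_at_menarche",
                         outcome_name = "time_in_education",
                         population = "women")
write_instruments(instruments, "results/instruments.tsv")
write.table(harmonization_report(instruments),
            "results/harmonization_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

weak <- flag_weak_instruments(instruments)
cat(sprintf("harmonized %d instruments (oriented to the menarche-delaying allele)\n",
            nrow(instruments)))
cat(sprintf("F statistics: min %.0f, median %.0f, max %.0f; %d below the threshold of 10\n",
            min(instruments$f_stat), median(instruments$f_stat),
            max(instruments$f_stat), nrow(weak)))
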