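test_that("swapped effect alleles flip the outcome beta", {
  exposure <- toy_assoc(snp_id = "rs1", effect_allele = "A", other_allele = "G",
                        eaf = 0.2, beta = 0.05, se = 0.01, pvalue = 1e-9)
  outcome <- toy_assoc(snp_id = "rs1", effect_allele = "G", other_allele = "A",
                       eaf = 0.8, beta = 0.02, se = 0.005, pvalue = 1e-4)
  h <- harmonize(exposure, outcome)
  expect_equal(h$bx, 0.05)
  expect_equal(h$by, -0.02)  # sign flip from the allele swap; bx already >= 0
  expect_equal(harmonization_report(h)$action, "flipped")
})

test_that("joint re-orientation to bx >= 0 preserves the ratio", {
  exposure <- toy_assoc(snp_id = "rs1", effect_allele = "A", other_allele = "G",
                        eaf = 0.2, beta = -0.05, se = 0.01, pvalue = 1e-9)
  outcome <- toy_assoc(snp_id = "rs1", effect_allele = "A", other_allele = "G",
                       eaf = 0.2, beta = -0.02, se = 0.005, pvalue = 1e-4)
  h <- harmonize(exposure, outcome)
  expect_equal(h$bx, 0.05)
  expect_equal(h$by, 0.02)
  expect_equal(h$by / h$bx, -0.02 / -0.05)
  expect_equal(h$maf, 0.2)  # eaf mirrored to 0.8, maf unchanged
})

test_that("strand complements are reconciled and mismatches excluded", {
  exposure <- toy_assoc(snp_id = c("rs1", "rs2"),
                        effect_allele = c("A", "A"), other_allele = c("G", "G"),
                        eaf = c(0.2, 0.3), beta = c(0.05, 0.04),
                        se = c(0.01, 0.01), pvalue = c(1e-9, 1e-9))
  outcome <- toy_assoc(snp_id = c("rs1", "rs2"),
                       effect_allele = c("T", "A"), other_allele = c("C", "C"),
                       eaf = c(0.2, 0.3), beta = c(0.02, 0.01),
                       se = c(0.005, 0.005), pvalue = c(1e-4, 1e-4))
  h <- harmonize(exposure, outcome)
  # rs1: T/C is the strand complement of A/G -> kept, no flip
  # rs2: A/C cannot be reconciled with A/G -> excluded
  expect_equal(h$snp_id, "rs1")
  expect_equal(h$by, 0.02)
  rep <- harmonization_report(h)
  expect_equal(rep$reason[rep$snp_id == "rs2"], "allele_mismatch")
})

test_that("palindromic SNPs follow the chosen policy", {
  exposure <- toy_assoc(snp_id = "rs1", effect_allele = "A", other_allele = "T",
                        eaf = 0.1, beta = 0.05, se = 0.01, pvalue = 1e-9)
  make_out <- function(eaf) {
    toy_assoc(snp_id = "rs1", effect_allele = "A", other_allele = "T",
              eaf = eaf, beta = 0.02, se = 0.005, pvalue = 1e-4)
  }
  expect_error(harmonize(exposure, make_out(0.1), palindromic_policy = "drop"),
               "no SNP could be harmonized")
  # freq policy: agreeing minor-allele side -> kept as-is
  h <- harmonize(exposure, make_out(0.1), palindromic_policy = "freq")
  expect_equal(h$by, 0.02)
  # disagreeing side -> the sources sit on opposite strands: extra sign flip
  h2 <- harmonize(exposure, make_out(0.9), palindromic_policy = "freq")
  expect_equal(h2$by, -0.02)
  expect_equal(harmonization_report(h2)$action, "strand_flipped")
  # ambiguity window or missing eaf -> dropped with reason
  expect_error(harmonize(exposure, make_out(0.5), palindromic_policy = "freq"))
  out_na <- make_out(0.1); out_na$eaf <- NA_real_
  expect_error(harmonize(exposure, out_na, palindromic_policy = "freq"),
               "no SNP")
  # keep policy trusts the reported strand
  h3 <- harmonize(exposure, make_out(0.9), palindromic_policy = "keep")
  expect_equal(h3$by, 0.02)
})

test_that("SNPs absent from either source land in the report, empty overlap errors", {
  exposure <- toy_assoc()
  outcome <- toy_assoc(snp_id = c("rs1", "rs2", "rs9"))
  h <- harmonize(exposure, outcome)
  rep <- harmonization_report(h)
  expect_equal(rep$reason[rep$snp_id == "rs3"], "absent_from_outcome")
  expect_equal(rep$reason[rep$snp_id == "rs9"], "absent_from_exposure")
  expect_setequal(h$snp_id, c("rs1", "rs2"))
  outcome2 <- toy_assoc(snp_id = c("rs7", "rs8", "rs9"))
  expect_error(harmonize(exposure, outcome2), "share no snp_id")
})

test_that("harmonization is idempotent on an already-aligned pair", {
  simdata <- simulate_gwas(sim_truth(n_snps = 40, beta_true = 0.05,
                                     gamma_sd = 0.05, seed = 11))
  h1 <- harmonize(simdata$exposure, simdata$outcome)
  # rebuild association tables from the harmonized set and harmonize again
  rebuild <- function(beta, se) {
    data.frame(snp_id = h1$snp_id, effect_allele = "A", other_allele = "G",
               eaf = h1$maf, beta = beta, se = se, pvalue = 0.5,
               stringsAsFactors = FALSE)
  }
  h2 <- harmonize(rebuild(h1$bx, h1$sx), rebuild(h1$by, h1$sy))
  expect_equal(h2$bx, h1$bx)
  expect_equal(h2$by, h1$by)
  expect_equal(h2$f_stat, h1$f_stat)
})

test_that("per-SNP ratios are invariant to allele scrambling (round-trip oracle)", {
  simdata <- simulate_gwas(sim_truth(n_snps = 60, beta_true = 0.045,
                                     pleiotropy_model = "balanced",
                                     pleiotropy_sd = 0.004, seed = 7))
  clean <- harmonize(simdata$exposure, simdata$outcome)
  ratio_clean <- clean$by / clean$bx
  names(ratio_clean) <- clean$snp_id
  for (s in c(1, 2, 3)) {
    scr <- scramble_alleles(simdata, seed = s)
    h <- harmonize(scr$exposure, scr$outcome)
    expect_identical(h$snp_id, clean$snp_id)
    expect_identical(h$by / h$bx, unname(ratio_clean[h$snp_id]))
  }
  # zero-probability scrambling is the identity
  same <- scramble_alleles(simdata, seed = 1, swap_prob = 0, complement_prob = 0)
  expect_identical(same$outcome, simdata$outcome)
})

test_that("exclude_snps removes listed instruments and keeps the rest intact", {
  ins <- toy_instruments(bx = c(0.05, 0.06, 0.07, 0.08), sx = 0.01,
                         by = c(0.002, 0.003, 0.004, 0.001), sy = 0.005)
  expect_equal(nrow(exclude_snps(ins, character(0))), 4L)
  kept <- exclude_snps(ins, c("rs2", "rs4"), reason = "bmi")
  expect_equal(kept$snp_id, c("rs1", "rs3"))
  er <- attr(kept, "exclusion_report")
  expect_equal(er$n_removed, 2L)
  expect_equal(er$n_retained, 2L)
  expect_equal(er$reason, "bmi")
  expect_error(exclude_snps(ins, ins$snp_id), "every instrument")
})
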