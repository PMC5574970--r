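# Fixture builders shared across test files. All fixtures are constructed in
# code; nothing is read from disk unless a test writes it first.

# A minimal valid association table.
toy_assoc <- function(snp_id = c("rs1", "rs2", "rs3"),
                      effect_allele = c("A", "T", "C"),
                      other_allele = c("G", "C", "A"),
                      eaf = c(0.2, 0.3, 0.4),
                      beta = c(0.05, -0.03, 0.02),
                      se = c(0.01, 0.012, 0.011),
                      pvalue = c(1e-8, 1e-6, 1e-5)) {
  data.frame(snp_id = snp_id, effect_allele = effect_allele,
             other_allele = other_allele, eaf = eaf, beta = beta, se = se,
             pvalue = pvalue, stringsAsFactors = FALSE)
}

# An already-harmonized instrument set built directly (bypasses harmonize()).
toy_instruments <- function(bx, sx, by, sy, maf = 0.3,
                            snp_id = sprintf("rs%d", seq_along(bx))) {
  out <- data.frame(snp_id = snp_id, bx = bx, sx = sx, by = by, sy = sy,
                    maf = maf, f_stat = (bx / sx)^2, stringsAsFactors = FALSE)
  class(out) <- c("mr_instruments", "data.frame")
  out
}

# Strong-instrument two-sample draws with known truth, built without the
# package generator so generator and estimators can be cross-checked
# independently. Returns an instrument set plus the truth used.
draw_instruments <- function(n, beta_true, gamma_range = c(0.02, 0.08),
                             sx = 5e-4, sy = 0.0045,
                             alpha = rep(0, n)) {
  gamma <- runif(n, gamma_range[1], gamma_range[2])
  bx <- rnorm(n, gamma, sx)
  by <- rnorm(n, beta_true * gamma + alpha, sy)
  toy_instruments(bx = bx, sx = rep(sx, n), by = by, sy = rep(sy, n))
}

write_assoc_file <- function(assoc, sep = "\t", ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(assoc, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
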