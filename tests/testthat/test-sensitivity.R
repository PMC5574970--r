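test_that("MR-Egger recovers an exact linear relationship to machine precision", {
  bx <- c(0.02, 0.04, 0.05, 0.07, 0.09)
  ins <- toy_instruments(bx = bx, sx = 0.005, by = -0.003 + 0.12 * bx,
                         sy = c(0.004, 0.005, 0.003, 0.006, 0.004))
  fit <- egger_fit(ins)
  expect_equal(fit$slope, 0.12, tolerance = 1e-12)
  expect_equal(fit$intercept, -0.003, tolerance = 1e-12)
})

test_that("MR-Egger enforces the bx >= 0 orientation", {
  set.seed(5)
  ins <- draw_instruments(30, beta_true = 0.05, alpha = rnorm(30, 0, 0.003))
  flipped <- ins
  i <- 1:10
  flipped$bx[i] <- -flipped$bx[i]
  flipped$by[i] <- -flipped$by[i]
  a <- egger_fit(ins); b <- egger_fit(flipped)
  expect_equal(b$slope, a$slope)
  expect_equal(b$intercept, a$intercept)
  expect_equal(b$slope_se, a$slope_se)
})

test_that("MR-Egger guards its preconditions and floors the residual scale", {
  ins <- toy_instruments(bx = c(0.05, 0.06), sx = 0.01,
                         by = c(0.002, 0.003), sy = 0.005)
  expect_error(egger_fit(ins), "at least 3")
  allsame <- toy_instruments(bx = rep(0.05, 4), sx = 0.01,
                             by = c(0.001, 0.002, 0.003, 0.004), sy = 0.005)
  expect_error(egger_fit(allsame), "unidentifiable")
  set.seed(6)
  fit <- egger_fit(draw_instruments(40, beta_true = 0.05))
  expect_gte(fit$residual_scale, 1)
})

test_that("MR-Egger corrects directional pleiotropy where IVW cannot", {
  # simulation oracle under InSIDE: pleiotropy with nonzero mean independent
  # of instrument strength biases IVW but not the Egger slope
  set.seed(140)
  beta_true <- 0.05
  est <- replicate(1000, {
    ins <- draw_instruments(40, beta_true = beta_true,
                            alpha = rnorm(40, 0.004, 0.002))
    c(egger = egger_fit(ins)$slope,
      ivw = ivw_fixed(wald_ratio(ins))$beta)
  })
  egger_bias <- abs(mean(est["egger", ]) - beta_true)
  ivw_bias <- abs(mean(est["ivw", ]) - beta_true)
  expect_lt(egger_bias / beta_true, 0.05)
  expect_gt(ivw_bias, 5 * egger_bias)
})

test_that("the Egger intercept test keeps its nominal type-I error under balanced pleiotropy", {
  set.seed(141)
  rejections <- replicate(2000, {
    ins <- draw_instruments(40, beta_true = 0.05,
                            alpha = rnorm(40, 0, 0.003))
    egger_fit(ins)$intercept_p < 0.05
  })
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})

test_that("I2_GX measures exposure-estimate heterogeneity", {
  allsame <- toy_instruments(bx = rep(0.05, 5), sx = 0.01,
                             by = rnorm(5, 0, 0.001), sy = 0.005)
  expect_equal(i2_gx(allsame), 0)
  expect_error(i2_gx(allsame[1, ]), "at least 2")

  # shared-oracle consistency: I2_GX equals the meta-analytic I2 of the bx
  set.seed(17)
  ins <- draw_instruments(50, beta_true = 0.05)
  fake_ratios <- data.frame(snp_id = ins$snp_id, beta_iv = ins$bx,
                            se_iv = ins$sx, weight = 1 / ins$sx^2)
  pooled <- ivw_fixed(fake_ratios)
  expect_equal(i2_gx(ins), pooled$i2, tolerance = 1e-10)

  # dilution vanishes as the exposure GWAS grows: I2_GX -> 100%
  big <- simulate_gwas(sim_truth(n_snps = 50, beta_true = 0.04,
                                 n_exposure = 5e7, seed = 3))
  h <- harmonize(big$exposure, big$outcome)
  expect_gt(i2_gx(h), 99)
})

test_that("the weighted median interpolates the 50th weighted percentile", {
  ins3 <- toy_instruments(bx = 1, sx = 1e-8, by = c(0.1, 0.2, 0.9), sy = 1)
  suppressWarnings(fit <- weighted_median(ins3, n_boot = 50, seed = 1))
  expect_equal(fit$beta, 0.2)

  # all estimates equal -> that value, whatever the weights
  same <- toy_instruments(bx = 1, sx = 1e-8, by = rep(0.3, 4),
                          sy = c(1, 2, 0.5, 3))
  suppressWarnings(fit2 <- weighted_median(same, n_boot = 50, seed = 1))
  expect_equal(fit2$beta, 0.3)

  # equal weights reduce to the ordinary interpolated median
  set.seed(33)
  for (i in 1:25) {
    x <- rnorm(sample(3:15, 1))
    expect_equal(mrsummary:::weighted_percentile(x, rep(1, length(x))),
                 median(x))
  }
})

test_that("weighted median stays within the per-SNP estimates and records its bootstrap", {
  set.seed(60)
  ins <- draw_instruments(30, beta_true = 0.05)
  fit <- weighted_median(ins, n_boot = 2000, seed = 4)
  r <- wald_ratio(ins)
  expect_gte(fit$beta, min(r$beta_iv))
  expect_lte(fit$beta, max(r$beta_iv))
  expect_gt(fit$se, 0)
  expect_equal(fit$seed, 4)
  # identical seed -> identical bootstrap SE; no RNG state leaks out
  before <- .Random.seed
  fit2 <- weighted_median(ins, n_boot = 2000, seed = 4)
  expect_identical(.Random.seed, before)
  expect_equal(fit2$se, fit$se)
  expect_warning(weighted_median(ins, n_boot = 500, seed = 1), "n_boot")
  expect_error(weighted_median(ins[1:2, ], n_boot = 2000, seed = 1),
               "at least 3")
})

test_that("the weighted median tolerates a pleiotropic minority", {
  # breakdown property: with 40% of weight on invalid instruments the
  # median recovers the truth; point estimates only (the bootstrap SE is
  # exercised elsewhere)
  set.seed(61)
  beta_true <- 0.05
  est <- replicate(1000, {
    n <- 30
    invalid <- rep(c(TRUE, FALSE), c(12, 18))  # 40% of equal-strength SNPs
    ins <- draw_instruments(n, beta_true = beta_true,
                            gamma_range = c(0.05, 0.05001),
                            sx = 1e-5, sy = 5e-5,
                            alpha = ifelse(invalid, 0.006, 0))
    r <- wald_ratio(ins)
    mrsummary:::weighted_percentile(r$beta_iv, r$weight)
  })
  expect_lt(abs(mean(est) - beta_true) / beta_true, 0.05)
})

test_that("the unweighted allele score pools outcome effects only", {
  null_by <- toy_instruments(bx = c(0.05, 0.06, 0.07), sx = 0.01,
                             by = rep(0, 3), sy = 0.005)
  res <- allele_score_test(null_by, population = "women")
  expect_equal(res$beta, 0)
  expect_equal(res$pvalue, 1)
  expect_error(allele_score_test(null_by[0, ]), "at least one")

  # equivalence: with bx = 1 and sx = 0 the IVW of the ratios is the score
  set.seed(21)
  ins <- toy_instruments(bx = 1, sx = 0, by = rnorm(20, 0.002, 0.001),
                         sy = runif(20, 0.003, 0.008))
  score <- allele_score_test(ins)
  ivw <- ivw_fixed(wald_ratio(ins, "first"))
  expect_equal(score$beta, ivw$beta, tolerance = 1e-12)
  expect_equal(score$se, ivw$se, tolerance = 1e-12)
  expect_equal(score$pvalue, ivw$pvalue, tolerance = 1e-12)
})

test_that("the male negative control passes on true mediation and fails on identical data", {
  set.seed(30)
  women <- draw_instruments(60, beta_true = 0.06, sy = 0.003)
  # exact null in men: no per-allele outcome effect at all
  men <- data.frame(snp_id = women$snp_id,
                    by = rep(0, 60), sy = 0.003,
                    stringsAsFactors = FALSE)
  nc <- negative_control(women, men)
  expect_true(nc$pass)
  expect_lt(nc$women$pvalue, 0.05)
  expect_gte(nc$men$pvalue, 0.05)

  # control of the control: identical populations cannot pass
  same <- negative_control(women, women[, c("snp_id", "by", "sy")])
  expect_false(same$pass)

  men_bad <- men; men_bad$snp_id[1] <- "rs_unknown"
  expect_error(negative_control(women, men_bad), "mismatch.*rs_unknown|rs1")
})
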