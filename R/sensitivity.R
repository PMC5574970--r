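# Sensitivity analyses: MR-Egger with I2_GX, weighted median with a
# parametric bootstrap, allele-score tests and the male negative control.

#' MR-Egger regression
#'
#' Weighted linear regression of the SNP-outcome effects on the SNP-exposure
#' effects with a free intercept, weights `1/sy^2`. The slope estimates the
#' causal effect under the InSIDE assumption (pleiotropic effects independent
#' of instrument strength); the intercept estimates the average directional
#' pleiotropy per allele, so an intercept indistinguishable from zero is
#' evidence against directional pleiotropy.
#'
#' The fit is orientation-dependent, so instruments are re-oriented to
#' `bx >= 0` (flipping `by` jointly) before fitting. Standard errors use a
#' multiplicative residual scale floored at 1 - overdispersion inflates them
#' but underdispersion earns no credit - with t-based CIs and p-values on
#' `n - 2` degrees of freedom. The `I2_GX` dilution diagnostic is attached.
#'
#' @param instruments instrument set from [harmonize()]; at least 3 SNPs.
#' @return object of class `mr_egger`: `slope`, `slope_se`, `slope_ci_low`,
#'   `slope_ci_high`, `slope_p`, the same for `intercept`, plus `i2_gx`,
#'   `residual_scale` and `n_snps`.
#' @export
egger_fit <- function(instruments) {
  n <- nrow(instruments)
  if (n < 3L) stop("MR-Egger needs at least 3 instruments", call. = FALSE)
  neg <- instruments$bx < 0
  bx <- ifelse(neg, -instruments$bx, instruments$bx)
  by <- ifelse(neg, -instruments$by, instruments$by)
  if (length(unique(bx)) == 1L) {
    stop("MR-Egger slope unidentifiable: all bx equal", call. = FALSE)
  }
  w <- 1 / instruments$sy^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  scale_used <- max(1, sm$sigma)
  co <- sm$coefficients
  # rescale to a residual SD floored at 1; an exact fit (sigma = 0) keeps
  # its zero standard errors
  se <- co[, "Std. Error"] * (if (sm$sigma > 0) scale_used / sm$sigma else 1)
  est <- co[, "Estimate"]
  tq <- stats::qt(0.975, df = n - 2L)
  pvals <- 2 * stats::pt(-abs(est / se), df = n - 2L)
  structure(list(
    slope = unname(est["bx"]), slope_se = unname(se["bx"]),
    slope_ci_low = unname(est["bx"] - tq * se["bx"]),
    slope_ci_high = unname(est["bx"] + tq * se["bx"]),
    slope_p = unname(pvals["bx"]),
    intercept = unname(est["(Intercept)"]), intercept_se = unname(se["(Intercept)"]),
    intercept_ci_low = unname(est["(Intercept)"] - tq * se["(Intercept)"]),
    intercept_ci_high = unname(est["(Intercept)"] + tq * se["(Intercept)"]),
    intercept_p = unname(pvals["(Intercept)"]),
    i2_gx = i2_gx(instruments),
    residual_scale = scale_used,
    n_snps = n
  ), class = "mr_egger")
}

#' I2_GX: heterogeneity of the SNP-exposure estimates
#'
#' Quantifies regression-dilution bias in MR-Egger from measurement error in
#' the exposure associations. Computes Cochran's Q of the `bx` values about
#' their inverse-variance weighted mean (weights `1/sx^2`) and returns
#' `max(0, 100 * (Q_GX - (n-1)) / Q_GX)`. Values near 100% indicate that
#' dilution is negligible.
#'
#' @param instruments instrument set; at least 2 SNPs with `sx > 0`.
#' @return percentage in [0, 100].
#' @export
i2_gx <- function(instruments) {
  n <- nrow(instruments)
  if (n < 2L) stop("I2_GX needs at least 2 instruments", call. = FALSE)
  if (any(instruments$sx <= 0)) stop("all sx must be > 0", call. = FALSE)
  w <- 1 / instruments$sx^2
  bxw <- sum(w * instruments$bx) / sum(w)
  q_gx <- sum(w * (instruments$bx - bxw)^2)
  if (q_gx == 0) return(0)
  max(0, 100 * (q_gx - (n - 1)) / q_gx)
}

# Weighted percentile of Bowden et al.'s form: each order statistic sits at
# its centred cumulative weight (S_j - w_j/2)/S_n; linear interpolation at
# `prob`. With equal weights this is the ordinary interpolated median.
weighted_percentile <- function(x, w, prob = 0.5) {
  ord <- order(x, method = "radix")  # stable: ties keep snp_id order
  x <- x[ord]; w <- w[ord]
  w <- w / sum(w)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, x, xout = prob, rule = 2, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' Orders the per-SNP Wald ratio estimates and takes the 50th weighted
#' percentile with weights proportional to `1/se_iv^2` (linear interpolation
#' between the bracketing order statistics at cumulative weight 0.5). The
#' estimator is consistent when at least half of the total weight comes from
#' valid instruments, so it tolerates pleiotropy that would bias IVW.
#'
#' The standard error comes from a parametric bootstrap: each replicate draws
#' `bx* ~ N(bx, sx)` and `by* ~ N(by, sy)` per SNP independently (two-sample
#' design), recomputes the ratio estimates and their weights, and re-takes
#' the weighted median. The default CI is the normal approximation
#' `estimate +/- 1.96 * SE`; percentile bootstrap bounds are also returned.
#'
#' @param instruments instrument set from [harmonize()]; at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 10000; below 1000 a warning is
#'   raised and the run proceeds).
#' @param seed integer seed for the bootstrap, recorded on the result.
#' @param se_order Delta-method order used for the weights.
#' @param ci_type `"normal"` (default) or `"percentile"` for the reported CI.
#' @return object of class `mr_median`: `beta`, `se`, `ci_low`, `ci_high`,
#'   `pvalue`, `ci_type`, `percentile_ci`, `n_boot`, `seed`, `n_snps`.
#' @export
weighted_median <- function(instruments, n_boot = 10000, seed,
                            se_order = c("second", "first"),
                            ci_type = c("normal", "percentile")) {
  se_order <- match.arg(se_order)
  ci_type <- match.arg(ci_type)
  n <- nrow(instruments)
  if (n < 3L) stop("weighted median needs at least 3 instruments", call. = FALSE)
  if (n_boot < 1000) {
    warning("n_boot < 1000: bootstrap SE will be noisy", call. = FALSE)
  }
  ratios <- wald_ratio(instruments, se_order = se_order)
  beta <- weighted_percentile(ratios$beta_iv, ratios$weight)

  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bxs <- stats::rnorm(n, instruments$bx, instruments$sx)
      bys <- stats::rnorm(n, instruments$by, instruments$sy)
      bxs[bxs == 0] <- .Machine$double.eps  # ratio defined a.s.
      biv <- bys / bxs
      siv <- switch(se_order,
        first = instruments$sy / abs(bxs),
        second = sqrt(instruments$sy^2 / bxs^2 +
                        bys^2 * instruments$sx^2 / bxs^4)
      )
      weighted_percentile(biv, 1 / siv^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  perc <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  ci <- if (ci_type == "normal") c(beta - Z95 * se, beta + Z95 * se) else perc
  structure(list(
    beta = beta, se = se, ci_low = ci[1], ci_high = ci[2],
    pvalue = z_pvalue(beta, se), ci_type = ci_type,
    percentile_ci = perc, n_boot = n_boot, seed = seed, n_snps = n
  ), class = "mr_median")
}

#' Unweighted allele-score association test
#'
#' Fixed-effect IVW pooling of the SNP-outcome effects themselves (weights
#' `1/sy^2`), on instruments oriented to the exposure-increasing allele.
#' Because the SNP-exposure effect sizes enter only through the orientation,
#' the test is immune to winner's-curse inflation of discovery-stage exposure
#' estimates. It is a test of association only - the pooled value is a
#' per-allele outcome effect, never a causal magnitude.
#'
#' @param outcome_assocs data.frame with oriented outcome effects: columns
#'   `snp_id`, `by`, `sy` (an instrument set from [harmonize()] works).
#' @param population label, e.g. `"women"` or `"men"`.
#' @return object of class `mr_allele_score`: `population`, `beta`, `se`,
#'   `pvalue`, `n_snps`.
#' @export
allele_score_test <- function(outcome_assocs, population = "unspecified") {
  n <- nrow(outcome_assocs)
  if (is.null(n) || n < 1L) stop("need at least one association", call. = FALSE)
  if (any(outcome_assocs$sy <= 0)) stop("all sy must be > 0", call. = FALSE)
  w <- 1 / outcome_assocs$sy^2
  beta <- sum(w * outcome_assocs$by) / sum(w)
  se <- 1 / sqrt(sum(w))
  structure(list(population = population, beta = beta, se = se,
                 pvalue = z_pvalue(beta, se), n_snps = n),
            class = "mr_allele_score")
}

#' Male negative-control comparison
#'
#' Men do not undergo menarche, so the allele score built from menarche
#' instruments should show no association with the outcome in men if the
#' association in women is mediated by age at menarche. Runs
#' [allele_score_test()] on both populations over the same instruments and
#' flags `pass` when the women's score is significant at `alpha` and the
#' men's is not.
#'
#' @param women_set instrument set (women) from [harmonize()].
#' @param men_outcome oriented outcome associations for men over the same
#'   SNPs (columns `snp_id`, `by`, `sy`).
#' @param alpha significance level for both decisions.
#' @return object of class `mr_negative_control`: `women`, `men` (both
#'   `mr_allele_score`), `alpha`, `pass`.
#' @export
negative_control <- function(women_set, men_outcome, alpha = 0.05) {
  mism <- c(setdiff(women_set$snp_id, men_outcome$snp_id),
            setdiff(men_outcome$snp_id, women_set$snp_id))
  if (length(mism) > 0L) {
    stop("snp_id mismatch between populations: ",
         paste(utils::head(mism, 10L), collapse = ", "), call. = FALSE)
  }
  women <- allele_score_test(women_set, population = "women")
  men <- allele_score_test(men_outcome[match(women_set$snp_id, men_outcome$snp_id), ],
                           population = "men")
  structure(list(women = women, men = men, alpha = alpha,
                 pass = women$pvalue < alpha && men$pvalue >= alpha),
            class = "mr_negative_control")
}

#' @export
print.mr_egger <- function(x, digits = 3, ...) {
  cat(sprintf("MR-Egger: slope = %.*f (95%% CI %.*f to %.*f, p = %.3g)\n",
              digits, x$slope, digits, x$slope_ci_low, digits, x$slope_ci_high,
              x$slope_p))
  cat(sprintf("  intercept = %.4f (95%% CI %.4f to %.4f, p = %.3g)\n",
              x$intercept, x$intercept_ci_low, x$intercept_ci_high, x$intercept_p))
  cat(sprintf("  I2_GX = %.1f%%; n = %d\n", x$i2_gx, x$n_snps))
  invisible(x)
}

#' @export
print.mr_median <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Weighted median: beta = %.*f (95%% CI %.*f to %.*f, p = %.3g; %s CI, %d bootstraps)\n",
    digits, x$beta, digits, x$ci_low, digits, x$ci_high, x$pvalue,
    x$ci_type, x$n_boot))
  invisible(x)
}

#' @export
print.mr_allele_score <- function(x, digits = 4, ...) {
  cat(sprintf("Allele score (%s): beta = %.*g, se = %.*g, p = %.3g, n = %d\n",
              x$population, digits, x$beta, digits, x$se, x$pvalue, x$n_snps))
  invisible(x)
}

#' @export
print.mr_negative_control <- function(x, ...) {
  print(x$women); print(x$men)
  cat(sprintf("Negative control (alpha = %.2f): %s\n", x$alpha,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
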