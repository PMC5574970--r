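# Per-SNP Wald ratio estimation and fixed-effect IVW pooling.

#' Per-SNP Wald ratio estimates
#'
#' For each instrument the causal effect of the exposure on the outcome is
#' estimated as the ratio of the two genetic associations,
#' `beta_iv = by / bx` (here: SD units of time in education per year of age
#' at menarche). The standard error comes from the Delta method:
#' \describe{
#'   \item{first}{`se_iv = sy / |bx|` - ignores uncertainty in `bx`.}
#'   \item{second}{`se_iv = sqrt(sy^2/bx^2 + by^2 * sx^2 / bx^4)` - includes
#'     the exposure term (default). The exposure-outcome covariance is taken
#'     as zero, as appropriate for non-overlapping two-sample designs.}
#' }
#'
#' @param instruments instrument set from [harmonize()] (or any data.frame
#'   with columns `snp_id`, `bx`, `sx`, `by`, `sy`).
#' @param se_order `"second"` (default) or `"first"`.
#' @return data.frame with columns `snp_id`, `beta_iv`, `se_iv`, `weight`
#'   (`= 1/se_iv^2`).
#' @export
wald_ratio <- function(instruments, se_order = c("second", "first")) {
  se_order <- match.arg(se_order)
  if (any(instruments$bx == 0)) {
    stop("Wald ratio undefined for bx = 0 (snp: ",
         paste(instruments$snp_id[instruments$bx == 0], collapse = ", "), ")",
         call. = FALSE)
  }
  bx <- instruments$bx; sx <- instruments$sx
  by <- instruments$by; sy <- instruments$sy
  beta_iv <- by / bx
  se_iv <- switch(se_order,
    first = sy / abs(bx),
    second = sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  )
  data.frame(snp_id = instruments$snp_id,
             beta_iv = beta_iv,
             se_iv = se_iv,
             weight = 1 / se_iv^2,
             stringsAsFactors = FALSE)
}

new_pooled <- function(method, beta, se, n_snps, het = NULL) {
  out <- list(method = method, beta = beta, se = se,
              ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
              pvalue = z_pvalue(beta, se), n_snps = n_snps)
  if (!is.null(het)) out <- c(out, het)
  structure(out, class = "mr_pooled")
}

#' Fixed-effect inverse-variance weighted pooling
#'
#' Pools per-SNP Wald ratio estimates with weights `1/se_iv^2`:
#' `beta = sum(w_i * beta_i) / sum(w_i)`, `se = 1/sqrt(sum(w_i))`, with a
#' 95% normal confidence interval and two-sided normal p-value. With two or
#' more estimates, Cochran's Q and the between-instrument I-squared (with its
#' test-based 95% CI) are attached as heterogeneity diagnostics; with a
#' single estimate they are absent rather than fabricated.
#'
#' @param ratios data.frame from [wald_ratio()].
#' @param method label stored on the result.
#' @return an object of class `mr_pooled`: `beta`, `se`, `ci_low`, `ci_high`,
#'   `pvalue`, `n_snps`, and (when defined) `q_stat`, `df`, `i2`,
#'   `i2_ci_low`, `i2_ci_high`, `heterogeneity_flag`.
#' @export
ivw_fixed <- function(ratios, method = "IVW (fixed-effect)") {
  n <- nrow(ratios)
  if (is.null(n) || n < 1L) stop("need at least one ratio estimate", call. = FALSE)
  w <- 1 / ratios$se_iv^2
  beta <- sum(w * ratios$beta_iv) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- NULL
  if (n >= 2L) {
    q <- cochran_q(ratios, beta)
    i2 <- i2_from_q(q$q_stat, q$df)
    het <- list(q_stat = q$q_stat, df = q$df,
                i2 = i2$i2, i2_ci_low = i2$ci_low, i2_ci_high = i2$ci_high,
                heterogeneity_flag = i2$i2 > 25)
  }
  new_pooled(method, beta, se, n, het)
}

#' Cochran's Q for a set of ratio estimates
#'
#' `Q = sum(w_i * (beta_i - pooled)^2)` with `w_i = 1/se_iv^2` and
#' `df = n - 1`. Under homogeneity Q is approximately chi-squared on `df`
#' degrees of freedom; excess Q signals between-instrument heterogeneity,
#' a proxy for pleiotropy in MR.
#'
#' @param ratios data.frame from [wald_ratio()].
#' @param pooled_beta the pooled estimate the deviations are measured from.
#' @return list with `q_stat` and `df`.
#' @export
cochran_q <- function(ratios, pooled_beta) {
  n <- nrow(ratios)
  if (n < 2L) stop("Cochran's Q needs at least 2 estimates", call. = FALSE)
  stopifnot_scalar_number(pooled_beta, "pooled_beta")
  w <- 1 / ratios$se_iv^2
  list(q_stat = sum(w * (ratios$beta_iv - pooled_beta)^2), df = n - 1L)
}

#' I-squared from Cochran's Q
#'
#' Point estimate `I2 = max(0, 100 * (Q - df) / Q)` (0 when Q = 0), the
#' percentage of variation across instruments attributable to heterogeneity
#' rather than chance. The 95% CI uses the test-based method of Higgins &
#' Thompson on the log of `H = sqrt(Q/df)`, transformed back through
#' `I2 = 100 * (H^2 - 1) / H^2` and truncated to [0, 100].
#'
#' @param q_stat Cochran's Q, >= 0.
#' @param df degrees of freedom (number of estimates minus 1), >= 1.
#' @return list with `i2`, `ci_low`, `ci_high` (percentages).
#' @export
i2_from_q <- function(q_stat, df) {
  stopifnot_scalar_number(q_stat, "q_stat")
  stopifnot_scalar_number(df, "df")
  if (q_stat < 0) stop("`q_stat` must be >= 0", call. = FALSE)
  if (df < 1) stop("`df` must be >= 1", call. = FALSE)
  i2 <- if (q_stat == 0) 0 else max(0, 100 * (q_stat - df) / q_stat)
  # test-based CI on ln H (Higgins & Thompson 2002)
  h <- sqrt(max(q_stat, df) / df)  # H floored at 1 for the point transform
  se_lnh <- if (q_stat > df) {
    0.5 * (log(q_stat) - log(df)) / (sqrt(2 * q_stat) - sqrt(2 * df - 1))
  } else if (df > 1) {
    sqrt(1 / (2 * (df - 1)) * (1 - 1 / (3 * (df - 1)^2)))
  } else {
    NA_real_
  }
  if (is.na(se_lnh)) {
    ci <- c(NA_real_, NA_real_)
  } else {
    h_lo <- max(1, exp(log(h) - Z95 * se_lnh))
    h_hi <- max(1, exp(log(h) + Z95 * se_lnh))
    ci <- 100 * c((h_lo^2 - 1) / h_lo^2, (h_hi^2 - 1) / h_hi^2)
  }
  list(i2 = min(100, max(0, i2)),
       ci_low = ci[1], ci_high = ci[2])
}

#' Convert an SD-scale effect on time in education to years and days
#'
#' Multiplies an effect expressed in standard deviation units of time spent
#' in education by the trait's standard deviation (3.6 years by default) and
#' converts to days (365.25 days/year); the integer day count is for display
#' alongside the exact value in years.
#'
#' @param beta_sd effect in SD units (vectorised; CI bounds welcome).
#' @param sd_years standard deviation of time in education, in years.
#' @return data.frame with columns `beta_sd`, `years`, `days` (exact) and
#'   `days_rounded`.
#' @export
#' @examples
#' units_to_days(c(0.04, 0.03, 0.06))
units_to_days <- function(beta_sd, sd_years = 3.6) {
  stopifnot_scalar_number(sd_years, "sd_years", positive = TRUE)
  years <- beta_sd * sd_years
  days <- years * 365.25
  data.frame(beta_sd = beta_sd, years = years, days = days,
             days_rounded = round(days))
}

#' @export
print.mr_pooled <- function(x, digits = 3, ...) {
  cat(sprintf("%s: beta = %.*f (95%% CI %.*f to %.*f), se = %.*g, p = %.3g, n = %d\n",
              x$method, digits, x$beta, digits, x$ci_low, digits, x$ci_high,
              digits, x$se, x$pvalue, x$n_snps))
  if (!is.null(x$i2)) {
    cat(sprintf("  Q = %.2f on %d df; I2 = %.1f%% (95%% CI %.1f%% to %.1f%%)%s\n",
                x$q_stat, x$df, x$i2, x$i2_ci_low, x$i2_ci_high,
                if (isTRUE(x$heterogeneity_flag)) " [heterogeneity present]" else ""))
  }
  invisible(x)
}
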