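# Plot-ready tables: scatter with fitted lines, funnel, forest.

#' Build plot-ready tables for MR diagnostics
#'
#' Produces three delimited-text-ready tables from a fitted analysis:
#' \describe{
#'   \item{scatter}{per-SNP `(bx, by)` with standard errors, plus a `lines`
#'     table holding the three fitted lines - IVW through the origin,
#'     MR-Egger with its intercept, and the weighted median through the
#'     origin. Line slopes equal the corresponding pooled estimates exactly.}
#'   \item{funnel}{per-SNP Wald estimate against its precision `1/se_iv`,
#'     with vertical reference lines at the IVW and MR-Egger estimates, an
#'     optional minor-allele-frequency-corrected instrument strength
#'     `bx * sqrt(2 * maf * (1-maf))` (per-allele effect rescaled to the
#'     per-SD-of-genotype scale), and a precision-weighted symmetry score.}
#'   \item{forest}{per-SNP estimates with 95% CIs followed by the pooled
#'     rows.}
#' }
#' The funnel symmetry score is the precision-weighted mean sign of
#' `beta_i - beta_IVW`, in [-1, 1] (0 for a symmetric funnel); the attached
#' `asymmetry_p` is the MR-Egger intercept p-value, the numeric counterpart
#' of judging funnel asymmetry by eye.
#'
#' @param instruments instrument set from [harmonize()].
#' @param ratios data.frame from [wald_ratio()].
#' @param pooled named list with elements `ivw` (`mr_pooled`), `egger`
#'   (`mr_egger`) and `median` (`mr_median`).
#' @return object of class `mr_plot_data`: `scatter`, `lines`, `funnel`,
#'   `forest` data.frames plus `funnel_symmetry` (score and p).
#' @export
build_plot_data <- function(instruments, ratios, pooled) {
  stopifnot(all(c("ivw", "egger", "median") %in% names(pooled)))
  scatter <- data.frame(snp_id = instruments$snp_id,
                        bx = instruments$bx, sx = instruments$sx,
                        by = instruments$by, sy = instruments$sy,
                        stringsAsFactors = FALSE)
  lines <- data.frame(
    method = c("ivw", "mr_egger", "weighted_median"),
    slope = c(pooled$ivw$beta, pooled$egger$slope, pooled$median$beta),
    intercept = c(0, pooled$egger$intercept, 0),
    stringsAsFactors = FALSE
  )
  maf_ok <- !is.na(instruments$maf)
  funnel <- data.frame(
    snp_id = ratios$snp_id,
    beta_iv = ratios$beta_iv,
    precision = 1 / ratios$se_iv,
    gx_maf_corrected = ifelse(maf_ok,
      instruments$bx * sqrt(2 * instruments$maf * (1 - instruments$maf)),
      NA_real_),
    stringsAsFactors = FALSE
  )
  ref_lines <- data.frame(method = c("ivw", "mr_egger"),
                          x = c(pooled$ivw$beta, pooled$egger$slope),
                          stringsAsFactors = FALSE)
  w <- 1 / ratios$se_iv
  score <- sum(w * sign(ratios$beta_iv - pooled$ivw$beta)) / sum(w)
  forest <- rbind(
    data.frame(label = ratios$snp_id, beta = ratios$beta_iv,
               ci_low = ratios$beta_iv - Z95 * ratios$se_iv,
               ci_high = ratios$beta_iv + Z95 * ratios$se_iv,
               pooled = FALSE, stringsAsFactors = FALSE),
    data.frame(label = c("IVW (fixed-effect)", "MR-Egger", "Weighted median"),
               beta = lines$slope,
               ci_low = c(pooled$ivw$ci_low, pooled$egger$slope_ci_low,
                          pooled$median$ci_low),
               ci_high = c(pooled$ivw$ci_high, pooled$egger$slope_ci_high,
                           pooled$median$ci_high),
               pooled = TRUE, stringsAsFactors = FALSE)
  )
  structure(list(scatter = scatter, lines = lines, funnel = funnel,
                 funnel_reference = ref_lines, forest = forest,
                 funnel_symmetry = list(score = score,
                                        asymmetry_p = pooled$egger$intercept_p)),
            class = "mr_plot_data")
}
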