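# Full-analysis orchestration: main IVW analysis plus all sensitivity
# analyses, plot data, and a run manifest.

#' Run configuration
#'
#' Validates and bundles everything [run_full_analysis()] needs. Exposure,
#' outcome and male-outcome inputs may be file paths (read with
#' [read_summary_table()]) or already-loaded association data.frames.
#'
#' @param exposure,outcome exposure and outcome summary statistics: path or
#'   data.frame.
#' @param outcome_male optional male outcome summary statistics for the
#'   negative control.
#' @param exclusion_list optional character vector of `snp_id`s (or path to
#'   a one-column text file) to exclude in the sensitivity rerun, e.g.
#'   instruments also associated with BMI.
#' @param palindromic_policy passed to [harmonize()].
#' @param se_order Delta-method order for [wald_ratio()].
#' @param n_boot bootstrap replicates for [weighted_median()].
#' @param seed integer seed; recorded in the manifest and used for every
#'   stochastic step.
#' @param sd_years standard deviation of time in education, years, for
#'   [units_to_days()].
#' @param out_dir optional directory; when given, every intermediate table
#'   and the manifest are written there.
#' @return object of class `mr_config`.
#' @export
mr_config <- function(exposure, outcome, outcome_male = NULL,
                      exclusion_list = NULL,
                      palindromic_policy = "freq",
                      se_order = "second",
                      n_boot = 10000, seed = 1L, sd_years = 3.6,
                      out_dir = NULL) {
  load_assoc <- function(x, what) {
    if (is.character(x) && length(x) == 1L) {
      if (!file.exists(x)) stop(what, " path not found: ", x, call. = FALSE)
      read_summary_table(x)
    } else if (is.data.frame(x)) {
      validate_associations(x, context = what)
    } else {
      stop(what, " must be a file path or a data.frame", call. = FALSE)
    }
  }
  exposure <- load_assoc(exposure, "exposure")
  outcome <- load_assoc(outcome, "outcome")
  if (!is.null(outcome_male)) outcome_male <- load_assoc(outcome_male, "outcome_male")
  if (is.character(exclusion_list) && length(exclusion_list) == 1L &&
      file.exists(exclusion_list)) {
    exclusion_list <- readLines(exclusion_list)
    exclusion_list <- trimws(exclusion_list[nzchar(trimws(exclusion_list))])
  }
  structure(list(exposure = exposure, outcome = outcome,
                 outcome_male = outcome_male, exclusion_list = exclusion_list,
                 palindromic_policy = palindromic_policy, se_order = se_order,
                 n_boot = n_boot, seed = as.integer(seed),
                 sd_years = sd_years, out_dir = out_dir),
            class = "mr_config")
}

#' Run the complete two-sample MR analysis
#'
#' Executes the full pipeline: read and harmonize, instrument strength,
#' per-SNP Wald ratios, fixed-effect IVW with heterogeneity (the main
#' analysis), MR-Egger with I2_GX, weighted median with parametric
#' bootstrap, the exclusion-list IVW rerun, unweighted allele-score tests
#' (women, and men when a male outcome table is given) with the
#' negative-control comparison, conversion of the main estimate to
#' years/days, and plot-ready tables. When `config$out_dir` is set, every
#' intermediate table, a combined summary table and a key-value run
#' manifest are written there.
#'
#' @param config an `mr_config`.
#' @return object of class `mr_report`: `instruments`, `weak_instruments`,
#'   `ratios`, `ivw`, `egger`, `median`, `ivw_excluded` (or NULL),
#'   `allele_score_women`, `negative_control` (or NULL), `effect_days`,
#'   `plot_data`, `summary` (one row per analysis), `config`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  instruments <- harmonize(config$exposure, config$outcome,
                           palindromic_policy = config$palindromic_policy,
                           exposure_name = "age_at_menarche",
                           outcome_name = "time_in_education",
                           population = "women")
  weak <- flag_weak_instruments(instruments)
  ratios <- wald_ratio(instruments, se_order = config$se_order)
  ivw <- ivw_fixed(ratios)
  egger <- egger_fit(instruments)
  med <- weighted_median(instruments, n_boot = config$n_boot,
                         seed = config$seed, se_order = config$se_order)

  ivw_excl <- NULL
  if (!is.null(config$exclusion_list) && length(config$exclusion_list) > 0L) {
    kept <- exclude_snps(instruments, config$exclusion_list,
                         reason = "exclusion_list")
    ivw_excl <- ivw_fixed(wald_ratio(kept, se_order = config$se_order),
                          method = "IVW (fixed-effect, exclusion rerun)")
  }

  score_women <- allele_score_test(instruments, population = "women")
  negctl <- NULL
  if (!is.null(config$outcome_male)) {
    male <- harmonize(config$exposure, config$outcome_male,
                      palindromic_policy = config$palindromic_policy,
                      exposure_name = "age_at_menarche",
                      outcome_name = "time_in_education",
                      population = "men")
    common <- intersect(instruments$snp_id, male$snp_id)
    negctl <- negative_control(
      instruments[match(common, instruments$snp_id), ],
      male[match(common, male$snp_id), c("snp_id", "by", "sy")]
    )
  }

  effect_days <- units_to_days(c(ivw$beta, ivw$ci_low, ivw$ci_high),
                               sd_years = config$sd_years)
  rownames(effect_days) <- c("estimate", "ci_low", "ci_high")

  plot_data <- build_plot_data(instruments, ratios,
                               list(ivw = ivw, egger = egger, median = med))

  pooled_row <- function(x, method) {
    data.frame(method = method, beta = x$beta, se = x$se,
               ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
               n_snps = x$n_snps,
               q_stat = if (is.null(x$q_stat)) NA_real_ else x$q_stat,
               i2 = if (is.null(x$i2)) NA_real_ else x$i2,
               i2_ci_low = if (is.null(x$i2_ci_low)) NA_real_ else x$i2_ci_low,
               i2_ci_high = if (is.null(x$i2_ci_high)) NA_real_ else x$i2_ci_high,
               stringsAsFactors = FALSE)
  }
  summary_tab <- rbind(
    pooled_row(ivw, "ivw_fixed"),
    data.frame(method = "mr_egger_slope", beta = egger$slope,
               se = egger$slope_se, ci_low = egger$slope_ci_low,
               ci_high = egger$slope_ci_high, pvalue = egger$slope_p,
               n_snps = egger$n_snps, q_stat = NA_real_, i2 = egger$i2_gx,
               i2_ci_low = NA_real_, i2_ci_high = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(method = "mr_egger_intercept", beta = egger$intercept,
               se = egger$intercept_se, ci_low = egger$intercept_ci_low,
               ci_high = egger$intercept_ci_high, pvalue = egger$intercept_p,
               n_snps = egger$n_snps, q_stat = NA_real_, i2 = NA_real_,
               i2_ci_low = NA_real_, i2_ci_high = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(method = "weighted_median", beta = med$beta, se = med$se,
               ci_low = med$ci_low, ci_high = med$ci_high, pvalue = med$pvalue,
               n_snps = med$n_snps, q_stat = NA_real_, i2 = NA_real_,
               i2_ci_low = NA_real_, i2_ci_high = NA_real_,
               stringsAsFactors = FALSE),
    if (!is.null(ivw_excl)) pooled_row(ivw_excl, "ivw_fixed_excluded"),
    data.frame(method = "allele_score_women", beta = score_women$beta,
               se = score_women$se, ci_low = NA_real_, ci_high = NA_real_,
               pvalue = score_women$pvalue, n_snps = score_women$n_snps,
               q_stat = NA_real_, i2 = NA_real_, i2_ci_low = NA_real_,
               i2_ci_high = NA_real_, stringsAsFactors = FALSE),
    if (!is.null(negctl)) data.frame(
      method = "allele_score_men", beta = negctl$men$beta,
      se = negctl$men$se, ci_low = NA_real_, ci_high = NA_real_,
      pvalue = negctl$men$pvalue, n_snps = negctl$men$n_snps,
      q_stat = NA_real_, i2 = NA_real_, i2_ci_low = NA_real_,
      i2_ci_high = NA_real_, stringsAsFactors = FALSE)
  )

  report <- structure(list(
    instruments = instruments, weak_instruments = weak, ratios = ratios,
    ivw = ivw, egger = egger, median = med, ivw_excluded = ivw_excl,
    allele_score_women = score_women, negative_control = negctl,
    effect_days = effect_days, plot_data = plot_data,
    summary = summary_tab, config = config
  ), class = "mr_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Writes every intermediate table plus a key-value manifest.
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(as.data.frame(report$instruments), "instruments.tsv")
  wt(harmonization_report(report$instruments), "harmonization_report.tsv")
  wt(report$weak_instruments, "weak_instruments.tsv")
  wt(report$ratios, "wald_ratios.tsv")
  wt(report$summary, "pooled_results.tsv")
  wt(report$plot_data$scatter, "plot_scatter.tsv")
  wt(report$plot_data$lines, "plot_lines.tsv")
  wt(report$plot_data$funnel, "plot_funnel.tsv")
  wt(report$plot_data$forest, "plot_forest.tsv")
  ed <- report$effect_days
  ed$quantity <- rownames(ed)
  wt(ed[, c("quantity", "beta_sd", "years", "days", "days_rounded")],
     "effect_in_days.tsv")
  cfg <- report$config
  manifest <- c(
    sprintf("package_version: %s", as.character(utils::packageVersion("mrsummary"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("seed: %d", cfg$seed),
    sprintf("se_order: %s", cfg$se_order),
    sprintf("palindromic_policy: %s", cfg$palindromic_policy),
    sprintf("n_boot: %d", cfg$n_boot),
    sprintf("sd_years: %g", cfg$sd_years),
    sprintf("n_exposure_rows: %d", nrow(cfg$exposure)),
    sprintf("n_outcome_rows: %d", nrow(cfg$outcome)),
    sprintf("n_instruments: %d", nrow(report$instruments)),
    sprintf("n_weak_instruments: %d", nrow(report$weak_instruments)),
    sprintf("negative_control: %s",
            if (is.null(report$negative_control)) "not_run"
            else if (report$negative_control$pass) "pass" else "fail")
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("Two-sample MR report: %d instruments (%d flagged weak)\n",
              nrow(x$instruments), nrow(x$weak_instruments)))
  print(x$ivw)
  print(x$egger)
  print(x$median)
  if (!is.null(x$ivw_excluded)) print(x$ivw_excluded)
  print(x$allele_score_women)
  if (!is.null(x$negative_control)) print(x$negative_control)
  cat(sprintf("Main estimate: %.2f years (%d days; 95%% CI %.2f to %.2f years)\n",
              x$effect_days["estimate", "years"],
              x$effect_days["estimate", "days_rounded"],
              x$effect_days["ci_low", "years"],
              x$effect_days["ci_high", "years"]))
  invisible(x)
}
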