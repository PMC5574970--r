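# Synthetic two-sample GWAS summary statistics with known causal truth.
#
# The generator mirrors the geometry of a two-sample MR study of age at
# menarche (exposure, years) and time spent in education (outcome, SD
# units): two non-overlapping GWAS samples, per-allele effects with standard
# errors implied by sample size and allele frequency on a unit-variance
# trait scale, and per-SNP pleiotropic effects alpha_i under configurable
# models. The latent per-SNP values are kept alongside the observable tables
# so estimator bias and coverage can be measured against the truth.

#' Simulation truth parameters
#'
#' Bundles and validates the generating parameters of a synthetic
#' two-sample GWAS summary dataset.
#'
#' Pleiotropy models for the direct (non-mediated) outcome effect alpha_i:
#' \describe{
#'   \item{none}{alpha_i = 0: all instruments valid.}
#'   \item{balanced}{alpha_i ~ N(0, pleiotropy_sd): heterogeneity without
#'     directional bias (InSIDE holds).}
#'   \item{directional}{alpha_i ~ N(pleiotropy_mean, pleiotropy_sd) with
#'     nonzero mean, independent of instrument strength (InSIDE holds, IVW
#'     biased, MR-Egger unbiased).}
#'   \item{inside_violating}{alpha_i correlated with the instrument strength
#'     gamma_i (correlation 0.7), breaking the InSIDE assumption.}
#' }
#'
#' @param n_snps number of candidate instruments (>= 3).
#' @param beta_true causal effect, SD units of outcome per year of exposure.
#' @param pleiotropy_model one of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`.
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of alpha_i, in per-allele
#'   SD units of the outcome.
#' @param maf_range interval for the uniform minor-allele frequency draw,
#'   within (0, 0.5].
#' @param gamma_sd spread of the true per-allele exposure effects (years).
#' @param n_exposure,n_outcome GWAS sample sizes of the two non-overlapping
#'   samples.
#' @param selection_p optional genome-wide significance threshold applied to
#'   the *observed* exposure association, reproducing winner's curse in the
#'   selected instruments; `NULL` disables selection.
#' @param seed integer seed; the dataset is a pure function of the truth.
#' @return object of class `mr_sim_truth` (a validated list).
#' @export
sim_truth <- function(n_snps = 122,
                      beta_true = 0.045,
                      pleiotropy_model = c("none", "balanced", "directional",
                                           "inside_violating"),
                      pleiotropy_mean = 0,
                      pleiotropy_sd = 0,
                      maf_range = c(0.05, 0.5),
                      gamma_sd = 0.04,
                      n_exposure = 182416,
                      n_outcome = 118443,
                      selection_p = NULL,
                      seed = 1L) {
  pleiotropy_model <- match.arg(pleiotropy_model)
  if (n_snps < 3) stop("`n_snps` must be >= 3", call. = FALSE)
  if (n_exposure <= 0 || n_outcome <= 0) {
    stop("sample sizes must be > 0", call. = FALSE)
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must lie within (0, 0.5]", call. = FALSE)
  }
  stopifnot_scalar_number(gamma_sd, "gamma_sd", positive = TRUE)
  if (!is.null(selection_p)) {
    stopifnot_scalar_number(selection_p, "selection_p", positive = TRUE)
  }
  structure(list(
    n_snps = as.integer(n_snps), beta_true = beta_true,
    pleiotropy_model = pleiotropy_model,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    maf_range = maf_range, gamma_sd = gamma_sd,
    n_exposure = n_exposure, n_outcome = n_outcome,
    selection_p = selection_p, seed = as.integer(seed)
  ), class = "mr_sim_truth")
}

#' Paper-like simulation preset
#'
#' Truth parameters calibrated to reproduce the data geometry of the
#' menarche-education study: 122 instruments from a 182,416-woman exposure
#' GWAS and a 118,443-woman outcome GWAS, a causal effect of 0.045 SD/year,
#' and balanced pleiotropy tuned so that the instrument F statistics
#' typically span the strong-instrument range (roughly 25 to a few hundred)
#' and the between-instrument I2 of the Wald ratios lands near 48%.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_truth()].
#' @return object of class `mr_sim_truth`.
#' @export
sim_truth_paper <- function(seed = 1L, ...) {
  args <- list(
    n_snps = 122L, beta_true = 0.045,
    pleiotropy_model = "balanced",
    pleiotropy_mean = 0, pleiotropy_sd = 0.0042,
    maf_range = c(0.08, 0.5), gamma_sd = 0.045,
    n_exposure = 182416, n_outcome = 118443,
    selection_p = 5e-8, seed = seed
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_truth, args)
}

# Non-palindromic allele pairs: harmonization is exercised separately by
# scramble_alleles(); palindromes are injected there when wanted.
ALLELE_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Simulate a two-sample GWAS summary dataset
#'
#' For each SNP i: `maf_i ~ U(maf_range)`; true exposure effect
#' `gamma_i = |N(0, gamma_sd)|` (oriented to the exposure-increasing
#' allele); pleiotropic effect `alpha_i` per the truth's pleiotropy model;
#' true outcome effect `Gamma_i = beta_true * gamma_i + alpha_i`. Standard
#' errors follow the unit-variance-trait approximation
#' `s = 1 / sqrt(2 * n * maf * (1 - maf))`, and the observed estimates are
#' independent draws `bx_i ~ N(gamma_i, sx_i)`, `by_i ~ N(Gamma_i, sy_i)`
#' (two non-overlapping samples). When `selection_p` is set, only SNPs whose
#' observed exposure p-value clears it are retained - the selected `bx` are
#' reported as observed, reproducing winner's curse.
#'
#' @param truth an `mr_sim_truth` from [sim_truth()].
#' @return object of class `mr_simdata`: `exposure` and `outcome`
#'   association tables in the canonical summary-statistics layout, `truth`,
#'   and `latent` (per-SNP `gamma`, `alpha`, `Gamma`, `maf`, `sx`, `sy`,
#'   `selected`) for oracle checks. The latent values are never written by
#'   [write_simdata()].
#' @export
simulate_gwas <- function(truth) {
  stopifnot(inherits(truth, "mr_sim_truth"))
  n <- truth$n_snps
  dat <- with_seed(truth$seed, {
    maf <- stats::runif(n, truth$maf_range[1], truth$maf_range[2])
    gamma <- abs(stats::rnorm(n, 0, truth$gamma_sd))
    alpha <- switch(truth$pleiotropy_model,
      none = rep(0, n),
      balanced = stats::rnorm(n, 0, truth$pleiotropy_sd),
      directional = stats::rnorm(n, truth$pleiotropy_mean, truth$pleiotropy_sd),
      inside_violating = {
        rho <- 0.7
        truth$pleiotropy_mean + truth$pleiotropy_sd *
          (rho * (gamma - mean(gamma)) / stats::sd(gamma) +
             sqrt(1 - rho^2) * stats::rnorm(n))
      })
    Gamma <- truth$beta_true * gamma + alpha
    sx <- 1 / sqrt(2 * truth$n_exposure * maf * (1 - maf))
    sy <- 1 / sqrt(2 * truth$n_outcome * maf * (1 - maf))
    bx <- stats::rnorm(n, gamma, sx)
    by <- stats::rnorm(n, Gamma, sy)
    pair <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), n, replace = TRUE), ,
                         drop = FALSE]
    # the effect allele is the exposure-increasing one; it is the minor
    # allele for a random half of SNPs
    eaf <- ifelse(stats::runif(n) < 0.5, maf, 1 - maf)
    list(maf = maf, gamma = gamma, alpha = alpha, Gamma = Gamma,
         sx = sx, sy = sy, bx = bx, by = by, pair = pair, eaf = eaf)
  })
  # floor at the smallest positive double: p-values of very strong
  # associations underflow to 0, which the (0, 1] invariant forbids
  px <- pmax(2 * stats::pnorm(-abs(dat$bx / dat$sx)), .Machine$double.xmin)
  py <- pmax(2 * stats::pnorm(-abs(dat$by / dat$sy)), .Machine$double.xmin)
  selected <- if (is.null(truth$selection_p)) rep(TRUE, n) else px < truth$selection_p
  if (sum(selected) < 3L) {
    stop("fewer than 3 SNPs passed instrument selection; ",
         "increase gamma_sd or n_snps", call. = FALSE)
  }
  snp_id <- sprintf("rs%07d", seq_len(n))
  make_tab <- function(beta, se, pval) {
    data.frame(snp_id = snp_id,
               effect_allele = dat$pair[, 1], other_allele = dat$pair[, 2],
               eaf = dat$eaf, beta = beta, se = se, pvalue = pval,
               stringsAsFactors = FALSE)[selected, ]
  }
  exposure <- make_tab(dat$bx, dat$sx, px)
  outcome <- make_tab(dat$by, dat$sy, py)
  rownames(exposure) <- rownames(outcome) <- NULL
  latent <- data.frame(snp_id = snp_id, gamma = dat$gamma, alpha = dat$alpha,
                       Gamma = dat$Gamma, maf = dat$maf,
                       sx = dat$sx, sy = dat$sy, selected = selected,
                       stringsAsFactors = FALSE)
  structure(list(exposure = exposure, outcome = outcome,
                 truth = truth, latent = latent),
            class = "mr_simdata")
}

#' Scramble allele encodings of the outcome table
#'
#' Randomly swaps effect/other alleles (negating the beta and mirroring the
#' frequency) and strand-complements a random subset of SNPs in the outcome
#' table only, leaving the encoded associations - and the truth - unchanged.
#' Harmonizing the scrambled dataset must recover the original per-SNP
#' ratios exactly, which makes this the round-trip test harness for
#' [harmonize()].
#'
#' @param simdata an `mr_simdata` from [simulate_gwas()].
#' @param seed integer seed for the scrambling.
#' @param swap_prob,complement_prob per-SNP probabilities of an allele swap
#'   and of a strand complement.
#' @return the dataset with a scrambled outcome table.
#' @export
scramble_alleles <- function(simdata, seed, swap_prob = 0.5,
                             complement_prob = 0.5) {
  stopifnot(inherits(simdata, "mr_simdata"))
  ou <- simdata$outcome
  n <- nrow(ou)
  with_seed(seed, {
    swap <- stats::runif(n) < swap_prob
    comp <- stats::runif(n) < complement_prob
    ea <- ou$effect_allele; oa <- ou$other_allele
    ou$effect_allele[swap] <- oa[swap]
    ou$other_allele[swap] <- ea[swap]
    ou$beta[swap] <- -ou$beta[swap]
    ou$eaf[swap] <- 1 - ou$eaf[swap]
    ou$effect_allele[comp] <- unname(COMPLEMENT[ou$effect_allele[comp]])
    ou$other_allele[comp] <- unname(COMPLEMENT[ou$other_allele[comp]])
  })
  simdata$outcome <- ou
  simdata
}

#' Write a synthetic dataset to disk
#'
#' Writes the exposure and outcome tables in the tab-delimited layout
#' [read_summary_table()] reads, plus a key-value truth manifest. Latent
#' per-SNP values are deliberately not written.
#'
#' @param simdata an `mr_simdata`.
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written, invisibly.
#' @export
write_simdata <- function(simdata, dir) {
  stopifnot(inherits(simdata, "mr_simdata"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             truth = file.path(dir, "truth.txt"))
  utils::write.table(simdata$exposure, paths[["exposure"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(simdata$outcome, paths[["outcome"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- simdata$truth
  kv <- vapply(names(tr), function(k) {
    v <- tr[[k]]
    sprintf("%s: %s", k, if (is.null(v)) "NULL" else paste(format(v, digits = 15), collapse = ","))
  }, character(1))
  writeLines(kv, paths[["truth"]])
  invisible(paths)
}
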