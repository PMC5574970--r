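# Allele harmonization of exposure and outcome summary statistics.
#
# Two GWAS sources may report the same SNP on different effect alleles or on
# opposite strands. Harmonization aligns the outcome estimate to the
# exposure's effect allele (sign-flipping where the alleles are swapped,
# complementing where the strand differs), then re-orients every instrument
# jointly so the exposure effect is non-negative - the exposure-increasing
# allele convention that MR-Egger requires.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  unname(COMPLEMENT[a1] == a2)
}

#' Harmonize exposure and outcome association tables
#'
#' Joins the two tables on `snp_id` and aligns each shared SNP's outcome
#' estimate onto the exposure's effect allele:
#' \itemize{
#'   \item same effect/other alleles: kept as is;
#'   \item swapped alleles (direct or after strand complement): outcome beta
#'     sign-flipped and its frequency mirrored;
#'   \item irreconcilable allele pairs: excluded with a reason code.
#' }
#' Palindromic SNPs (A/T or C/G), whose strand cannot be inferred from the
#' alleles, are handled per `palindromic_policy`:
#' \describe{
#'   \item{freq}{align using effect-allele frequencies; drop the SNP when
#'     either frequency lies in the ambiguity window (0.42, 0.58) or is
#'     missing (default).}
#'   \item{drop}{exclude all palindromic SNPs.}
#'   \item{keep}{assume both sources report the same strand.}
#' }
#' Finally both betas are re-oriented jointly so `bx >= 0` (per-SNP ratios
#' are invariant to this), the minor-allele frequency and F statistic are
#' attached, and every excluded SNP is listed in the harmonization report
#' (attribute `"report"`).
#'
#' @param exposure,outcome validated association tables
#'   (see [read_summary_table()]).
#' @param palindromic_policy `"freq"`, `"drop"` or `"keep"`.
#' @param exposure_name,outcome_name,population provenance labels stored as
#'   attributes on the result.
#' @return a `data.frame` of class `mr_instruments` with columns `snp_id`,
#'   `bx`, `sx`, `by`, `sy`, `maf`, `f_stat`; attributes `report` (per-SNP
#'   action/reason codes), `exposure`, `outcome`, `population`.
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_policy = c("freq", "drop", "keep"),
                      exposure_name = "exposure", outcome_name = "outcome",
                      population = "unspecified") {
  palindromic_policy <- match.arg(palindromic_policy)
  exposure <- validate_associations(exposure, context = "exposure")
  outcome <- validate_associations(outcome, context = "outcome")

  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0L) {
    stop("exposure and outcome tables share no snp_id", call. = FALSE)
  }
  report <- data.frame(
    snp_id = exposure$snp_id,
    action = NA_character_,
    reason = NA_character_,
    stringsAsFactors = FALSE
  )
  mark <- function(ids, action, reason) {
    idx <- match(ids, report$snp_id)
    report$action[idx] <<- action
    report$reason[idx] <<- reason
  }
  only_exposure <- setdiff(exposure$snp_id, shared)
  mark(only_exposure, "excluded", "absent_from_outcome")
  extra_outcome <- setdiff(outcome$snp_id, shared)
  if (length(extra_outcome) > 0L) {
    report <- rbind(report, data.frame(
      snp_id = extra_outcome, action = "excluded",
      reason = "absent_from_exposure", stringsAsFactors = FALSE
    ))
  }

  ex <- exposure[match(shared, exposure$snp_id), ]
  ou <- outcome[match(shared, outcome$snp_id), ]

  same <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  swap <- ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele
  oc_e <- unname(COMPLEMENT[ou$effect_allele])
  oc_o <- unname(COMPLEMENT[ou$other_allele])
  same_c <- oc_e == ex$effect_allele & oc_o == ex$other_allele
  swap_c <- oc_e == ex$other_allele & oc_o == ex$effect_allele
  palin <- is_palindromic(ex$effect_allele, ex$other_allele)

  keep <- logical(length(shared))
  flip <- logical(length(shared))
  action <- character(length(shared))
  reason <- rep(NA_character_, length(shared))

  for (i in seq_along(shared)) {
    if (palin[i]) {
      # for a palindromic SNP, same and swap_c (and swap and same_c) are
      # indistinguishable from the alleles alone
      if (palindromic_policy == "drop") {
        action[i] <- "excluded"; reason[i] <- "palindromic_dropped"
        next
      }
      if (!(same[i] || swap[i])) {
        action[i] <- "excluded"; reason[i] <- "allele_mismatch"
        next
      }
      if (palindromic_policy == "keep") {
        keep[i] <- TRUE
        flip[i] <- swap[i]
        action[i] <- if (swap[i]) "flipped" else "kept"
        next
      }
      # freq policy: orient by effect-allele frequency agreement
      fe <- ex$eaf[i]; fo <- ou$eaf[i]
      if (swap[i]) fo <- 1 - fo  # put both on the exposure's effect allele
      if (is.na(fe) || is.na(fo)) {
        action[i] <- "excluded"; reason[i] <- "palindromic_missing_eaf"
        next
      }
      in_window <- function(f) f > 0.42 & f < 0.58
      if (in_window(fe) || in_window(fo)) {
        action[i] <- "excluded"; reason[i] <- "palindromic_ambiguous_eaf"
        next
      }
      keep[i] <- TRUE
      if ((fe < 0.5) == (fo < 0.5)) {
        flip[i] <- swap[i]
        action[i] <- if (swap[i]) "flipped" else "kept"
      } else {
        # frequencies disagree: the sources report opposite strands with
        # swapped labels; net effect is one extra sign flip
        flip[i] <- !swap[i]
        action[i] <- "strand_flipped"
      }
    } else {
      if (same[i]) {
        keep[i] <- TRUE; action[i] <- "kept"
      } else if (swap[i]) {
        keep[i] <- TRUE; flip[i] <- TRUE; action[i] <- "flipped"
      } else if (same_c[i]) {
        keep[i] <- TRUE; action[i] <- "strand_complemented"
      } else if (swap_c[i]) {
        keep[i] <- TRUE; flip[i] <- TRUE; action[i] <- "strand_complemented_flipped"
      } else {
        action[i] <- "excluded"; reason[i] <- "allele_mismatch"
      }
    }
  }
  mark(shared, action, reason)

  if (!any(keep)) stop("no SNP could be harmonized", call. = FALSE)

  bx <- ex$beta[keep]
  by <- ifelse(flip[keep], -ou$beta[keep], ou$beta[keep])
  sx <- ex$se[keep]
  sy <- ou$se[keep]
  eaf <- ex$eaf[keep]

  # joint re-orientation to the exposure-increasing allele: flipping both
  # betas leaves every ratio by/bx unchanged
  neg <- bx < 0
  bx[neg] <- -bx[neg]
  by[neg] <- -by[neg]
  eaf[neg] <- 1 - eaf[neg]

  out <- data.frame(
    snp_id = shared[keep],
    bx = bx, sx = sx, by = by, sy = sy,
    maf = pmin(eaf, 1 - eaf),
    f_stat = f_statistic(bx, sx),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out,
            report = report,
            exposure = exposure_name,
            outcome = outcome_name,
            population = population,
            class = c("mr_instruments", "data.frame"))
}

#' Harmonization report
#'
#' @param instruments result of [harmonize()].
#' @return data.frame with one row per input SNP: `snp_id`, `action`
#'   (kept/flipped/strand_complemented/.../excluded) and `reason` for
#'   exclusions.
#' @export
harmonization_report <- function(instruments) {
  attr(instruments, "report")
}

#' Remove instruments by identifier
#'
#' Drops the listed SNPs from an instrument set, e.g. instruments also
#' associated with a potential pleiotropic pathway such as BMI, so that all
#' downstream estimators can be re-run unchanged on the reduced set.
#'
#' @param instruments instrument set from [harmonize()].
#' @param exclusion_list character vector of `snp_id`s to remove.
#' @param reason label recorded in the exclusion report.
#' @return the reduced instrument set; attribute `exclusion_report` holds
#'   counts of removed/retained SNPs and the reason label.
#' @export
exclude_snps <- function(instruments, exclusion_list, reason = "excluded") {
  removed <- instruments$snp_id %in% exclusion_list
  if (all(removed)) stop("exclusion removes every instrument", call. = FALSE)
  out <- instruments[!removed, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- attr(instruments, "report")
  attr(out, "exposure") <- attr(instruments, "exposure")
  attr(out, "outcome") <- attr(instruments, "outcome")
  attr(out, "population") <- attr(instruments, "population")
  attr(out, "exclusion_report") <- data.frame(
    reason = reason,
    n_listed = length(unique(exclusion_list)),
    n_removed = sum(removed),
    n_retained = sum(!removed),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mr_instruments", "data.frame")
  out
}
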