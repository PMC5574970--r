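# Reading and validating GWAS summary-statistic tables.
#
# A summary table holds one row per SNP with the per-allele association of
# that SNP with a single trait: identifier, effect/other allele, effect-allele
# frequency, beta, standard error and p-value. Exposure tables here carry
# effects on age at menarche in years per allele; outcome tables carry effects
# on time spent in education in SD units per allele.

VALID_ALLELES <- c("A", "C", "G", "T")

ASSOC_COLUMNS <- c("snp_id", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue")

#' Column-name presets for summary-statistic dialects
#'
#' Returns a named character vector mapping the canonical column names used
#' throughout this package (`snp_id`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pvalue`) to the header names found in the file. Two presets
#' ship with the package:
#' \describe{
#'   \item{generic}{the package's own canonical headers.}
#'   \item{gwas_catalog}{GWAS-Catalog-style headers (`variant_id`,
#'     `effect_allele_frequency`, `standard_error`, `p_value`, ...).}
#' }
#' Semantics are never sniffed from the data: an unknown dialect must be
#' described with an explicit `column_map`.
#'
#' @param name preset name, `"generic"` or `"gwas_catalog"`.
#' @return named character vector: canonical name -> file header.
#' @export
#' @examples
#' column_preset("gwas_catalog")
column_preset <- function(name = c("generic", "gwas_catalog")) {
  name <- match.arg(name)
  switch(name,
    generic = stats::setNames(ASSOC_COLUMNS, ASSOC_COLUMNS),
    gwas_catalog = c(
      snp_id = "variant_id",
      effect_allele = "effect_allele",
      other_allele = "other_allele",
      eaf = "effect_allele_frequency",
      beta = "beta",
      se = "standard_error",
      pvalue = "p_value"
    )
  )
}

# Delimiter detection: tab wins if the header contains any tab, else comma.
# This sniffs only the separator character, never column semantics.
detect_sep <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited (optionally gzip-compressed) table of
#' per-SNP association estimates and validates every row. Validation failures
#' are never silently dropped: the function stops with a message naming each
#' offending row and the rule it breaks.
#'
#' Validation rules: alleles must be single bases A/C/G/T and differ within a
#' row; `se` must be a positive number; `beta` must be numeric; `eaf`, when
#' present, must lie strictly between 0 and 1; `pvalue`, when present, must
#' lie in (0, 1]; `snp_id` must be unique.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical column names to
#'   the file's headers (see [column_preset()]), or a preset name.
#' @return a `data.frame` with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue` (missing optional columns
#'   filled with `NA`).
#' @export
read_summary_table <- function(path, column_map = "generic") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(column_map) && length(column_map) == 1L && is.null(names(column_map))) {
    column_map <- column_preset(column_map)
  }
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing_map <- setdiff(mandatory, names(column_map))
  if (length(missing_map) > 0L) {
    stop("column_map lacks mandatory entries: ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(unname(column_map[mandatory]), names(raw))
  if (length(missing_cols) > 0L) {
    stop("mandatory column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(snp_id = as.character(raw[[column_map[["snp_id"]]]]),
                    stringsAsFactors = FALSE)
  out$effect_allele <- toupper(as.character(raw[[column_map[["effect_allele"]]]]))
  out$other_allele <- toupper(as.character(raw[[column_map[["other_allele"]]]]))
  for (col in c("eaf", "beta", "se", "pvalue")) {
    out[[col]] <- if (col %in% names(column_map) && column_map[[col]] %in% names(raw)) {
      suppressWarnings(as.numeric(raw[[column_map[[col]]]]))
    } else {
      NA_real_
    }
  }
  validate_associations(out, context = path)
}

#' Validate a table of SNP associations
#'
#' Applies the row-level invariants of a summary-statistics table (see
#' [read_summary_table()]) and stops with a message listing every failing row.
#'
#' @param assoc data.frame with the canonical association columns.
#' @param context label used in error messages (e.g. the source file).
#' @return the validated data.frame, invisibly unchanged.
#' @export
validate_associations <- function(assoc, context = "summary table") {
  need <- setdiff(c("snp_id", "effect_allele", "other_allele", "beta", "se"),
                  names(assoc))
  if (length(need) > 0L) {
    stop(context, ": missing column(s) ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("eaf", "pvalue")) if (!col %in% names(assoc)) assoc[[col]] <- NA_real_
  problems <- character(0)
  flag <- function(bad, msg) {
    if (any(bad)) {
      ids <- assoc$snp_id[bad]
      problems <<- c(problems,
                     sprintf("%s: %s", msg, paste(utils::head(ids, 10L), collapse = ", ")))
    }
  }
  flag(!assoc$effect_allele %in% VALID_ALLELES, "effect_allele not one of A/C/G/T")
  flag(!assoc$other_allele %in% VALID_ALLELES, "other_allele not one of A/C/G/T")
  flag(assoc$effect_allele == assoc$other_allele, "effect and other allele identical")
  flag(!is.finite(assoc$beta), "beta missing or non-numeric")
  flag(!is.finite(assoc$se) | assoc$se <= 0, "se missing, non-numeric or not > 0")
  flag(!is.na(assoc$eaf) & (assoc$eaf <= 0 | assoc$eaf >= 1),
       "eaf outside (0, 1)")
  flag(!is.na(assoc$pvalue) & (assoc$pvalue <= 0 | assoc$pvalue > 1),
       "pvalue outside (0, 1]")
  dup <- duplicated(assoc$snp_id)
  if (any(dup)) {
    problems <- c(problems, sprintf("duplicate snp_id: %s",
                                    paste(unique(assoc$snp_id[dup]), collapse = ", ")))
  }
  if (length(problems) > 0L) {
    stop(context, ": row-level validation failed\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  assoc[, ASSOC_COLUMNS]
}

#' Instrument F statistic
#'
#' Strength of a genetic instrument for the exposure, computed as the square
#' of the Wald z statistic of the SNP-exposure association, `(bx / sx)^2`.
#' Values above 10 are conventionally taken to indicate a strong instrument.
#'
#' @param bx per-allele SNP-exposure effect.
#' @param sx its standard error, must be > 0 (vectorised).
#' @return F statistic(s), non-negative.
#' @export
#' @examples
#' f_statistic(0.10, 0.02)  # 25
f_statistic <- function(bx, sx) {
  if (any(!is.finite(sx)) || any(sx <= 0)) {
    stop("`sx` must be finite and > 0", call. = FALSE)
  }
  (bx / sx)^2
}

#' Flag weak instruments
#'
#' Lists instruments whose F statistic falls below a threshold (default 10,
#' the conventional weak-instrument cut-off). Instruments are reported, never
#' removed: downstream estimators keep the full set.
#'
#' @param instruments an instrument set from [harmonize()].
#' @param threshold F-statistic threshold.
#' @return data.frame of flagged instruments (`snp_id`, `f_stat`); zero rows
#'   when all instruments are strong.
#' @export
flag_weak_instruments <- function(instruments, threshold = 10) {
  if (nrow(instruments) == 0L) stop("instrument set is empty", call. = FALSE)
  weak <- instruments$f_stat < threshold
  out <- instruments[weak, c("snp_id", "f_stat"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a harmonized instrument table
#'
#' @param instruments instrument set from [harmonize()].
#' @param path output path; tab-delimited text.
#' @return `path`, invisibly.
#' @export
write_instruments <- function(instruments, path) {
  utils::write.table(as.data.frame(instruments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
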