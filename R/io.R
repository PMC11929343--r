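#' Default column mapping for GWAS summary-statistic tables
#'
#' Maps the internal field names to the column names expected in input
#' files. The defaults follow the common GWAS-catalog-style convention
#' (`snp`, `chr`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se`, `p`, `n`). Mapping is explicit: a column that is absent under its
#' mapped name is an error for required fields, never fuzzy-matched.
#'
#' @return Named character vector mapping internal names to file columns.
#' @export
default_column_map <- function() {
  c(snp_id = "snp", chrom = "chr", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", p = "p", n = "n")
}

REQUIRED_SUMMARY_FIELDS <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
OPTIONAL_SUMMARY_FIELDS <- c("chrom", "pos", "eaf", "p", "n")

#' Construct a validated GWAS summary dataset
#'
#' A summary dataset holds one row per SNP for a single trait: alleles,
#' effect-allele frequency, effect size (log-odds for binary traits),
#' standard error, p-value and sample size. Missing p-values are filled
#' from the two-sided normal tail of beta/se.
#'
#' @param records Data frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` and optionally `chrom`, `pos`, `eaf`,
#'   `p`, `n`.
#' @param trait_label Human-readable trait name.
#' @param sample_overlap_tag Free-text tag identifying the sample the GWAS
#'   was run in; datasets from the same tag should not be combined in a
#'   two-sample analysis.
#' @return An object of class `summary_dataset`.
#' @export
summary_dataset <- function(records, trait_label, sample_overlap_tag = "") {
  if (!is.data.frame(records)) stop_config("'records' must be a data frame")
  missing_cols <- setdiff(REQUIRED_SUMMARY_FIELDS, names(records))
  if (length(missing_cols))
    stop_config("summary dataset lacks required column(s): %s",
                paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (f in OPTIONAL_SUMMARY_FIELDS)
    if (is.null(records[[f]])) records[[f]] <- NA
  records$snp_id <- as.character(records$snp_id)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))

  dup <- records$snp_id[duplicated(records$snp_id)]
  if (length(dup))
    stop_config("duplicate snp_id in dataset '%s': %s", trait_label,
                paste(unique(dup), collapse = ", "))
  bad_allele <- !(records$effect_allele %in% names(DNA_COMPLEMENT)) |
    !(records$other_allele %in% names(DNA_COMPLEMENT))
  if (any(bad_allele))
    stop_config("non-ACGT allele at snp_id %s",
                paste(records$snp_id[bad_allele], collapse = ", "))
  if (any(records$effect_allele == records$other_allele))
    stop_config("effect and other allele identical at snp_id %s",
                paste(records$snp_id[records$effect_allele == records$other_allele],
                      collapse = ", "))
  for (f in c("beta", "se")) {
    if (!is.numeric(records[[f]]) || anyNA(records[[f]]))
      stop_config("column '%s' must be numeric and non-missing", f)
  }
  if (any(records$se <= 0)) stop_config("'se' must be positive for every SNP")
  records$p <- as.numeric(records$p)
  fill <- is.na(records$p)
  records$p[fill] <- two_sided_normal_p(records$beta[fill] / records$se[fill])
  if (any(records$p <= 0 | records$p > 1, na.rm = TRUE))
    stop_config("p-values must lie in (0, 1]")
  records$eaf <- as.numeric(records$eaf)
  if (any(records$eaf < 0 | records$eaf > 1, na.rm = TRUE))
    stop_config("eaf must lie in [0, 1]")
  rownames(records) <- NULL
  structure(list(trait_label = as.character(trait_label),
                 records = records,
                 sample_overlap_tag = as.character(sample_overlap_tag)),
            class = "summary_dataset")
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s: %d SNPs (sample tag: '%s')\n",
              x$trait_label, nrow(x$records), x$sample_overlap_tag))
  invisible(x)
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab-separated table with a header row and maps its columns onto
#' the internal schema via an explicit column mapping. Required columns are
#' SNP id, both alleles, beta and se; frequency, p and n are optional (a
#' missing p column is recomputed from beta/se).
#'
#' @param path Path to a tab-separated text file.
#' @param column_map Named character vector as produced by
#'   [default_column_map()]; names are internal fields, values are file
#'   column names.
#' @param trait_label Trait name to attach; defaults to the file name.
#' @param sample_overlap_tag Sample tag, see [summary_dataset()].
#' @return A `summary_dataset`.
#' @export
read_summary_stats <- function(path, column_map = default_column_map(),
                               trait_label = basename(path),
                               sample_overlap_tag = "") {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  full_map <- default_column_map()
  full_map[names(column_map)] <- column_map
  for (f in REQUIRED_SUMMARY_FIELDS) {
    if (!(full_map[[f]] %in% names(raw)))
      stop_config("required column '%s' (mapped to field '%s') missing from %s",
                  full_map[[f]], f, path)
  }
  out <- data.frame(snp_id = raw[[full_map[["snp_id"]]]],
                    stringsAsFactors = FALSE)
  for (f in c("effect_allele", "other_allele"))
    out[[f]] <- raw[[full_map[[f]]]]
  for (f in c("chrom")) {
    col <- full_map[[f]]
    out[[f]] <- if (col %in% names(raw)) raw[[col]] else NA_character_
  }
  for (f in c("pos", "eaf", "beta", "se", "p", "n")) {
    col <- full_map[[f]]
    if (col %in% names(raw)) {
      val <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(val) & !(raw[[col]] %in% c("", "NA", "na", ".")))
      if (length(bad) && f %in% c("beta", "se"))
        stop_parse("non-numeric value in column '%s' at data row %d of %s",
                   col, bad[1], path)
      out[[f]] <- val
    } else {
      out[[f]] <- NA_real_
    }
  }
  summary_dataset(out, trait_label = trait_label,
                  sample_overlap_tag = sample_overlap_tag)
}

#' Write a GWAS summary dataset
#'
#' Writes the tab-separated format [read_summary_stats()] reads, preserving
#' numeric fields through the text round trip.
#'
#' @param dataset A `summary_dataset`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(dataset, path) {
  stopifnot(inherits(dataset, "summary_dataset"))
  r <- dataset$records
  out <- data.frame(snp = r$snp_id, chr = r$chrom, pos = fmt_num(r$pos),
                    effect_allele = r$effect_allele,
                    other_allele = r$other_allele,
                    eaf = fmt_num(r$eaf), beta = fmt_num(r$beta),
                    se = fmt_num(r$se), p = fmt_num(r$p), n = fmt_num(r$n),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report table
#'
#' Serializes a collection of MR and/or mediation estimates to one
#' tab-separated table: method, point estimate, 95% CI bounds, p-value,
#' SNP count and heterogeneity statistics (NA where a column does not
#' apply). Values survive a read/write round trip to at least 12
#' significant digits.
#'
#' @param results Non-empty list of `mr_estimate` and/or
#'   `mediation_estimate` objects (a single object is accepted).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(results, path) {
  if (inherits(results, c("mr_estimate", "mediation_estimate")))
    results <- list(results)
  if (!is.list(results) || length(results) == 0)
    stop_config("'results' must be a non-empty collection of estimates")
  rows <- lapply(results, function(x) {
    if (inherits(x, "mr_estimate")) {
      data.frame(method = x$method, estimate = x$theta, se = x$se,
                 ci_lower = x$ci95[1], ci_upper = x$ci95[2], p = x$p,
                 k_snps = x$k_snps, q = x$q %||% NA_real_,
                 i2 = x$i2 %||% NA_real_, stringsAsFactors = FALSE)
    } else if (inherits(x, "mediation_estimate")) {
      data.frame(method = "two_step_mediation", estimate = x$pm, se = x$pm_se,
                 ci_lower = x$pm_ci95[1], ci_upper = x$pm_ci95[2], p = x$p,
                 k_snps = NA_real_, q = NA_real_, i2 = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      stop_config("unsupported result type: %s", paste(class(x), collapse = "/"))
    }
  })
  tab <- do.call(rbind, rows)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], fmt_num)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_parse("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a report table written by [write_report()]
#'
#' @param path Path to the report file.
#' @return Data frame with numeric columns restored.
#' @export
read_report <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  for (f in setdiff(names(tab), "method")) tab[[f]] <- as.numeric(tab[[f]])
  tab
}

#' Read a cohort table
#'
#' One row per subject, tab-separated with a header; column roles (time,
#' event, exposure, covariates, mediators) are declared at analysis time
#' by the cohort functions rather than guessed at parse time.
#'
#' @param path Path to a tab-separated text file.
#' @return Data frame.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
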