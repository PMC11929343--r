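#' Pipeline configuration
#'
#' Bundles every tunable of the MR pipeline. Defaults encode the study
#' design: genome-wide instrument significance P < 5e-8 (dietary exposures
#' with few genome-wide hits conventionally relax this to 5e-6 via
#' `p_threshold`), LD clumping at r^2 < 0.001 within a 10,000 kb window,
#' and a 0.42-0.58 allele-frequency ambiguity band for palindromic SNPs.
#'
#' @param p_threshold Instrument p-value threshold for the exposure
#'   (strict inequality).
#' @param mediator_p_threshold Instrument threshold for mediator traits;
#'   kept separate because mediator GWAS are typically well powered and use
#'   the genome-wide 5e-8 even when the exposure threshold is relaxed.
#' @param clump_r2 LD r-squared above which the weaker SNP is discarded.
#' @param clump_window_kb Half-width of the clumping window in kb around
#'   the index SNP.
#' @param palindromic_eaf_band Two frequencies; palindromic SNPs whose
#'   effect-allele frequency falls inside this band (or is missing) are
#'   dropped during harmonization.
#' @param n_boot Bootstrap replicates for the weighted-median SE.
#' @param n_presso_sim Simulations for the MR-PRESSO global/outlier tests.
#' @param seed Integer seed used by the stochastic diagnostics.
#' @param alpha Two-sided significance level.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(p_threshold = 5e-8,
                            mediator_p_threshold = 5e-8,
                            clump_r2 = 0.001,
                            clump_window_kb = 10000,
                            palindromic_eaf_band = c(0.42, 0.58),
                            n_boot = 1000,
                            n_presso_sim = 1000,
                            seed = 1L,
                            alpha = 0.05) {
  assert_scalar_number(p_threshold, "p_threshold", 0, 1, TRUE, FALSE)
  assert_scalar_number(mediator_p_threshold, "mediator_p_threshold", 0, 1, TRUE, FALSE)
  assert_scalar_number(clump_r2, "clump_r2", 0, 1)
  assert_scalar_number(clump_window_kb, "clump_window_kb", 0, Inf, TRUE)
  if (length(palindromic_eaf_band) != 2 ||
      palindromic_eaf_band[1] > palindromic_eaf_band[2])
    stop_config("'palindromic_eaf_band' must be an ordered pair of frequencies")
  assert_scalar_number(n_boot, "n_boot", 1, Inf)
  assert_scalar_number(n_presso_sim, "n_presso_sim", 1, Inf)
  assert_scalar_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  structure(list(p_threshold = p_threshold,
                 mediator_p_threshold = mediator_p_threshold,
                 clump_r2 = clump_r2,
                 clump_window_kb = as.integer(clump_window_kb),
                 palindromic_eaf_band = as.numeric(palindromic_eaf_band),
                 n_boot = as.integer(n_boot),
                 n_presso_sim = as.integer(n_presso_sim),
                 seed = as.integer(seed),
                 alpha = alpha),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys mirror
#'   the arguments of [pipeline_config()]; absent keys take their defaults.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_config("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write deterministic run metadata to a sidecar file
#'
#' Records the configuration (and a digest of it), the seed and a
#' timestamp alongside an analysis output, so a run can be reproduced and
#' audited from the output directory alone.
#'
#' @param config A `pipeline_config`.
#' @param path Sidecar file path.
#' @param extra Optional named list of additional fields to log.
#' @return Invisibly, `path`.
#' @export
write_run_metadata <- function(config, path, extra = list()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  meta <- c(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 seed = config$seed,
                 config_digest = sprintf("%d", sum(utf8ToInt(cfg_json)) %% 1000000007L),
                 config = unclass(config)),
            extra)
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' Construct an LD matrix
#'
#' Squared-correlation (r^2) matrix between SNPs, with per-SNP chromosome
#' and 1-based position used by the clumping window.
#'
#' @param snp_ids Character vector of SNP ids (defines row/column order).
#' @param r2 Square symmetric matrix of r-squared values in \[0, 1\] with
#'   unit diagonal.
#' @param positions Data frame with columns `snp_id`, `chrom`, `pos`.
#' @return Object of class `ld_matrix`.
#' @export
ld_matrix <- function(snp_ids, r2, positions) {
  snp_ids <- as.character(snp_ids)
  r2 <- as.matrix(r2)
  if (nrow(r2) != length(snp_ids) || ncol(r2) != length(snp_ids))
    stop_config("r2 matrix dimensions do not match the number of SNP ids")
  if (max(abs(r2 - t(r2))) > 1e-12)
    stop_config("r2 matrix must be symmetric (within 1e-12)")
  if (any(abs(diag(r2) - 1) > 1e-12))
    stop_config("r2 matrix must have unit diagonal")
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12))
    stop_config("r2 values must lie in [0, 1]")
  dimnames(r2) <- list(snp_ids, snp_ids)
  positions <- as.data.frame(positions, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "chrom", "pos") %in% names(positions)))
    stop_config("'positions' needs columns snp_id, chrom, pos")
  if (!setequal(positions$snp_id, snp_ids))
    stop_config("'positions' must cover exactly the SNPs of the r2 matrix")
  positions <- positions[match(snp_ids, positions$snp_id), , drop = FALSE]
  rownames(positions) <- NULL
  structure(list(snp_ids = snp_ids, r2 = r2, positions = positions),
            class = "ld_matrix")
}

#' LD matrix for mutually independent SNPs
#'
#' Identity r^2, with positions taken from a summary dataset (or placed on
#' distinct chromosomes when the dataset carries none).
#'
#' @param dataset A `summary_dataset`.
#' @return An `ld_matrix` with zero off-diagonal r^2.
#' @export
independent_ld <- function(dataset) {
  stopifnot(inherits(dataset, "summary_dataset"))
  r <- dataset$records
  chrom <- r$chrom
  pos <- r$pos
  if (anyNA(chrom) || anyNA(pos)) {
    chrom <- as.character(rep_len(1:22, nrow(r)))
    pos <- as.numeric(seq_len(nrow(r))) * 2.1e7
  }
  ld_matrix(r$snp_id, diag(nrow(r)),
            data.frame(snp_id = r$snp_id, chrom = chrom, pos = pos,
                       stringsAsFactors = FALSE))
}

#' Read an LD matrix
#'
#' Expects a square tab-separated table whose header and first column are
#' SNP ids, plus a companion positions table (`snp_id`, `chrom`, `pos`).
#'
#' @param path Path to the r^2 table.
#' @param positions_path Path to the positions table.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path, positions_path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  pos <- utils::read.delim(positions_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  ld_matrix(rownames(tab), as.matrix(tab), pos)
}

#' Write an LD matrix
#'
#' @param ld An `ld_matrix`.
#' @param path Output path for the r^2 table.
#' @param positions_path Output path for the positions table.
#' @return Invisibly, `path`.
#' @export
write_ld_matrix <- function(ld, path, positions_path) {
  stopifnot(inherits(ld, "ld_matrix"))
  tab <- as.data.frame(ld$r2)
  utils::write.table(cbind(snp_id = ld$snp_ids, tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ld$positions, positions_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
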