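#' Univariable two-sample MR pipeline
#'
#' Runs the full chain on one exposure/outcome pair: instrument selection
#' at the configured p threshold, greedy LD clumping, F-statistic
#' instrument strength, effect-allele harmonization, and the estimator
#' suite: IVW (fixed and multiplicative random effects, the latter being
#' the primary estimate), and when enough instruments survive, the
#' weighted median (k >= 3), MR-Egger (k >= 3) and MR-PRESSO (k >= 4).
#' With a single retained instrument only the Wald ratio/IVW row is
#' produced and the diagnostics are marked unavailable.
#'
#' @param exposure,outcome `summary_dataset`s from non-overlapping samples.
#' @param ld An `ld_matrix` covering the exposure instruments (use
#'   [independent_ld()] when instruments are pre-pruned).
#' @param config A [pipeline_config()].
#' @param binary_outcome If `TRUE` (the default, matching a case-control
#'   outcome GWAS) estimates are log-odds ratios and the report carries
#'   `exp(theta)` columns.
#' @param p_threshold Optional override of `config$p_threshold` for this
#'   exposure.
#' @return Object of class `mr_report`: `estimates` (data frame, one row
#'   per method), `egger` (`egger_estimate` or NULL), `presso`
#'   (`presso_result` or NULL), `strength`, `instruments`, `harmonized`,
#'   `per_snp` (ratio, SE, leave-one-out estimate, outlier p).
#' @export
run_univariable_mr <- function(exposure, outcome, ld, config = pipeline_config(),
                               binary_outcome = TRUE, p_threshold = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  thr <- p_threshold %||% config$p_threshold
  selected <- select_instruments(exposure, thr)
  if (length(selected) == 0)
    stop_config("no instrument passes p < %g for '%s'", thr,
                exposure$trait_label)
  kept <- clump(selected, exposure, ld, config$clump_r2, config$clump_window_kb)
  strength <- instrument_strength(exposure, kept)
  hset <- harmonize(exposure, outcome, intersect(kept, outcome$records$snp_id),
                    config$palindromic_eaf_band)
  lost <- setdiff(kept, outcome$records$snp_id)
  if (length(lost))
    hset$dropped <- rbind(hset$dropped,
                          data.frame(snp_id = lost, reason = "absent_in_outcome",
                                     stringsAsFactors = FALSE))
  k <- nrow(hset$pairs)
  if (k == 0)
    stop_config("no SNP pair survives harmonization for '%s' on '%s'",
                exposure$trait_label, outcome$trait_label)

  ests <- list(mr_ivw(hset, "random", binary_outcome = binary_outcome),
               mr_ivw(hset, "fixed", binary_outcome = binary_outcome))
  if (k == 1) ests[[1]]$method <- "wald_ivw"
  egger <- NULL; wm <- NULL; presso <- NULL
  if (k >= 3) {
    wm <- mr_weighted_median(hset, n_boot = config$n_boot,
                             seed = config$seed, binary_outcome = binary_outcome)
    egger <- mr_egger(hset, binary_outcome = binary_outcome)
    ests <- c(ests, list(wm, egger$slope))
  }
  if (k >= 4) {
    presso <- mr_presso(hset, n_sim = config$n_presso_sim, seed = config$seed,
                        alpha = config$alpha, binary_outcome = binary_outcome)
    if (!is.null(presso$corrected)) ests <- c(ests, list(presso$corrected))
  }
  est_tab <- do.call(rbind, lapply(ests, function(e) {
    data.frame(method = e$method, theta = e$theta, se = e$se,
               ci_lower = e$ci95[1], ci_upper = e$ci95[2], p = e$p,
               or = e$or, or_lower = e$or_ci95[1], or_upper = e$or_ci95[2],
               k_snps = e$k_snps, q = e$q, i2 = e$i2,
               egger_intercept = NA_real_, egger_intercept_p = NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(egger)) {
    row <- est_tab$method == "egger_slope"
    est_tab$egger_intercept[row] <- egger$intercept
    est_tab$egger_intercept_p[row] <- egger$intercept_p
  }
  rc <- ratio_components(hset)
  w <- 1 / rc$se^2
  per_snp <- data.frame(snp_id = rc$snp_id, ratio = rc$theta, se = rc$se,
                        f_stat = strength$per_snp_f[rc$snp_id],
                        loo_estimate = if (k >= 2)
                          loo_slopes(hset$pairs$beta_exp, hset$pairs$beta_out,
                                     1 / hset$pairs$se_out^2) else NA_real_,
                        outlier_p = if (!is.null(presso))
                          unname(presso$outlier_p[rc$snp_id]) else NA_real_,
                        stringsAsFactors = FALSE)
  structure(list(exposure = exposure$trait_label,
                 outcome = outcome$trait_label,
                 estimates = est_tab, egger = egger, presso = presso,
                 strength = strength, instruments = kept,
                 harmonized = hset, per_snp = per_snp,
                 binary_outcome = binary_outcome,
                 config = config, seed = config$seed),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> %s -> %s (%d instruments, mean F = %.1f%s)\n",
              x$exposure, x$outcome, length(x$instruments),
              x$strength$mean_f,
              if (x$strength$weak) ", WEAK" else ""))
  cols <- if (x$binary_outcome) c("method", "or", "or_lower", "or_upper", "p", "q", "i2")
          else c("method", "theta", "ci_lower", "ci_upper", "p", "q", "i2")
  print(x$estimates[, cols], digits = 4, row.names = FALSE)
  if (!is.null(x$egger))
    cat(sprintf("MR-Egger intercept %.4f (p = %.3g)\n",
                x$egger$intercept, x$egger$intercept_p))
  if (!is.null(x$presso) && length(x$presso$outlier_snps))
    cat("MR-PRESSO outliers:", paste(x$presso$outlier_snps, collapse = ", "), "\n")
  invisible(x)
}
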