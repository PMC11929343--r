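#' Screen candidate mediators by two-step MR
#'
#' A mediator qualifies when both causal steps are nominally significant
#' by IVW: (i) exposure -> mediator, instrumented by the exposure's own
#' clumped instruments, and (ii) mediator -> outcome, instrumented by the
#' mediator's own instruments (selected and clumped independently at
#' `config$mediator_p_threshold`). Both step reports, including their
#' Egger-intercept diagnostics, are returned for every candidate with the
#' qualification flag attached; a mediator with no usable instruments is
#' recorded as unevaluable rather than failing the screen.
#'
#' @param exposure `summary_dataset` for the exposure.
#' @param mediators Named list of `summary_dataset`s, one per candidate.
#' @param outcome `summary_dataset` for the outcome.
#' @param ld An `ld_matrix` covering all instruments.
#' @param config A [pipeline_config()].
#' @param p_threshold Optional exposure-instrument threshold override.
#' @param binary_outcome Whether the outcome GWAS is case-control.
#' @return List of class `mediator_screen`; one element per candidate
#'   with `mediator`, `step1`, `step2` (`mr_report`s or NULL),
#'   `qualified`, `unevaluable`, `reason`.
#' @export
screen_mediators <- function(exposure, mediators, outcome, ld,
                             config = pipeline_config(), p_threshold = NULL,
                             binary_outcome = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(mediators) == 0) return(structure(list(), class = "mediator_screen"))
  if (is.null(names(mediators)) || any(names(mediators) == ""))
    names(mediators) <- vapply(mediators, function(m) m$trait_label, character(1))
  out <- lapply(names(mediators), function(nm) {
    med <- mediators[[nm]]
    res <- list(mediator = nm, step1 = NULL, step2 = NULL,
                qualified = FALSE, unevaluable = FALSE, reason = "")
    step1 <- tryCatch(
      run_univariable_mr(exposure, med, ld, config, binary_outcome = FALSE,
                         p_threshold = p_threshold),
      error = function(e) e)
    step2 <- tryCatch(
      run_univariable_mr(med, outcome, ld, config,
                         binary_outcome = binary_outcome,
                         p_threshold = config$mediator_p_threshold),
      error = function(e) e)
    if (inherits(step1, "error") || inherits(step2, "error")) {
      res$unevaluable <- TRUE
      res$reason <- conditionMessage(if (inherits(step1, "error")) step1 else step2)
      if (!inherits(step1, "error")) res$step1 <- step1
      if (!inherits(step2, "error")) res$step2 <- step2
      return(res)
    }
    res$step1 <- step1; res$step2 <- step2
    p1 <- primary_estimate(step1)$p
    p2 <- primary_estimate(step2)$p
    res$qualified <- (p1 < config$alpha) && (p2 < config$alpha)
    res
  })
  names(out) <- names(mediators)
  structure(out, class = "mediator_screen")
}

# the report's primary (random-effects IVW) row as an mr_estimate-like list
primary_estimate <- function(report) {
  row <- report$estimates[report$estimates$method %in% c("ivw_random", "wald_ivw"), ][1, ]
  list(method = row$method, theta = row$theta, se = row$se,
       ci95 = c(row$ci_lower, row$ci_upper), p = row$p, k_snps = row$k_snps,
       q = row$q, i2 = row$i2)
}

#' Combine two-step MR estimates into a mediation estimate
#'
#' Product-of-coefficients mediation on the scale of the step estimates
#' (log-odds for a binary outcome): the indirect effect is
#' `theta1 * theta2`, its SE is the two-sample delta form
#' `sqrt(theta2^2 se1^2 + theta1^2 se2^2)` (cross-step covariances are
#' zero under the non-overlapping-samples design), and the proportion
#' mediated is `indirect / theta_total` with a first-order delta-method
#' CI treating the indirect and total estimates as independent. A
#' negative proportion is reported as 0 with the `truncated` flag set,
#' while the CI is reported untruncated so the uncertainty is not
#' misrepresented.
#'
#' @param total Total-effect estimate (`mr_estimate` or list with
#'   `theta`, `se`): exposure -> outcome.
#' @param step1 Exposure -> mediator estimate.
#' @param step2 Mediator -> outcome estimate.
#' @param mediator Optional mediator label.
#' @return Object of class `mediation_estimate`: `total`, `step1`,
#'   `step2`, `indirect`, `indirect_se`, `pm` (truncated), `pm_untruncated`,
#'   `pm_se`, `pm_ci95` (untruncated), `truncated`, `p` (for the indirect
#'   effect).
#' @export
two_step_mediation <- function(total, step1, step2, mediator = NA_character_) {
  for (nm in c("total", "step1", "step2")) {
    e <- get(nm)
    if (!is.list(e) || is.null(e$theta) || is.null(e$se))
      stop_config("'%s' must carry fields theta and se", nm)
  }
  if (total$theta == 0)
    stop_config("proportion mediated undefined: total effect is 0")
  t1 <- step1$theta; s1 <- step1$se
  t2 <- step2$theta; s2 <- step2$se
  tt <- total$theta; st <- total$se
  indirect <- t1 * t2
  indirect_se <- sqrt(t2^2 * s1^2 + t1^2 * s2^2)
  pm_raw <- indirect / tt
  pm_se <- if (indirect == 0) {
    indirect_se / abs(tt)   # first-order limit as the product vanishes
  } else {
    abs(pm_raw) * sqrt(indirect_se^2 / indirect^2 + st^2 / tt^2)
  }
  pm_ci <- pm_raw + c(-1, 1) * stats::qnorm(0.975) * pm_se
  truncated <- pm_raw < 0
  p_ind <- if (indirect_se > 0) two_sided_normal_p(indirect / indirect_se) else NA_real_
  structure(list(mediator = mediator, total = total, step1 = step1,
                 step2 = step2, indirect = indirect,
                 indirect_se = indirect_se,
                 pm = if (truncated) 0 else pm_raw,
                 pm_untruncated = pm_raw, pm_se = pm_se, pm_ci95 = pm_ci,
                 truncated = truncated, p = p_ind),
            class = "mediation_estimate")
}

#' @export
print.mediation_estimate <- function(x, ...) {
  cat(sprintf("<mediation_estimate>%s indirect = %.4f (SE %.4f), PM = %.1f%%%s, 95%% CI [%.1f%%, %.1f%%]\n",
              if (is.na(x$mediator)) "" else paste0(" ", x$mediator, ":"),
              x$indirect, x$indirect_se, 100 * x$pm,
              if (x$truncated) " (truncated from < 0)" else "",
              100 * x$pm_ci95[1], 100 * x$pm_ci95[2]))
  invisible(x)
}

#' Tabulate mediation estimates
#'
#' One row per mediator: both step estimates with CIs, the indirect
#' effect, and the proportion mediated in percent with its untruncated CI
#' and truncation flag.
#'
#' @param results Non-empty list of `mediation_estimate`s.
#' @return Data frame.
#' @export
mediation_report <- function(results) {
  if (inherits(results, "mediation_estimate")) results <- list(results)
  if (!is.list(results) || length(results) == 0)
    stop_config("'results' must be a non-empty list of mediation estimates")
  do.call(rbind, lapply(results, function(x) {
    stopifnot(inherits(x, "mediation_estimate"))
    data.frame(mediator = x$mediator,
               step1_beta = x$step1$theta, step1_se = x$step1$se,
               step1_lower = x$step1$theta - 1.96 * x$step1$se,
               step1_upper = x$step1$theta + 1.96 * x$step1$se,
               step2_beta = x$step2$theta, step2_se = x$step2$se,
               step2_lower = x$step2$theta - 1.96 * x$step2$se,
               step2_upper = x$step2$theta + 1.96 * x$step2$se,
               indirect = x$indirect, indirect_se = x$indirect_se,
               pm_pct = 100 * x$pm,
               pm_pct_lower = 100 * x$pm_ci95[1],
               pm_pct_upper = 100 * x$pm_ci95[2],
               truncated = x$truncated,
               stringsAsFactors = FALSE)
  }))
}

#' End-to-end two-step MR mediation
#'
#' Convenience orchestration mirroring the analysis design: estimate the
#' total effect by univariable MR, screen the candidate mediators, and
#' form a mediation estimate for every qualified mediator using the raw
#' IVW total effect as the denominator (switch `use_corrected_total` to
#' divide by the MR-PRESSO outlier-corrected total instead).
#'
#' @inheritParams screen_mediators
#' @param use_corrected_total Use the outlier-corrected IVW total effect
#'   as the PM denominator when available.
#' @return List with `total` (`mr_report`), `screen` (`mediator_screen`),
#'   `mediation` (list of `mediation_estimate`s) and `table`
#'   (the [mediation_report()] data frame, NULL when nothing qualified).
#' @export
run_two_step_mr <- function(exposure, mediators, outcome, ld,
                            config = pipeline_config(), p_threshold = NULL,
                            binary_outcome = TRUE,
                            use_corrected_total = FALSE) {
  total_report <- run_univariable_mr(exposure, outcome, ld, config,
                                     binary_outcome = binary_outcome,
                                     p_threshold = p_threshold)
  total <- primary_estimate(total_report)
  if (use_corrected_total && !is.null(total_report$presso) &&
      !is.null(total_report$presso$corrected)) {
    cc <- total_report$presso$corrected
    total <- list(method = cc$method, theta = cc$theta, se = cc$se, p = cc$p)
  }
  screen <- screen_mediators(exposure, mediators, outcome, ld, config,
                             p_threshold = p_threshold,
                             binary_outcome = binary_outcome)
  med <- lapply(Filter(function(r) isTRUE(r$qualified), screen), function(r) {
    two_step_mediation(total, primary_estimate(r$step1),
                       primary_estimate(r$step2), mediator = r$mediator)
  })
  list(total = total_report, screen = screen, mediation = med,
       table = if (length(med)) mediation_report(med) else NULL)
}
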