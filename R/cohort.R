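check_cohort_records <- function(records, time = "time", event = "event") {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop_config("'records' must be a non-empty data frame")
  for (col in c(time, event))
    if (is.null(records[[col]])) stop_config("column '%s' missing", col)
  if (any(records[[time]] <= 0)) stop_config("follow-up times must be positive")
  if (!all(records[[event]] %in% c(0, 1)))
    stop_config("'%s' must be a 0/1 event indicator", event)
  invisible(records)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximum partial likelihood with Efron tie handling (via the survival
#' package's Newton-Raphson fitter). Requires at least two events and no
#' constant term; a monotone partial likelihood (perfect separation) is
#' reported as an error naming the offending term rather than returning a
#' silently diverged coefficient.
#'
#' @param records Data frame, one row per subject.
#' @param terms Character vector of model terms (column names, or
#'   expressions like `"log(x)"`).
#' @param time,event Names of the follow-up time (years) and 0/1 event
#'   columns.
#' @return Object of class `cox_fit`: `coefficients`, `covariance`,
#'   `hr` (data frame with HR and 95% CI per term), `loglik`,
#'   `n_events`, `ties_method`, and the underlying `model`.
#' @export
fit_cox <- function(records, terms, time = "time", event = "event") {
  check_cohort_records(records, time, event)
  if (length(terms) == 0) stop_config("'terms' must be non-empty")
  if (sum(records[[event]]) < 2)
    stop_config("Cox model needs at least 2 events, got %d",
                sum(records[[event]]))
  for (tm in terms) {
    v <- records[[tm]]
    if (!is.null(v) && length(unique(v)) < 2)
      stop_config("term '%s' is constant across subjects", tm)
  }
  fml <- stats::as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ",
                                  paste(terms, collapse = " + ")))
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "efron",
                    model = TRUE, x = FALSE),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w), ignore.case = TRUE))
        diverged <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- stats::coef(fit)
  if (diverged || any(abs(coefs) > 15)) {
    bad <- names(coefs)[which.max(abs(coefs))]
    stop_config("monotone partial likelihood (separation) for term '%s'", bad)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  hr <- data.frame(term = names(coefs), coef = unname(coefs),
                   se = unname(se), hr = exp(unname(coefs)),
                   hr_lower = exp(unname(coefs) - 1.96 * unname(se)),
                   hr_upper = exp(unname(coefs) + 1.96 * unname(se)),
                   p = two_sided_normal_p(unname(coefs) / unname(se)),
                   stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, covariance = stats::vcov(fit),
                 hr = hr, loglik = fit$loglik[length(fit$loglik)],
                 n_events = fit$nevent, ties_method = "efron",
                 model = fit, terms = terms, time = time, event = event),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %d events, Efron ties, loglik = %.3f\n",
              x$n_events, x$loglik))
  print(x$hr, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Schoenfeld residual test of proportional hazards
#'
#' Correlation test of the scaled Schoenfeld residuals against the rank
#' of event time (via `survival::cox.zph(transform = "rank")`), per term
#' plus a global chi-square test.
#'
#' @param fit A `cox_fit`.
#' @return Data frame: `term`, `chisq`, `df`, `p` (last row `GLOBAL`).
#' @export
schoenfeld_test <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_events < 2)
    stop_config("Schoenfeld test needs at least 2 events")
  z <- survival::cox.zph(fit$model, transform = "rank")
  tab <- as.data.frame(z$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, stringsAsFactors = FALSE, row.names = NULL)
}

#' Person-year and incidence-rate summary
#'
#' Per-group subjects, person-years, events, incidence rate per 1000
#' person-years and mean follow-up (person-years divided by subjects).
#' Group sums always reproduce the overall totals.
#'
#' @param records Cohort data frame.
#' @param group Optional name of a grouping column; `NULL` summarizes the
#'   whole cohort in one row.
#' @param time,event Column names as in [fit_cox()].
#' @return Data frame: `group`, `n_subjects`, `person_years`, `events`,
#'   `rate_per_1000py`, `mean_follow_up`.
#' @export
incidence_summary <- function(records, group = NULL, time = "time",
                              event = "event") {
  check_cohort_records(records, time, event)
  g <- if (is.null(group)) rep("overall", nrow(records))
       else as.character(records[[group]])
  agg <- lapply(split(seq_len(nrow(records)), g), function(ix) {
    py <- sum(records[[time]][ix])
    ev <- sum(records[[event]][ix])
    data.frame(n_subjects = length(ix), person_years = py, events = ev,
               rate_per_1000py = if (py > 0) ev / py * 1000 else 0,
               mean_follow_up = py / length(ix))
  })
  out <- do.call(rbind, agg)
  out <- cbind(group = names(agg), out)
  rownames(out) <- NULL
  out
}

#' Screen a candidate mediator by linear regression
#'
#' Ordinary least squares of the continuous mediator on the exposure
#' (indicator contrasts against the lowest category for a factor) plus
#' covariates. Returns the exposure-contrast coefficients with two-sided
#' p-values; mediators whose exposure contrast is significant at alpha
#' are candidates for [difference_method()]. Rank deficiency is an error
#' naming the collinear terms.
#'
#' @param records Cohort data frame.
#' @param mediator Name of the continuous mediator column.
#' @param exposure Name of the exposure term.
#' @param covariates Character vector of adjustment terms.
#' @return List: `contrasts` (data frame: term, estimate, se, ci bounds,
#'   p) and `model` (the `lm` fit).
#' @export
screen_mediators_obs <- function(records, mediator, exposure,
                                 covariates = character(0)) {
  if (is.null(records[[mediator]]) || !is.numeric(records[[mediator]]))
    stop_config("mediator '%s' must be a numeric column", mediator)
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(mediator, "~", rhs))
  X <- stats::model.matrix(fml, data = records)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_config("model is rank deficient; collinear term(s): %s",
                paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(fml, data = records)
  sm <- summary(fit)$coefficients
  keep <- grepl(paste0("^", exposure), rownames(sm))
  est <- sm[keep, , drop = FALSE]
  contrasts <- data.frame(term = rownames(est), estimate = est[, 1],
                          se = est[, 2],
                          ci_lower = est[, 1] - 1.96 * est[, 2],
                          ci_upper = est[, 1] + 1.96 * est[, 2],
                          p = est[, 4], stringsAsFactors = FALSE,
                          row.names = NULL)
  list(contrasts = contrasts, model = fit)
}

exposure_coef <- function(fit, exposure) {
  nm <- names(fit$coefficients)
  hit <- which(nm == exposure | grepl(paste0("^", exposure), nm))
  if (length(hit) == 0)
    stop_config("exposure term '%s' not found in the fitted model", exposure)
  if (length(hit) > 1)
    stop_config("exposure '%s' yields multiple contrasts; use a binary or numeric exposure for the difference method", exposure)
  hit
}

#' Difference-method mediation for a Cox exposure effect
#'
#' Compares the exposure log hazard ratio between a model without
#' (`beta_total`) and with (`beta_direct`) the mediator:
#' `PM = (beta_total - beta_direct) / beta_total` on the log-HR scale
#' (the `"hr"` scale alternative `(HR_t - HR_d)/(HR_t - 1)` is available).
#' The CI is a subject-level nonparametric bootstrap of the whole
#' two-model procedure (percentile interval, seeded); bootstrap
#' replicates where either model fails are dropped and counted, with more
#' than 5% dropped reported as an error. A negative PM is reported as 0
#' with the `truncated` flag, the CI staying untruncated.
#'
#' @param records Cohort data frame.
#' @param exposure Exposure term (numeric or two-level factor).
#' @param mediator Mediator column name.
#' @param covariates Adjustment terms.
#' @param n_boot Bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @param pm_scale `"loghr"` (default) or `"hr"`.
#' @param time,event Column names as in [fit_cox()].
#' @return Object of class `obs_mediation`: `beta_total`, `beta_direct`,
#'   `pm` (truncated), `pm_untruncated`, `pm_ci95`, `truncated`,
#'   `n_boot_used`, `n_boot_failed`, `method = "difference"`, plus both
#'   `cox_fit`s.
#' @export
difference_method <- function(records, exposure, mediator,
                              covariates = character(0), n_boot = 500,
                              seed = 1L, pm_scale = c("loghr", "hr"),
                              time = "time", event = "event") {
  pm_scale <- match.arg(pm_scale)
  fit_pair <- function(dat) {
    f_tot <- fit_cox(dat, c(exposure, covariates), time = time, event = event)
    f_dir <- fit_cox(dat, c(exposure, covariates, mediator),
                     time = time, event = event)
    i_tot <- exposure_coef(f_tot$model, exposure)
    i_dir <- exposure_coef(f_dir$model, exposure)
    c(total = unname(f_tot$coefficients[i_tot]),
      direct = unname(f_dir$coefficients[i_dir]))
  }
  pm_from <- function(bt, bd) {
    if (pm_scale == "loghr") (bt - bd) / bt
    else (exp(bt) - exp(bd)) / (exp(bt) - 1)
  }
  f_total <- fit_cox(records, c(exposure, covariates), time = time, event = event)
  f_direct <- fit_cox(records, c(exposure, covariates, mediator),
                      time = time, event = event)
  bt <- unname(f_total$coefficients[exposure_coef(f_total$model, exposure)])
  bd <- unname(f_direct$coefficients[exposure_coef(f_direct$model, exposure)])
  if (bt == 0) stop_config("proportion mediated undefined: total effect is 0")
  pm_raw <- pm_from(bt, bd)

  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ix <- sample.int(nrow(records), replace = TRUE)
      tryCatch({
        cf <- fit_pair(records[ix, , drop = FALSE])
        if (cf["total"] == 0) NA_real_ else pm_from(cf["total"], cf["direct"])
      }, error = function(e) NA_real_)
    }, numeric(1))
  })
  failed <- sum(is.na(boot))
  if (failed > 0.05 * n_boot)
    stop_config("%d of %d bootstrap replicates failed to converge", failed, n_boot)
  ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  truncated <- pm_raw < 0
  structure(list(beta_total = bt, beta_direct = bd,
                 pm = if (truncated) 0 else pm_raw,
                 pm_untruncated = pm_raw, pm_ci95 = ci,
                 truncated = truncated, method = "difference",
                 pm_scale = pm_scale,
                 n_boot_used = n_boot - failed, n_boot_failed = failed,
                 fit_total = f_total, fit_direct = f_direct),
            class = "obs_mediation")
}

#' @export
print.obs_mediation <- function(x, ...) {
  cat(sprintf("<obs_mediation> difference method (%s scale): total log HR %.4f, direct %.4f\n",
              x$pm_scale, x$beta_total, x$beta_direct))
  cat(sprintf("  PM = %.1f%%%s, bootstrap 95%% CI [%.1f%%, %.1f%%] (%d reps)\n",
              100 * x$pm, if (x$truncated) " (truncated from < 0)" else "",
              100 * x$pm_ci95[1], 100 * x$pm_ci95[2], x$n_boot_used))
  invisible(x)
}
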