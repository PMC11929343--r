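mr_estimate <- function(method, theta, se, p, k_snps,
                        q = NA_real_, i2 = NA_real_, binary_outcome = FALSE) {
  ci <- theta + c(-1, 1) * stats::qnorm(0.975) * se
  structure(list(method = method, theta = theta, se = se,
                 ci95 = ci, p = p, k_snps = as.integer(k_snps),
                 q = q, i2 = i2,
                 or = if (binary_outcome) exp(theta) else NA_real_,
                 or_ci95 = if (binary_outcome) exp(ci) else c(NA_real_, NA_real_)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: theta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, k = %d\n",
              x$method, x$theta, x$se, x$ci95[1], x$ci95[2], x$p, x$k_snps))
  if (!is.na(x$q))
    cat(sprintf("  Cochran's Q = %.3f, I2 = %.1f%%\n", x$q, 100 * x$i2))
  if (!is.na(x$or))
    cat(sprintf("  OR = %.3f [%.3f, %.3f]\n", x$or, x$or_ci95[1], x$or_ci95[2]))
  invisible(x)
}

ratio_components <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  p <- hset$pairs
  if (nrow(p) == 0) stop_config("harmonized set has no retained SNP pairs")
  if (any(p$beta_exp == 0))
    stop_config("Wald ratio undefined: beta_exp = 0 at %s",
                paste(p$snp_id[p$beta_exp == 0], collapse = ", "))
  list(snp_id = p$snp_id,
       theta = p$beta_out / p$beta_exp,
       se = p$se_out / abs(p$beta_exp))
}

#' Wald ratio for a single SNP
#'
#' The per-SNP causal estimate: the SNP-outcome association divided by the
#' SNP-exposure association, with the first-order standard error
#' `se_out / |beta_exp|` (the SNP-exposure uncertainty is ignored, which
#' is standard when instruments satisfy the F > 10 rule).
#'
#' @param beta_exp,se_exp SNP-exposure association and its SE.
#' @param beta_out,se_out SNP-outcome association and its SE.
#' @param snp_id Optional SNP label.
#' @return List with `snp_id`, `theta`, `se_theta`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out, snp_id = NA_character_) {
  if (beta_exp == 0) stop_config("Wald ratio undefined: beta_exp = 0")
  if (se_out <= 0) stop_config("'se_out' must be positive")
  list(snp_id = snp_id, theta = beta_out / beta_exp,
       se_theta = se_out / abs(beta_exp))
}

#' Inverse-variance weighted estimate
#'
#' Precision-weighted meta-analysis of the per-SNP Wald ratios with
#' weights 1/se_theta^2. The fixed-effect SE is `1/sqrt(sum(w))`; the
#' multiplicative random-effects model inflates it by
#' `max(1, sqrt(Q/(k-1)))` for k >= 2, so heterogeneity can widen but
#' never narrow the interval. With a single SNP both models reduce to the
#' Wald ratio. P-values are two-sided normal.
#'
#' @param hset A `harmonized_set` with k >= 1 retained pairs.
#' @param model `"random"` (multiplicative overdispersion, the default) or
#'   `"fixed"`.
#' @param binary_outcome If `TRUE` the estimate is a log-odds ratio and
#'   the report carries `exp(theta)`.
#' @return An `mr_estimate` with heterogeneity statistics attached
#'   (`q`, `i2`; NA when k = 1).
#' @export
mr_ivw <- function(hset, model = c("random", "fixed"), binary_outcome = FALSE) {
  model <- match.arg(model)
  rc <- ratio_components(hset)
  k <- length(rc$theta)
  w <- 1 / rc$se^2
  theta <- sum(w * rc$theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  if (k >= 2) {
    q <- sum(w * (rc$theta - theta)^2)
    i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
  } else {
    q <- NA_real_; i2 <- NA_real_
  }
  se <- if (model == "random" && k >= 2)
    se_fixed * max(1, sqrt(q / (k - 1))) else se_fixed
  mr_estimate(method = paste0("ivw_", model), theta = theta, se = se,
              p = two_sided_normal_p(theta / se), k_snps = k,
              q = q, i2 = i2, binary_outcome = binary_outcome)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j (theta_j - theta_ivw)^2)` over the Wald ratios, referred
#' to a chi-square with k - 1 degrees of freedom;
#' `I2 = max(0, (Q - (k-1))/Q)` quantifies the fraction of variation
#' beyond chance.
#'
#' @param hset A `harmonized_set` with k >= 2 pairs.
#' @param theta_ivw The IVW point estimate the ratios are referred to; by
#'   default recomputed from `hset`.
#' @return List with `q`, `i2`, `p_het`, `df`.
#' @export
cochran_q <- function(hset, theta_ivw = NULL) {
  rc <- ratio_components(hset)
  k <- length(rc$theta)
  if (k < 2) stop_config("Cochran's Q needs at least 2 SNPs, got %d", k)
  w <- 1 / rc$se^2
  if (is.null(theta_ivw)) theta_ivw <- sum(w * rc$theta) / sum(w)
  q <- sum(w * (rc$theta - theta_ivw)^2)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
  list(q = q, i2 = i2, p_het = stats::pchisq(q, df = k - 1, lower.tail = FALSE),
       df = k - 1L)
}

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  s <- cumsum(w)
  pj <- (s - w / 2) / s[length(s)]
  if (0.5 <= pj[1]) return(theta[1])
  if (0.5 >= pj[length(pj)]) return(theta[length(theta)])
  j <- max(which(pj <= 0.5))
  theta[j] + (theta[j + 1] - theta[j]) * (0.5 - pj[j]) / (pj[j + 1] - pj[j])
}

#' Weighted median estimate
#'
#' Consistent when at least half of the instrument weight comes from
#' valid instruments. The point estimate interpolates the weighted
#' empirical CDF of the ordered Wald ratios at probability 0.5, using
#' cumulative weight fractions `(S_j - w_j/2)/S_k`; the SE comes from a
#' seeded parametric bootstrap that redraws each ratio from
#' `Normal(theta_j, se_j)` while keeping the weights fixed.
#'
#' @param hset A `harmonized_set` with k >= 3 pairs.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param binary_outcome See [mr_ivw()].
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed = 1L,
                               binary_outcome = FALSE) {
  rc <- ratio_components(hset)
  k <- length(rc$theta)
  if (k < 3) stop_config("weighted median needs at least 3 SNPs, got %d", k)
  w <- 1 / rc$se^2
  theta <- weighted_median_point(rc$theta, w)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      weighted_median_point(stats::rnorm(k, rc$theta, rc$se), w)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  mr_estimate("weighted_median", theta, se, two_sided_normal_p(theta / se),
              k, binary_outcome = binary_outcome)
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' MR-Egger regression
#'
#' Weighted least squares of the SNP-outcome associations on the
#' SNP-exposure associations with an unconstrained intercept and weights
#' 1/se_out^2, after orienting every pair so beta_exp >= 0. The slope is
#' the pleiotropy-robust causal estimate (valid under InSIDE); a nonzero
#' intercept signals directional pleiotropy. Both coefficients get
#' t-tests with k - 2 degrees of freedom, with the residual scale bounded
#' below at 1 (multiplicative overdispersion is allowed, underdispersion
#' is not).
#'
#' @param hset A `harmonized_set` with k >= 3 pairs.
#' @param binary_outcome See [mr_ivw()].
#' @return List of class `egger_estimate`: `slope` (an `mr_estimate`),
#'   `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(hset, binary_outcome = FALSE) {
  p <- hset$pairs
  k <- nrow(p)
  if (k < 3) stop_config("MR-Egger needs at least 3 SNPs, got %d", k)
  flip <- p$beta_exp < 0
  bx <- abs(p$beta_exp)
  by <- ifelse(flip, -p$beta_out, p$beta_out)
  if (stats::var(bx) == 0)
    stop_config("MR-Egger undefined: no variance in |beta_exp|")
  w <- 1 / p$se_out^2
  X <- cbind(1, bx)
  xtwx <- crossprod(X, w * X)
  xtwy <- crossprod(X, w * by)
  coefs <- unname(solve(xtwx, xtwy)[, 1])
  resid <- by - X %*% coefs
  sigma2 <- sum(w * resid^2) / (k - 2)
  scale <- max(1, sqrt(sigma2))
  se_unit <- sqrt(diag(solve(xtwx)))
  se <- se_unit * scale
  tstat <- coefs / se
  pvals <- 2 * stats::pt(-abs(tstat), df = k - 2)
  slope <- mr_estimate("egger_slope", coefs[2], se[2], pvals[2], k,
                       binary_outcome = binary_outcome)
  structure(list(slope = slope, intercept = coefs[1],
                 intercept_se = se[1], intercept_p = pvals[1]),
            class = "egger_estimate")
}

#' @export
print.egger_estimate <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n",
              x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}
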