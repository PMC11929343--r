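ivw_slope <- function(bx, by, w) sum(w * bx * by) / sum(w * bx^2)

# leave-one-out IVW slopes for all SNPs at once
loo_slopes <- function(bx, by, w) {
  num <- sum(w * bx * by)
  den <- sum(w * bx^2)
  (num - w * bx * by) / (den - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based horizontal-pleiotropy diagnostic with three parts.
#' The global test compares the observed weighted residual sum of squares
#' of leave-one-out IVW fits against an empirical null in which each
#' SNP-outcome association is redrawn from
#' `Normal(fitted, se_out)`. The per-SNP outlier test compares each
#' observed squared residual with its own simulated null, Bonferroni
#' corrected at `alpha / k`. When outliers are found, the
#' outlier-corrected estimate is the IVW on the remaining SNPs, and a
#' distortion test contrasts the corrected and full estimates against a
#' null built by discarding random same-size SNP subsets. All simulation
#' p-values use the add-one rule `(#exceedances + 1)/(n_sim + 1)`.
#'
#' @param hset A `harmonized_set` with k >= 4 pairs.
#' @param n_sim Number of simulations (default 1000).
#' @param seed Integer seed.
#' @param alpha Significance level for the Bonferroni-corrected outlier
#'   test (default 0.05).
#' @param model IVW variant used for the corrected estimate.
#' @param binary_outcome See [mr_ivw()].
#' @return List of class `presso_result`: `global_rss`, `global_p`,
#'   `outlier_snps`, `outlier_p` (named per-SNP), `corrected`
#'   (`mr_estimate`, present iff outliers were found), `distortion_p`,
#'   `n_sim`, `seed`.
#' @export
mr_presso <- function(hset, n_sim = 1000, seed = 1L, alpha = 0.05,
                      model = "random", binary_outcome = FALSE) {
  p <- hset$pairs
  k <- nrow(p)
  if (k < 4) stop_config("MR-PRESSO needs at least 4 SNPs, got %d", k)
  if (any(p$beta_exp == 0))
    stop_config("Wald ratio undefined: beta_exp = 0 at %s",
                paste(p$snp_id[p$beta_exp == 0], collapse = ", "))
  bx <- p$beta_exp; by <- p$beta_out; se <- p$se_out
  w <- 1 / se^2
  slopes <- loo_slopes(bx, by, w)
  fitted <- slopes * bx
  res2_obs <- w * (by - fitted)^2
  rss_obs <- sum(res2_obs)

  sim <- withr_seed(seed, {
    # redraw outcome associations about the leave-one-out fits, then
    # recompute the whole leave-one-out residual structure per draw
    ysim <- matrix(stats::rnorm(k * n_sim, mean = fitted, sd = se), nrow = k)
    res2_sim <- matrix(NA_real_, k, n_sim)
    rss_sim <- numeric(n_sim)
    for (b in seq_len(n_sim)) {
      yb <- ysim[, b]
      sl <- loo_slopes(bx, yb, w)
      r2 <- w * (yb - sl * bx)^2
      res2_sim[, b] <- r2
      rss_sim[b] <- sum(r2)
    }
    list(res2 = res2_sim, rss = rss_sim)
  })
  global_p <- (sum(sim$rss >= rss_obs) + 1) / (n_sim + 1)
  outlier_p <- (rowSums(sim$res2 >= res2_obs) + 1) / (n_sim + 1)
  names(outlier_p) <- p$snp_id
  outliers <- p$snp_id[outlier_p < alpha / k]

  corrected <- NULL; distortion_p <- NA_real_
  if (length(outliers)) {
    keep <- !(p$snp_id %in% outliers)
    if (sum(keep) < 1)
      stop_config("all SNPs flagged as outliers; no corrected estimate possible")
    sub <- hset
    sub$pairs <- p[keep, , drop = FALSE]
    corrected <- mr_ivw(sub, model = model, binary_outcome = binary_outcome)
    corrected$method <- paste0("presso_corrected_", model)
    theta_full <- ivw_slope(bx, by, w)
    d_obs <- (theta_full - corrected$theta) / abs(corrected$theta)
    n_out <- length(outliers)
    d_null <- withr_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(b) {
        drop_idx <- sample.int(k, n_out)
        th <- ivw_slope(bx[-drop_idx], by[-drop_idx], w[-drop_idx])
        (theta_full - th) / abs(th)
      }, numeric(1))
    })
    distortion_p <- (sum(abs(d_null) >= abs(d_obs)) + 1) / (n_sim + 1)
  }
  structure(list(global_rss = rss_obs, global_p = global_p,
                 outlier_snps = outliers, outlier_p = outlier_p,
                 corrected = corrected, distortion_p = distortion_p,
                 n_sim = as.integer(n_sim), seed = as.integer(seed)),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> global RSS = %.3f, global p = %.4g\n",
              x$global_rss, x$global_p))
  if (length(x$outlier_snps)) {
    cat("  outliers:", paste(x$outlier_snps, collapse = ", "), "\n")
    print(x$corrected)
    cat(sprintf("  distortion p = %.4g\n", x$distortion_p))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}
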