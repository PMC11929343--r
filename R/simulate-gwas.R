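#' Configuration for the synthetic GWAS generator
#'
#' Parameterizes a two-sample (three-sample, with a mediator) summary-MR
#' data-generating process with a known causal chain
#' exposure -> mediator -> outcome plus an optional direct effect and
#' SNP-level horizontal pleiotropy. Defaults emulate a dietary-exposure
#' analysis: 14 exposure instruments at a mean F near 25, a binary
#' (case-control) outcome, and genome-wide-sized but desk-scale samples.
#'
#' @param m_snps Number of SNPs with direct effects on the exposure.
#' @param m_snps_mediator Number of SNPs with direct effects on the
#'   mediator (needed so the mediator has its own instruments; 0 disables
#'   the mediator pathway).
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param n_exposure,n_mediator,n_outcome Sizes of the three
#'   non-overlapping GWAS samples.
#' @param beta_causal_xy Direct exposure -> outcome effect (log-odds per
#'   exposure SD for a binary outcome).
#' @param beta_xm Exposure -> mediator effect (mediator units per
#'   exposure SD).
#' @param beta_my Mediator -> outcome effect.
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct SNP
#'   effects on the outcome; InSIDE holds) or `"directional"` (mean
#'   `pleiotropy_sd`, sd `pleiotropy_sd / 2`; biases IVW but not the
#'   Egger slope).
#' @param pleiotropy_sd Scale of the pleiotropic effects.
#' @param h2_x Exposure variance explained by its instruments, in (0, 1).
#' @param h2_m Mediator variance explained by the mediator's own
#'   instruments.
#' @param outcome_type `"binary"` (logistic single-SNP GWAS, the default)
#'   or `"continuous"`.
#' @param case_fraction Expected case fraction for a binary outcome.
#' @param confounder_sd Loading of the shared confounder on exposure,
#'   mediator and outcome (MR should be immune to it; default 0.3).
#' @param seed Integer seed.
#' @return Object of class `gwas_sim_config`.
#' @export
gwas_sim_config <- function(m_snps = 14, m_snps_mediator = 20,
                            maf_range = c(0.05, 0.5),
                            n_exposure = 20000, n_mediator = 20000,
                            n_outcome = 20000,
                            beta_causal_xy = 0.3, beta_xm = 0.3,
                            beta_my = 0.2,
                            pleiotropy_mode = c("none", "balanced", "directional"),
                            pleiotropy_sd = 0,
                            h2_x = 0.02, h2_m = 0.1,
                            outcome_type = c("binary", "continuous"),
                            case_fraction = 0.1,
                            confounder_sd = 0.3, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_type <- match.arg(outcome_type)
  assert_scalar_number(m_snps, "m_snps", 1, Inf)
  assert_scalar_number(m_snps_mediator, "m_snps_mediator", 0, Inf)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_config("'maf_range' must be an ordered interval within (0, 0.5]")
  m_total <- m_snps + m_snps_mediator
  for (nm in c("n_exposure", "n_mediator", "n_outcome")) {
    n <- get(nm)
    assert_scalar_number(n, nm, 1, Inf)
    if (n <= m_total)
      stop_config("'%s' (%d) must exceed the total SNP count (%d)", nm, n, m_total)
  }
  assert_scalar_number(h2_x, "h2_x", 0, 1, TRUE, TRUE)
  assert_scalar_number(h2_m, "h2_m", 0, 1, TRUE, TRUE)
  assert_scalar_number(pleiotropy_sd, "pleiotropy_sd", 0, Inf)
  assert_scalar_number(case_fraction, "case_fraction", 0, 1, TRUE, TRUE)
  if (h2_x + confounder_sd^2 >= 1)
    stop_config("infeasible h2_x: instrument plus confounder variance reaches 1")
  if (pleiotropy_mode != "none" && pleiotropy_sd <= 0)
    stop_config("'pleiotropy_sd' must be positive when pleiotropy is on")
  structure(list(m_snps = as.integer(m_snps),
                 m_snps_mediator = as.integer(m_snps_mediator),
                 maf_range = as.numeric(maf_range),
                 n_exposure = as.integer(n_exposure),
                 n_mediator = as.integer(n_mediator),
                 n_outcome = as.integer(n_outcome),
                 beta_causal_xy = beta_causal_xy, beta_xm = beta_xm,
                 beta_my = beta_my, pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd, h2_x = h2_x, h2_m = h2_m,
                 outcome_type = outcome_type, case_fraction = case_fraction,
                 confounder_sd = confounder_sd, seed = as.integer(seed)),
            class = "gwas_sim_config")
}

# non-palindromic allele pairs so harmonization never drops simulated SNPs
NONPAL_ALLELE_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                "G", "A", "C", "A", "G", "T", "C", "T"),
                              ncol = 2, byrow = TRUE)

# vectorized single-SNP linear GWAS: one simple regression per column of G
linear_gwas <- function(G, y) {
  n <- length(y)
  gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  sxy <- as.numeric(crossprod(gc, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  sigma2 <- pmax(0, (syy - beta * sxy)) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tstat <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# single-SNP logistic GWAS mimicking a case-control outcome scan
logistic_gwas <- function(G, y) {
  m <- ncol(G)
  beta <- se <- numeric(m)
  for (j in seq_len(m)) {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, G[, j]), y, family = stats::binomial()))
    cf <- fit$coefficients[2]
    # observed-information SE from the final IRLS weights
    X <- cbind(1, G[, j])
    XtWX <- crossprod(X, fit$weights * X)
    se[j] <- sqrt(solve(XtWX)[2, 2])
    beta[j] <- cf
  }
  list(beta = beta, se = se, p = two_sided_normal_p(beta / se))
}

#' Simulate three-sample GWAS summary statistics with known truth
#'
#' Draws three disjoint samples (exposure, mediator, outcome scans) of
#' binomial(2, maf) genotypes over a shared SNP panel, builds phenotypes
#' from the configured causal chain
#' `X = sum(gamma_j G_j) + confounder + noise`,
#' `M = beta_xm X + sum(alpha_h H_h) + confounder + noise`,
#' `Y = beta_causal_xy X + beta_my M + sum(delta_j G_j) + confounder + noise`
#' (logistic link for a binary outcome), and produces per-SNP summary
#' statistics by actually regressing each phenotype on each SNP within
#' its own sample, so the SE and p-value structure (including
#' weak-instrument behaviour) is realistic. Exposure instrument effects
#' `gamma` are equal-magnitude with random sign, scaled so they explain
#' `h2_x` of the exposure variance; likewise `alpha` and `h2_m` for the
#' mediator's own SNPs. Pleiotropic effects `delta` act directly on the
#' outcome. Simulated SNPs are placed on distinct genomic windows with
#' non-palindromic alleles so instrument pruning and harmonization are
#' exercised without stochastic losses.
#'
#' @param config A [gwas_sim_config()].
#' @return List of class `gwas_sim`: `exposure`, `mediator`, `outcome`
#'   (`summary_dataset`s over the full panel), `ld` (independent
#'   `ld_matrix`), and `truth` (all generative parameters plus the
#'   implied total/indirect effects and mediated proportion).
#' @export
simulate_gwas <- function(config) {
  stopifnot(inherits(config, "gwas_sim_config"))
  set.seed(config$seed)
  m_x <- config$m_snps; m_m <- config$m_snps_mediator
  m <- m_x + m_m
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  gvar <- 2 * maf * (1 - maf)
  idx_x <- seq_len(m_x)
  idx_m <- if (m_m > 0) m_x + seq_len(m_m) else integer(0)

  # per-SNP effect magnitudes vary over a 3-fold range (a spread in
  # instrument strength is what identifies the Egger slope), random sign,
  # jointly scaled to the target heritability
  draw_effects <- function(idx, h2) {
    out <- numeric(m)
    u <- stats::runif(length(idx), 0.5, 1.5) *
      sample(c(-1, 1), length(idx), replace = TRUE)
    out[idx] <- u * sqrt(h2 / sum(gvar[idx] * u^2))
    out
  }
  gamma <- draw_effects(idx_x, config$h2_x)
  alpha <- if (m_m > 0) draw_effects(idx_m, config$h2_m) else numeric(m)
  delta <- numeric(m)
  if (config$pleiotropy_mode == "balanced") {
    delta[idx_x] <- stats::rnorm(m_x, 0, config$pleiotropy_sd)
  } else if (config$pleiotropy_mode == "directional") {
    # directional = nonzero mean in the exposure-increasing orientation,
    # so it cannot cancel across instruments with random-sign effects
    delta[idx_x] <- sign(gamma[idx_x]) *
      stats::rnorm(m_x, config$pleiotropy_sd, config$pleiotropy_sd / 2)
  }

  cs <- config$confounder_sd
  sd_ex <- sqrt(1 - config$h2_x - cs^2)
  draw_sample <- function(n) {
    G <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
    U <- stats::rnorm(n)
    X <- as.numeric(G %*% gamma) + cs * U + stats::rnorm(n, sd = sd_ex)
    M <- config$beta_xm * X + as.numeric(G %*% alpha) + cs * U + stats::rnorm(n)
    lp <- config$beta_causal_xy * X + config$beta_my * M +
      as.numeric(G %*% delta) + cs * U
    Y <- if (config$outcome_type == "binary") {
      stats::rbinom(n, 1L, stats::plogis(stats::qlogis(config$case_fraction) + lp))
    } else {
      lp + stats::rnorm(n)
    }
    list(G = G, X = X, M = M, Y = Y)
  }

  snp_ids <- sprintf("rs%05d", seq_len(m))
  chrom <- as.character(rep_len(1:22, m))
  pos <- (seq_len(m) %/% 22 + 1) * 2.1e7 + seq_len(m)
  pair <- NONPAL_ALLELE_PAIRS[sample.int(nrow(NONPAL_ALLELE_PAIRS), m,
                                         replace = TRUE), , drop = FALSE]
  make_dataset <- function(stats_list, eaf, n, label, tag) {
    summary_dataset(data.frame(snp_id = snp_ids, chrom = chrom, pos = pos,
                               effect_allele = pair[, 1],
                               other_allele = pair[, 2],
                               eaf = eaf, beta = stats_list$beta,
                               se = stats_list$se, p = stats_list$p, n = n,
                               stringsAsFactors = FALSE),
                    trait_label = label, sample_overlap_tag = tag)
  }

  s1 <- draw_sample(config$n_exposure)
  exposure <- make_dataset(linear_gwas(s1$G, s1$X), colMeans(s1$G) / 2,
                           config$n_exposure, "exposure", "sample_exposure")
  s2 <- draw_sample(config$n_mediator)
  mediator <- make_dataset(linear_gwas(s2$G, s2$M), colMeans(s2$G) / 2,
                           config$n_mediator, "mediator", "sample_mediator")
  s3 <- draw_sample(config$n_outcome)
  ostats <- if (config$outcome_type == "binary") logistic_gwas(s3$G, s3$Y)
            else linear_gwas(s3$G, s3$Y)
  outcome <- make_dataset(ostats, colMeans(s3$G) / 2,
                          config$n_outcome, "outcome", "sample_outcome")

  indirect <- config$beta_xm * config$beta_my
  total <- config$beta_causal_xy + indirect
  truth <- list(config = config, maf = maf, gamma = gamma, alpha = alpha,
                delta = delta, snp_ids = snp_ids,
                exposure_snps = snp_ids[idx_x],
                mediator_snps = snp_ids[idx_m],
                total_effect = total, indirect_effect = indirect,
                pm = if (total != 0) indirect / total else NA_real_)
  structure(list(exposure = exposure, mediator = mediator, outcome = outcome,
                 ld = independent_ld(exposure), truth = truth),
            class = "gwas_sim")
}
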