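test_that("Wald ratio follows the defining formula and rejects a null exposure", {
  w <- wald_ratio(beta_exp = 0.1, se_exp = 0.02, beta_out = 0.05, se_out = 0.02)
  expect_equal(w$theta, 0.5)
  expect_equal(w$se_theta, 0.2)
  expect_equal(wald_ratio(0.1, 0.02, 0, 0.02)$theta, 0)
  # negative exposure beta: ratio flips, SE uses |beta_exp|
  expect_equal(wald_ratio(-0.1, 0.02, 0.05, 0.02)$theta, -0.5)
  expect_equal(wald_ratio(-0.1, 0.02, 0.05, 0.02)$se_theta, 0.2)
  expect_error(wald_ratio(0, 0.02, 0.05, 0.02), "beta_exp")
})

test_that("IVW is the precision-weighted mean with correct degenerate cases", {
  # single SNP: IVW collapses to the Wald ratio exactly
  h1 <- harmonized_set("a", 0.1, 0.01, 0.05, 0.02)
  iv1 <- mr_ivw(h1, "random")
  expect_equal(iv1$theta, 0.5)
  expect_equal(iv1$se, 0.2)
  expect_true(is.na(iv1$q))
  # hand-weighted three-SNP instance: w = 100, 25, 100
  h3 <- harmonized_set(c("a", "b", "c"), rep(1, 3), rep(0.01, 3),
                       c(0.40, 0.55, 0.70), c(0.10, 0.20, 0.10))
  ivf <- mr_ivw(h3, "fixed")
  expect_equal(ivf$theta, 0.55, tolerance = 1e-12)
  expect_equal(ivf$se, 1 / sqrt(225), tolerance = 1e-12)
  # two identical ratios: the estimate is that value whatever the SEs
  h2 <- harmonized_set(c("a", "b"), c(0.1, 0.2), c(0.01, 0.01),
                       c(0.07, 0.14), c(0.01, 0.05))
  expect_equal(mr_ivw(h2)$theta, 0.7, tolerance = 1e-12)
  expect_error(mr_ivw(harmonized_set("a", 0, 0.01, 0.1, 0.1)), "beta_exp")
})

test_that("fixed-effect IVW equals origin-constrained WLS on random instances", {
  for (seed in 1:10) {
    h <- random_hset(sample(4:30, 1), seed = 100 + seed)
    iv <- mr_ivw(h, "fixed")
    w <- 1 / h$pairs$se_out^2
    beta_wls <- sum(w * h$pairs$beta_exp * h$pairs$beta_out) /
      sum(w * h$pairs$beta_exp^2)
    expect_equal(iv$theta, beta_wls, tolerance = 1e-10)
  }
})

test_that("IVW point estimate is invariant to rescaling all outcome SEs", {
  h <- random_hset(12, seed = 5)
  base <- mr_ivw(h, "fixed")
  h$pairs$se_out <- h$pairs$se_out * 3.7
  scaled <- mr_ivw(h, "fixed")
  expect_equal(scaled$theta, base$theta, tolerance = 1e-12)
  expect_equal(scaled$se, base$se * 3.7, tolerance = 1e-12)
})

test_that("Cochran's Q and I2 behave per definition", {
  h3 <- harmonized_set(c("a", "b", "c"), rep(1, 3), rep(0.01, 3),
                       c(0.40, 0.55, 0.70), c(0.10, 0.20, 0.10))
  q <- cochran_q(h3)
  expect_equal(q$q, 4.5, tolerance = 1e-12)       # 100*.15^2 + 0 + 100*.15^2
  expect_equal(q$i2, 1 - 2 / 4.5, tolerance = 1e-12)
  expect_equal(q$df, 2L)
  # identical ratios: no heterogeneity at all
  hid <- harmonized_set(c("a", "b"), c(0.1, 0.2), c(0.01, 0.01),
                        c(0.05, 0.10), c(0.02, 0.03))
  expect_equal(cochran_q(hid)$q, 0, tolerance = 1e-20)
  expect_equal(cochran_q(hid)$i2, 0)
  # q below its degrees of freedom truncates I2 at zero
  hsmall <- harmonized_set(c("a", "b", "c"), rep(1, 3), rep(0.01, 3),
                           c(0.499, 0.5, 0.501), rep(0.1, 3))
  expect_equal(cochran_q(hsmall)$i2, 0)
  expect_error(cochran_q(harmonized_set("a", 1, 0.01, 0.5, 0.1)), "at least 2")
  # permutation invariance
  h <- random_hset(9, seed = 3)
  qa <- cochran_q(h)
  h$pairs <- h$pairs[sample(nrow(h$pairs)), ]
  expect_equal(cochran_q(h)$q, qa$q, tolerance = 1e-12)
})

test_that("weighted median interpolates the weighted CDF and is reproducible", {
  # equal weights: the ordinary median
  heq <- harmonized_set(c("a", "b", "c"), rep(1, 3), rep(0.01, 3),
                        c(0.1, 0.2, 0.3), rep(1, 3))
  expect_equal(mr_weighted_median(heq, n_boot = 10, seed = 1)$theta, 0.2)
  # weights 1, 1, 2: hand interpolation of the weighted CDF gives 0.2333...
  hw <- harmonized_set(c("a", "b", "c"), rep(1, 3), rep(0.01, 3),
                       c(0.1, 0.2, 0.3), c(1, 1, 1 / sqrt(2)))
  expect_equal(mr_weighted_median(hw, n_boot = 10, seed = 1)$theta,
               0.2 + 0.125 / 0.375 * 0.1, tolerance = 1e-12)
  # same seed, same bootstrap SE; different seed differs
  a <- mr_weighted_median(hw, n_boot = 200, seed = 7)
  b <- mr_weighted_median(hw, n_boot = 200, seed = 7)
  expect_identical(a$se, b$se)
  expect_error(mr_weighted_median(harmonized_set(c("a", "b"), c(1, 1),
                                                 c(0.01, 0.01), c(0.1, 0.2),
                                                 c(1, 1))),
               "at least 3")
  # estimate always lies within the range of the ratios
  for (seed in 1:8) {
    h <- random_hset(sample(3:15, 1), seed = 200 + seed)
    est <- mr_weighted_median(h, n_boot = 10, seed = 1)$theta
    r <- h$pairs$beta_out / h$pairs$beta_exp
    expect_gte(est, min(r)); expect_lte(est, max(r))
  }
})

test_that("MR-Egger matches the normal-equations oracle and exact lines", {
  # exactly proportional data: slope recovered exactly, intercept zero
  hline <- harmonized_set(sprintf("s%d", 1:4), c(0.05, 0.1, 0.15, 0.2),
                          rep(0.01, 4), 2 * c(0.05, 0.1, 0.15, 0.2),
                          c(0.02, 0.03, 0.02, 0.04))
  e <- mr_egger(hline)
  expect_equal(e$slope$theta, 2, tolerance = 1e-10)
  expect_equal(e$intercept, 0, tolerance = 1e-10)
  # random 5-SNP instances against a direct normal-equations solve
  for (seed in 1:8) {
    h <- random_hset(5, seed = 300 + seed)
    e <- mr_egger(h)
    flip <- h$pairs$beta_exp < 0
    bx <- abs(h$pairs$beta_exp)
    by <- ifelse(flip, -h$pairs$beta_out, h$pairs$beta_out)
    cf <- wls_oracle(cbind(1, bx), by, 1 / h$pairs$se_out^2)
    expect_equal(e$intercept, cf[1], tolerance = 1e-10)
    expect_equal(e$slope$theta, cf[2], tolerance = 1e-10)
  }
  # orientation invariance: pre-flipping a pair changes nothing
  h <- random_hset(6, seed = 42)
  e1 <- mr_egger(h)
  h$pairs$beta_exp[2] <- -h$pairs$beta_exp[2]
  h$pairs$beta_out[2] <- -h$pairs$beta_out[2]
  e2 <- mr_egger(h)
  expect_equal(e1$slope$theta, e2$slope$theta, tolerance = 1e-12)
  expect_equal(e1$intercept, e2$intercept, tolerance = 1e-12)
  expect_error(mr_egger(harmonized_set(c("a", "b"), c(1, 1), c(0.01, 0.01),
                                       c(0.1, 0.2), c(1, 1))),
               "at least 3")
})

test_that("MR-PRESSO flags a planted outlier and stays quiet on clean data", {
  sim <- simulate_gwas(gwas_sim_config(m_snps = 12, m_snps_mediator = 0,
    n_exposure = 4000, n_mediator = 200, n_outcome = 4000,
    beta_causal_xy = 0.3, beta_xm = 0, beta_my = 0, h2_x = 0.15,
    outcome_type = "continuous", seed = 61))
  h <- harmonize(sim$exposure, sim$outcome,
                 select_instruments(sim$exposure, 5e-6))
  clean <- mr_ivw(h)
  # clean data: no outliers across several diagnostic seeds, and the
  # absent-outlier contract (no corrected estimate) holds
  for (s in 1:5) {
    pr0 <- mr_presso(h, n_sim = 400, seed = s)
    expect_length(pr0$outlier_snps, 0)
    expect_null(pr0$corrected)
    expect_true(is.na(pr0$distortion_p))
  }
  # plant one SNP at 10x the causal slope: flagged, global test fires,
  # and the corrected estimate returns to within 2 SE of the clean IVW
  hp <- h
  j <- which.min(abs(hp$pairs$beta_exp))
  hp$pairs$beta_out[j] <- 10 * clean$theta * hp$pairs$beta_exp[j]
  pr <- mr_presso(hp, n_sim = 400, seed = 1)
  expect_true(hp$pairs$snp_id[j] %in% pr$outlier_snps)
  expect_lt(pr$global_p, 0.05)
  expect_false(is.null(pr$corrected))
  expect_lt(abs(pr$corrected$theta - clean$theta), 2 * clean$se)
  expect_error(mr_presso(harmonized_set(c("a", "b", "c"), rep(1, 3),
                                        rep(0.01, 3), 1:3 / 10, rep(1, 3))),
               "at least 4")
})

test_that("the univariable pipeline orchestrates all estimators", {
  sim <- simulate_gwas(gwas_sim_config(m_snps = 10, m_snps_mediator = 0,
    n_exposure = 6000, n_mediator = 200, n_outcome = 6000,
    beta_causal_xy = 0.4, beta_xm = 0, beta_my = 0, h2_x = 0.15,
    outcome_type = "binary", case_fraction = 0.2, seed = 17))
  cfg <- pipeline_config(p_threshold = 5e-6, n_boot = 100, n_presso_sim = 100)
  rep1 <- run_univariable_mr(sim$exposure, sim$outcome, sim$ld, cfg,
                             binary_outcome = TRUE)
  expect_s3_class(rep1, "mr_report")
  methods <- rep1$estimates$method
  expect_true(all(c("ivw_random", "ivw_fixed", "weighted_median",
                    "egger_slope") %in% methods))
  # binary outcome: the report carries odds ratios exp(theta)
  expect_equal(rep1$estimates$or, exp(rep1$estimates$theta))
  expect_false(any(is.na(rep1$per_snp$loo_estimate)))
  # deterministic given the config seed
  rep2 <- run_univariable_mr(sim$exposure, sim$outcome, sim$ld, cfg)
  expect_equal(rep1$estimates, rep2$estimates, tolerance = 1e-15)
})

test_that("a single surviving instrument yields the degenerate Wald-only path", {
  ex <- make_dataset(c("rs1", "rs2"), p = c(1e-9, 1e-3),
                     beta = c(0.12, 0.01), se = c(0.01, 0.01))
  out <- make_dataset(c("rs1", "rs2"), p = c(0.5, 0.5),
                      beta = c(0.06, 0.001), se = c(0.02, 0.02))
  rep1 <- run_univariable_mr(ex, out, independent_ld(ex),
                             pipeline_config(), binary_outcome = FALSE)
  expect_equal(rep1$estimates$method[1], "wald_ivw")
  expect_false("weighted_median" %in% rep1$estimates$method)
  expect_false("egger_slope" %in% rep1$estimates$method)
  expect_true(all(is.na(rep1$estimates$q)))
  expect_equal(rep1$estimates$theta[1], 0.5, tolerance = 1e-12)
  expect_null(rep1$presso)
})

test_that("IVW p-values are uniform under the causal null", {
  ps <- vapply(1:200, function(r) {
    sim <- simulate_gwas(gwas_sim_config(m_snps = 10, m_snps_mediator = 0,
      n_exposure = 6000, n_mediator = 200, n_outcome = 6000,
      beta_causal_xy = 0, beta_xm = 0, beta_my = 0, h2_x = 0.1,
      outcome_type = "continuous", seed = 7000 + r))
    rep1 <- run_univariable_mr(sim$exposure, sim$outcome, sim$ld,
      pipeline_config(p_threshold = 5e-6, n_boot = 50, n_presso_sim = 50),
      binary_outcome = FALSE)
    rep1$estimates$p[rep1$estimates$method == "ivw_fixed"]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
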