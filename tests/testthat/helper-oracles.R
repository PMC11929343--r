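# Independent oracles the implementation is checked against. These are
# deliberately written as direct transcriptions of the defining formulas
# (grid searches, normal equations, exhaustive greedy passes), sharing no
# code with the package internals.

# Efron partial log-likelihood for a single covariate
efron_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(exp(beta * x[D]))
    sumR <- sum(exp(beta * x[R]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sumR - (l / d) * sumD)
  }
  ll
}

# 1-D grid/golden-section maximizer of the Efron partial likelihood
cox_grid_oracle <- function(time, event, x, interval = c(-8, 8)) {
  stats::optimize(function(b) -efron_partial_loglik(b, time, event, x),
                  interval = interval, tol = 1e-10)$minimum
}

# weighted least squares by explicit normal equations
wls_oracle <- function(X, y, w) {
  unname(solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1])
}

# greedy clumping oracle: explicit loop, smallest p first
clump_oracle <- function(snp, p, chrom, pos, r2, r2_threshold, window_kb) {
  pool <- order(p, snp)
  kept <- integer(0)
  while (length(pool)) {
    i <- pool[1]
    kept <- c(kept, i)
    keep_in_pool <- vapply(pool, function(j) {
      if (j == i) return(FALSE)
      !(chrom[j] == chrom[i] &&
          abs(pos[j] - pos[i]) <= window_kb * 1000 &&
          r2[i, j] >= r2_threshold)
    }, logical(1))
    pool <- pool[keep_in_pool]
  }
  sort(snp[kept])
}

# random summary-MR instance on k SNPs (pre-aligned alleles)
random_hset <- function(k, seed, theta = 0.5) {
  set.seed(seed)
  bx <- stats::runif(k, 0.05, 0.3) * sample(c(-1, 1), k, TRUE)
  sx <- stats::runif(k, 0.005, 0.02)
  sy <- stats::runif(k, 0.01, 0.05)
  by <- theta * bx + stats::rnorm(k, 0, sy)
  harmonized_set(sprintf("snp%02d", seq_len(k)), bx, sx, by, sy)
}

# small summary dataset builder for instrument-level tests
make_dataset <- function(snp_id, p, beta = NULL, se = NULL,
                         chrom = NULL, pos = NULL,
                         ea = "A", oa = "G", eaf = 0.3,
                         trait = "trait") {
  k <- length(snp_id)
  if (is.null(se)) se <- rep(0.01, k)
  if (is.null(beta)) beta <- abs(stats::qnorm(p / 2)) * se
  summary_dataset(data.frame(
    snp_id = snp_id, chrom = chrom %||% rep("1", k),
    pos = pos %||% seq_len(k) * 3e7,
    effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
    eaf = rep_len(eaf, k), beta = beta, se = se, p = p,
    n = 10000, stringsAsFactors = FALSE), trait_label = trait)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# survival cohort under exact proportional hazards (exponential baseline)
sim_ph_cohort <- function(n, beta, seed, rate = 0.15, censor = 10) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, 0.5)
  T <- stats::rexp(n, rate * exp(beta * x))
  data.frame(time = pmin(T, censor), event = as.integer(T <= censor), x = x)
}

# cohort whose exposure effect reverses sign at t0 (PH violated)
sim_reversal_cohort <- function(n, seed, b = 0.8, t0 = 3, rate = 0.15,
                                censor = 10) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, 0.5)
  e1 <- stats::rexp(n, rate * exp(b * x))
  T <- ifelse(e1 < t0, e1, t0 + stats::rexp(n, rate * exp(-b * x)))
  data.frame(time = pmin(T, censor), event = as.integer(T <= censor), x = x)
}

# paired exposure/outcome datasets from a compact allele/effect table
make_pair_datasets <- function(out_tab) {
  exp_tab <- data.frame(snp_id = out_tab$snp_id, chrom = "1",
                        pos = seq_len(nrow(out_tab)) * 3e7,
                        effect_allele = out_tab$ea_x, other_allele = out_tab$oa_x,
                        eaf = out_tab$eaf_x, beta = out_tab$bx, se = 0.01,
                        p = 1e-10, n = 1e5, stringsAsFactors = FALSE)
  out <- data.frame(snp_id = out_tab$snp_id, chrom = "1",
                    pos = seq_len(nrow(out_tab)) * 3e7,
                    effect_allele = out_tab$ea_y, other_allele = out_tab$oa_y,
                    eaf = out_tab$eaf_y, beta = out_tab$by, se = 0.02,
                    p = NA, n = 1e5, stringsAsFactors = FALSE)
  list(exposure = summary_dataset(exp_tab, "exp"),
       outcome = summary_dataset(out, "out"))
}
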