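---
title: "Triangulating a dietary exposure and disease risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating a dietary exposure and disease risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mrmediate` implements a triangulated epidemiological analysis: the same
exposure–outcome question is asked of two very different study designs, a
two-sample Mendelian randomization (MR) analysis of GWAS summary statistics
and a prospective survival cohort, each with its own mediation analysis.
The motivating application is a beverage exposure (sugar-sweetened drinks)
and breast-cancer incidence, with anthropometric and metabolic biomarkers
(BMI, uric acid, lipid fractions) as candidate mediators, but every stage
is generic: any trait with GWAS summary statistics and any cohort with a
time-to-event outcome fits the same interfaces.

# The Mendelian randomization arm

## Model and assumptions

For SNP $j$, let $\hat\beta_{Xj}$ and $\hat\beta_{Yj}$ be its estimated
associations with exposure and outcome in two *non-overlapping* samples.
Under the instrumental-variable assumptions (relevance, independence from
confounders, and no effect on the outcome except through the exposure),
each SNP gives a Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order standard
error $se_j = se_{Yj}/|\hat\beta_{Xj}|$. The first-order SE ignores the
exposure-side uncertainty; this is the standard choice when instruments
satisfy the $F > 10$ rule, and the package reports the mean F-statistic
$(\hat\beta_{Xj}/se_{Xj})^2$ so the user can see when it is strained.

Estimators on the harmonized ratios:

* **IVW** — weights $w_j = se_j^{-2}$; fixed-effect SE
  $(\sum w_j)^{-1/2}$; the primary *multiplicative random-effects* model
  inflates this by $\max\!\big(1, \sqrt{Q/(k-1)}\big)$. Multiplicative
  overdispersion was chosen over additive because it is the standard for
  summary-data MR, leaves the point estimate unchanged, and never rewards
  heterogeneity with a narrower interval; both variants are exposed.
* **Cochran's Q / $I^2$** — $Q = \sum w_j(\hat\theta_j - \hat\theta)^2$
  against $\chi^2_{k-1}$, $I^2 = \max(0, (Q-(k-1))/Q)$.
* **Weighted median** — linear interpolation of the weighted empirical
  CDF $p_j = (S_j - w_j/2)/S_k$ at 0.5; SE from a seeded parametric
  bootstrap redrawing each ratio from $N(\hat\theta_j, se_j)$.
* **MR-Egger** — WLS of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with free
  intercept, weights $se_{Yj}^{-2}$, pairs pre-oriented so
  $\hat\beta_{Xj} \ge 0$. Coefficient tests use $t_{k-2}$ with the
  residual scale bounded below at 1. No measurement-error (NOME)
  correction is applied; instead the mean F is reported.
* **MR-PRESSO** — leave-one-out IVW residual sum of squares compared with
  a simulated null (outcome betas redrawn about their leave-one-out
  fits), per-SNP outlier tests Bonferroni-corrected at $\alpha/k$, an
  outlier-corrected IVW, and a permutation-style distortion test.
  Defaults: 1000 simulations, $\alpha = 0.05$, add-one p-values.

## Instrument processing

Selection keeps SNPs with $p$ *strictly* below the threshold
($5\times10^{-8}$ by default; dietary exposures with few genome-wide hits
conventionally use $5\times10^{-6}$, passed per-exposure). Clumping is the
de-facto greedy algorithm — keep the smallest-p SNP, discard neighbours
with $r^2 \ge 0.001$ within $\pm$10,000 kb, repeat — with ties broken by
SNP id so the result is reproducible and order-independent.

Harmonization re-expresses the outcome association on the exposure's
effect allele: label swaps negate the beta and mirror the frequency,
strand complements are resolved then re-checked. Palindromic SNPs (A/T,
C/G) cannot be resolved from labels; if either frequency is missing or
inside the 0.42–0.58 ambiguity band they are dropped (reason
`ambiguous_palindrome`), otherwise frequency concordance decides the
orientation. Drops are recorded per SNP, never silently.

## Two-step mediation

The total effect $\hat\theta_T$ (exposure→outcome IVW), step 1
$\hat\theta_1$ (exposure→mediator, exposure instruments) and step 2
$\hat\theta_2$ (mediator→outcome, the *mediator's own* instruments) give
the product-of-coefficients indirect effect
$\hat\theta_1\hat\theta_2$ with delta-method SE
$\sqrt{\hat\theta_2^2 se_1^2 + \hat\theta_1^2 se_2^2}$ — cross-step
covariances are zero by the three-sample design. The proportion mediated
is $PM = \hat\theta_1\hat\theta_2/\hat\theta_T$ on the log-odds scale for
binary outcomes, with a first-order delta CI. Negative PM is reported as
0% with an explicit flag; the CI is deliberately left untruncated because
truncating an interval at a boundary the point estimate was clipped to
would overstate certainty. A mediator qualifies for reporting when both
steps are nominally significant ($p < \alpha$ by IVW); non-qualifying and
unevaluable candidates are returned with diagnostics rather than hidden.
Whether the PM denominator uses the raw or the MR-PRESSO outlier-corrected
total effect is genuinely open in this design; the raw IVW is the default
and `use_corrected_total = TRUE` switches, which matters exactly when the
total effect itself is contaminated by outlying loci.

# The observational arm

Cox proportional-hazards models (Efron tie handling, via the `survival`
package) estimate crude and adjusted hazard ratios for the exposure
categories against the lowest-consumption reference, with the
proportional-hazards assumption checked by the scaled Schoenfeld residual
test against event-time rank. Person-years, incidence rates per 1000
person-years, and mean follow-up are tabulated per exposure group.
Candidate mediators are screened by OLS of the biomarker on the exposure
contrasts plus covariates; rank deficiency is an error naming the
collinear terms, because a silently dropped adjustment variable is worse
than a refusal.

Mediation uses the difference method: $PM = (\beta_{total} -
\beta_{direct})/\beta_{total}$, comparing the exposure log hazard ratio
without and with the mediator. The closed-form variance of the classic
implementation of this estimator depends on a covariance expression that
is not identifiable from the two fits alone, so the CI here is a
subject-level nonparametric bootstrap of the whole two-model procedure
(default 500 replicates, percentile interval, seeded); replicates whose
fits fail are dropped and counted, and more than 5% failures is an error.
The alternative hazard-ratio-scale definition
$(HR_t - HR_d)/(HR_t - 1)$ is available via `pm_scale = "hr"`. The same
truncate-at-zero-with-flag policy applies as in the MR arm.

# The synthetic-data generators

Both generators exist so that every stage can be validated against known
truth; they are first-class, tested code.

**GWAS generator** (`simulate_gwas`): three disjoint samples of
`rbinom(2, maf)` genotypes over a shared panel; exposure, mediator and
outcome phenotypes built from the causal chain
$X \to M \to Y$ with a direct $X \to Y$ path, a shared confounder loading
on all three (MR must be immune to it), and optional SNP-level direct
effects on the outcome (balanced: zero-mean; directional: nonzero mean in
the exposure-increasing orientation, which is what makes it
non-cancelling). Summary statistics come from actually running one
regression per SNP in the appropriate sample — linear, or logistic for
the case-control outcome — so SE/p structure, winner's curse and
weak-instrument behaviour are all real rather than assumed. Per-SNP
effect magnitudes vary over a three-fold range with random sign, jointly
scaled to the target heritability: a spread in instrument strength is
required for the MR-Egger slope to be identified at all (with
equal-magnitude effects the exposure betas have no signal variance and
the intercept absorbs everything). The mediator carries its own
instrument set (`m_snps_mediator`, `h2_m`); without it the only
instruments for $M$ would act through $X$ and the second mediation step
would be unidentified. Simulated SNPs are placed on distinct genomic
windows with non-palindromic alleles, so pruning and harmonization are
exercised without stochastic instrument loss; palindrome handling is
tested on explicit fixtures instead.

Defaults emulate the dietary-exposure setting: 14 exposure instruments,
20 mediator instruments, samples of 20,000, a binary outcome, and
exposure heritability giving mean F in the 25–45 range. What the
generator deliberately does *not* model: linkage disequilibrium between
panel SNPs (an explicit r² matrix can be supplied to exercise clumping),
sample overlap between the three GWAS, and assortative or population
structure. Passing tests therefore demonstrate correctness of the
estimators under the two-sample assumptions, not robustness to their
violation in real data.

**Cohort generator** (`simulate_cohort`): Weibull proportional-hazards
event times with linear predictor
$\log(hr_{direct})\,E + b\,M + \text{confounders}$, mediator
$M = a\,E + \text{confounders} + \varepsilon$, exposure propensity mildly
dependent on the first confounder (so crude and adjusted estimates
differ), and administrative censoring. Defaults reproduce the motivating
cohort's shape: 13,567 subjects, 11% exposed, censoring at 14.8 years,
baseline scale 900 years (about 1.2 events per 1000 person-years,
roughly 250 events per run), 16 confounders, and mediation parameters
$a = b = 0.3$ with $hr_{direct} = 1.44$, i.e. a total HR near 1.58 with
about a fifth of the log-hazard effect mediated.

# Numerical choices and degenerate inputs

* P-values absent from an input table are reconstructed as the two-sided
  normal tail of $\hat\beta/se$; the reconstruction is sign-symmetric.
* A single retained instrument collapses the pipeline to the Wald/IVW
  row with heterogeneity and pleiotropy diagnostics marked unavailable
  (they need $k \ge 2$, 3, 3, 4 respectively); $\hat\beta_X = 0$ is an
  error, not an infinite ratio.
* Cochran's $I^2$ truncates at zero when $Q < k-1$; all simulation
  p-values use the add-one rule so they are never exactly zero.
* Cox separation (monotone partial likelihood) is detected and reported
  as an error naming the term; the fitter's convergence tolerances are
  those of `survival::coxph`.
* Clumping tie-breaks on SNP id; every stochastic routine takes an
  explicit seed and records it.

# Validation scales

The test suite validates against independent oracles (grid-search Efron
partial likelihood, direct normal-equations solves, an exhaustive greedy
clumping re-implementation) and Monte-Carlo operating characteristics.
The simulation checks use deliberately chosen problem sizes: IVW bias
and coverage at $n = 50{,}000$, $k = 50$, 100 replicates; Egger-intercept
calibration at $n = 4{,}000$, $k = 30$, 500 replicates with strong
instruments (the intercept $t$-test is a large-F procedure — near the
selection threshold winner's curse visibly distorts it, which is a
property of the method, not the implementation); outlier detection over
100 replicates with the contaminant planted on a low-leverage instrument
(planting on a dominant-weight instrument makes *every* leave-one-out
fit look outlying — a real and documented failure mode of the residual
approach); and mediated-proportion recovery at $n = 20{,}000$ per sample
with a true mediated fraction of 25%, cross-checked between the two arms
under a shared rare-outcome generative model.

# Known limitations

Multivariable MR, Steiger filtering, contamination-mixture and mode-based
estimators are out of scope, as are competing-risks (Fine–Gray) models,
LD estimation from reference panels, proxy-SNP lookup, and any handling
of overlapping GWAS samples. PM values above 100% are reported as
computed (only negative truncation is defined). The difference-method CI
is a bootstrap, not the closed-form macro variance some historical
analyses used; the two agree asymptotically but not replicate-by-replicate.
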