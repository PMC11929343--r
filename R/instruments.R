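#' Select genetic instruments by p-value threshold
#'
#' Returns the SNPs associated with the trait at p strictly below the
#' threshold. A SNP with p exactly equal to the threshold is excluded.
#'
#' @param dataset A `summary_dataset`.
#' @param p_threshold Significance threshold (e.g. 5e-8, or 5e-6 for
#'   dietary traits with few genome-wide hits).
#' @return Character vector of SNP ids (possibly empty, with a warning).
#' @export
select_instruments <- function(dataset, p_threshold) {
  stopifnot(inherits(dataset, "summary_dataset"))
  if (nrow(dataset$records) == 0) stop_config("dataset is empty")
  assert_scalar_number(p_threshold, "p_threshold", 0, 1, TRUE, FALSE)
  keep <- dataset$records$snp_id[dataset$records$p < p_threshold]
  if (length(keep) == 0)
    warning(sprintf("no SNP passes p < %g for trait '%s'",
                    p_threshold, dataset$trait_label))
  keep
}

#' Greedy LD clumping
#'
#' Prunes a SNP set so no two retained SNPs on the same chromosome within
#' `window_kb` of each other have r^2 at or above `r2_threshold`. The
#' algorithm is the standard greedy one: repeatedly keep the remaining SNP
#' with the smallest p-value (the index SNP) and discard all SNPs
#' correlated with it within the window. The result does not depend on the
#' input order of `snps` (p-value ties are broken by SNP id for
#' determinism).
#'
#' @param snps Character vector of candidate SNP ids.
#' @param dataset `summary_dataset` supplying the p-values.
#' @param ld An `ld_matrix` covering all candidates.
#' @param r2_threshold Discard at r^2 >= this value (default 0.001).
#' @param window_kb Window half-width in kb around the index SNP
#'   (default 10,000).
#' @return Character vector of retained (index) SNP ids.
#' @export
clump <- function(snps, dataset, ld, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(dataset, "summary_dataset"), inherits(ld, "ld_matrix"))
  snps <- as.character(snps)
  if (length(snps) == 0) return(character(0))
  missing_ld <- setdiff(snps, ld$snp_ids)
  if (length(missing_ld))
    stop_config("SNP(s) absent from the LD matrix: %s",
                paste(missing_ld, collapse = ", "))
  rec <- dataset$records
  missing_ds <- setdiff(snps, rec$snp_id)
  if (length(missing_ds))
    stop_config("SNP(s) absent from the dataset: %s",
                paste(missing_ds, collapse = ", "))
  idx <- match(snps, rec$snp_id)
  p <- rec$p[idx]
  pos <- ld$positions[match(snps, ld$positions$snp_id), ]
  ord <- order(p, snps)   # deterministic tie-break on id
  remaining <- snps[ord]
  pvec <- stats::setNames(p[ord], remaining)
  chrom <- stats::setNames(as.character(pos$chrom[ord]), remaining)
  bp <- stats::setNames(pos$pos[ord], remaining)
  kept <- character(0)
  while (length(remaining)) {
    index <- remaining[1]
    kept <- c(kept, index)
    same_chr <- chrom[remaining] == chrom[index]
    in_window <- abs(bp[remaining] - bp[index]) <= window_kb * 1000
    r2 <- ld$r2[index, remaining]
    drop <- same_chr & in_window & r2 >= r2_threshold
    drop[1] <- TRUE  # the index SNP itself leaves the pool
    remaining <- remaining[!drop]
  }
  sort(kept)
}

#' Instrument strength via the F-statistic
#'
#' Per-SNP F is the squared z-score (beta/se)^2; the headline figure is
#' the arithmetic mean across instruments, with mean F <= 10 flagged as a
#' weak-instrument warning sign.
#'
#' @param dataset A `summary_dataset`.
#' @param snps Non-empty character vector of instrument ids.
#' @return List with `per_snp_f` (named), `mean_f` and logical `weak`.
#' @export
instrument_strength <- function(dataset, snps) {
  stopifnot(inherits(dataset, "summary_dataset"))
  snps <- as.character(snps)
  if (length(snps) == 0) stop_config("'snps' must be non-empty")
  rec <- dataset$records
  idx <- match(snps, rec$snp_id)
  if (anyNA(idx))
    stop_config("SNP(s) absent from the dataset: %s",
                paste(snps[is.na(idx)], collapse = ", "))
  f <- (rec$beta[idx] / rec$se[idx])^2
  names(f) <- snps
  list(per_snp_f = f, mean_f = mean(f), weak = mean(f) <= 10)
}

#' Harmonize exposure and outcome effect alleles
#'
#' Puts the SNP-outcome association on the exposure's effect allele.
#' Swapped alleles negate the outcome beta and mirror its frequency;
#' strand complements are resolved and re-checked. Palindromic SNPs (A/T
#' or C/G) whose effect-allele frequency is missing or falls inside the
#' ambiguity band in either dataset are dropped with reason
#' `ambiguous_palindrome`; outside the band, frequency alignment is
#' trusted (betas are flipped when the two frequencies sit on opposite
#' sides of 0.5). Irreconcilable allele pairs are dropped with reason
#' `allele_mismatch`. Drops are recorded, never raised.
#'
#' @param exposure,outcome `summary_dataset`s sharing the SNPs in `snps`.
#' @param snps Character vector of instrument ids present in both.
#' @param palindromic_band Frequency ambiguity band, default `c(0.42, 0.58)`.
#' @return Object of class `harmonized_set` with elements `pairs` (data
#'   frame: snp_id, beta_exp, se_exp, beta_out, se_out, eaf_exp, eaf_out)
#'   and `dropped` (data frame: snp_id, reason).
#' @export
harmonize <- function(exposure, outcome, snps,
                      palindromic_band = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  snps <- as.character(snps)
  ex <- exposure$records
  ou <- outcome$records
  iex <- match(snps, ex$snp_id)
  iou <- match(snps, ou$snp_id)
  if (anyNA(iex) || anyNA(iou))
    stop_config("SNP(s) absent from exposure or outcome dataset: %s",
                paste(snps[is.na(iex) | is.na(iou)], collapse = ", "))
  pairs <- list(); dropped <- list()
  for (j in seq_along(snps)) {
    e <- ex[iex[j], ]; o <- ou[iou[j], ]
    ea_x <- e$effect_allele; oa_x <- e$other_allele
    ea_y <- o$effect_allele; oa_y <- o$other_allele
    beta_out <- o$beta; eaf_out <- o$eaf
    pal <- is_palindromic(ea_x, oa_x)
    if (pal) {
      # strand is unknowable from alleles alone; decide on frequency
      band_or_na <- function(f) is.na(f) ||
        (f >= palindromic_band[1] && f <= palindromic_band[2])
      if (band_or_na(e$eaf) || band_or_na(eaf_out)) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(snp_id = snps[j], reason = "ambiguous_palindrome",
                     stringsAsFactors = FALSE)
        next
      }
      if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(snp_id = snps[j], reason = "allele_mismatch",
                     stringsAsFactors = FALSE)
        next
      }
      # allele labels cannot resolve the strand for a palindrome, so
      # orientation rests on frequency alone: first re-express the outcome
      # on the exposure's effect-allele label, then complement-flip if the
      # frequencies still sit on opposite sides of 0.5
      if (ea_y != ea_x) { beta_out <- -beta_out; eaf_out <- 1 - eaf_out }
      if ((e$eaf > 0.5) != (eaf_out > 0.5)) {
        beta_out <- -beta_out; eaf_out <- 1 - eaf_out
      }
    } else {
      direct   <- ea_y == ea_x && oa_y == oa_x
      swapped  <- ea_y == oa_x && oa_y == ea_x
      comp_d   <- complement_allele(ea_y) == ea_x && complement_allele(oa_y) == oa_x
      comp_s   <- complement_allele(ea_y) == oa_x && complement_allele(oa_y) == ea_x
      if (direct || comp_d) {
        # orientation already matches (possibly after strand complement)
      } else if (swapped || comp_s) {
        beta_out <- -beta_out
        if (!is.na(eaf_out)) eaf_out <- 1 - eaf_out
      } else {
        dropped[[length(dropped) + 1L]] <-
          data.frame(snp_id = snps[j], reason = "allele_mismatch",
                     stringsAsFactors = FALSE)
        next
      }
    }
    pairs[[length(pairs) + 1L]] <-
      data.frame(snp_id = snps[j], beta_exp = e$beta, se_exp = e$se,
                 beta_out = beta_out, se_out = o$se,
                 eaf_exp = e$eaf, eaf_out = eaf_out,
                 stringsAsFactors = FALSE)
  }
  empty_pairs <- data.frame(snp_id = character(0), beta_exp = numeric(0),
                            se_exp = numeric(0), beta_out = numeric(0),
                            se_out = numeric(0), eaf_exp = numeric(0),
                            eaf_out = numeric(0), stringsAsFactors = FALSE)
  empty_drop <- data.frame(snp_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  structure(list(pairs = if (length(pairs)) do.call(rbind, pairs) else empty_pairs,
                 dropped = if (length(dropped)) do.call(rbind, dropped) else empty_drop),
            class = "harmonized_set")
}

#' Build a harmonized set directly from aligned effect estimates
#'
#' Convenience constructor for pre-aligned pairs (simulation output, unit
#' fixtures) where allele bookkeeping is already resolved.
#'
#' @param snp_id,beta_exp,se_exp,beta_out,se_out Equal-length vectors.
#' @param eaf_exp,eaf_out Optional frequencies.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(snp_id, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = NA_real_, eaf_out = NA_real_) {
  if (any(se_exp <= 0) || any(se_out <= 0))
    stop_config("standard errors must be positive")
  structure(list(pairs = data.frame(snp_id = as.character(snp_id),
                                    beta_exp = beta_exp, se_exp = se_exp,
                                    beta_out = beta_out, se_out = se_out,
                                    eaf_exp = eaf_exp, eaf_out = eaf_out,
                                    stringsAsFactors = FALSE),
                 dropped = data.frame(snp_id = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %d SNP pairs retained, %d dropped\n",
              nrow(x$pairs), nrow(x$dropped)))
  if (nrow(x$dropped))
    print(table(x$dropped$reason))
  invisible(x)
}
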