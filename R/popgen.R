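# Allele counts ---------------------------------------------------------------

#' Genotype counts and risk-allele frequency for one SNP in one population
#'
#' Counts are taken over typed subjects only (missing genotypes are
#' excluded pairwise, per SNP). The risk-allele frequency is
#' `(n_het + 2 * n_hom_risk) / (2 * n_typed)`.
#'
#' @param cohort A cohort table.
#' @param snp_id rsID present in the cohort's panel.
#' @param population `"general"` or `"roma"`.
#' @return A one-row `data.frame` of class `"allele_counts"` with columns
#'   `snp_id`, `population`, `n_hom_nonrisk`, `n_het`, `n_hom_risk`,
#'   `n_typed`, `n_missing`, `risk_allele_freq`.
#' @export
allele_counts <- function(cohort, snp_id, population) {
  stopifnot(inherits(cohort, "cohort"))
  panel <- cohort_panel(cohort)
  if (!snp_id %in% panel$snp_id) {
    stop("'", snp_id, "' is not in the cohort's SNP panel", call. = FALSE)
  }
  sub <- cohort[cohort$population == population, , drop = FALSE]
  d <- sub[[snp_id]]
  n_missing <- sum(is.na(d))
  d <- d[!is.na(d)]
  if (length(d) == 0L) {
    stop("no typed subjects for ", snp_id, " in population '", population,
         "'", call. = FALSE)
  }
  counts <- tabulate(d + 1L, nbins = 3L)
  n <- length(d)
  out <- data.frame(
    snp_id = snp_id, population = population,
    n_hom_nonrisk = counts[1L], n_het = counts[2L], n_hom_risk = counts[3L],
    n_typed = n, n_missing = n_missing,
    risk_allele_freq = (counts[2L] + 2 * counts[3L]) / (2 * n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("allele_counts", "data.frame")
  out
}

#' Allele counts for every (SNP, population) stratum
#' @param cohort A cohort table.
#' @return A `data.frame` with one row per SNP and population.
#' @export
allele_count_table <- function(cohort) {
  panel <- cohort_panel(cohort)
  pops <- intersect(c("general", "roma"), unique(cohort$population))
  out <- do.call(rbind, lapply(panel$snp_id, function(s) {
    do.call(rbind, lapply(pops, function(p) allele_counts(cohort, s, p)))
  }))
  rownames(out) <- NULL
  out
}

# Hardy-Weinberg exact test ---------------------------------------------------

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the genotype counts of a biallelic SNP: with
#' the allele totals fixed, the two-sided p-value is the sum of the
#' probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count. The conditional distribution
#' is evaluated on the log scale over all heterozygote counts compatible
#' with the minor-allele total.
#'
#' @param counts Either an `"allele_counts"` row or an integer vector of
#'   length 3 `(n_hom_nonrisk, n_het, n_hom_risk)`.
#' @return The two-sided exact p-value. A monomorphic stratum returns 1 by
#'   convention (with a message).
#' @export
hwe_exact_test <- function(counts) {
  if (inherits(counts, "data.frame")) {
    counts <- c(counts$n_hom_nonrisk, counts$n_het, counts$n_hom_risk)
  }
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n1 <- counts[1L]; h <- counts[2L]; n2 <- counts[3L]
  n <- n1 + h + n2
  if (n < 1L) stop("no typed subjects", call. = FALSE)
  nm <- h + 2L * min(n1, n2)   # minor-allele copy total
  if (nm == 0L) {
    message("monomorphic SNP: HWE p = 1 by convention")
    return(1)
  }
  hs <- seq.int(nm %% 2L, min(nm, 2L * n - nm), by = 2L)
  # log P(h | n, nm) up to the common normalising constant
  lp <- h_log_prob(hs, n, nm)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(h, hs)]
  sum(p[p <= obs * (1 + 1e-9)])
}

# log of n! nm! (2n-nm)! 2^h / ((nm-h)/2)! h! (n-(nm+h)/2)! (2n)!
h_log_prob <- function(hs, n, nm) {
  lfactorial(n) + lfactorial(nm) + lfactorial(2 * n - nm) -
    lfactorial((nm - hs) / 2) - lfactorial(hs) -
    lfactorial(n - (nm + hs) / 2) - lfactorial(2 * n) + hs * log(2)
}

# Allelic association ---------------------------------------------------------

#' Compare risk-allele frequencies between two populations
#'
#' Pearson chi-square test (1 df, no continuity correction) on the 2x2
#' table of allele counts (risk vs non-risk x population). When any
#' expected cell is below 5, or any observed cell is zero (an allele
#' absent from one population), a two-sided exact (Fisher) p-value is
#' computed alongside and reported in `p_exact`.
#'
#' @param c1,c2 `"allele_counts"` rows for the same SNP in two populations.
#' @param alpha Base significance level.
#' @param m Number of tests for the Bonferroni adjustment (default: the
#'   six-SNP panel).
#' @return A one-row `data.frame` of class `"freq_comparison"`: per-population
#'   frequencies, `chi2`, `p_value`, `p_exact` (NA unless computed),
#'   `alpha_adjusted` and `significant_after_bonferroni`.
#' @export
allelic_chi2_test <- function(c1, c2, alpha = 0.05, m = 6L) {
  stopifnot(inherits(c1, "data.frame"), inherits(c2, "data.frame"))
  if (c1$snp_id != c2$snp_id) {
    stop("allele count summaries are for different SNPs", call. = FALSE)
  }
  r1 <- c1$n_het + 2 * c1$n_hom_risk; t1 <- 2 * c1$n_typed
  r2 <- c2$n_het + 2 * c2$n_hom_risk; t2 <- 2 * c2$n_typed
  tab <- matrix(c(r1, t1 - r1, r2, t2 - r2), nrow = 2L, byrow = TRUE,
                dimnames = list(c(c1$population, c2$population),
                                c("risk", "nonrisk")))
  fixed_both <- (r1 + r2 == 0) || (r1 + r2 == t1 + t2)
  p_exact <- NA_real_
  if (fixed_both) {
    warning("allele fixed in both populations; p = 1", call. = FALSE)
    chi2 <- 0; p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic); p <- unname(ct$p.value)
    if (any(ct$expected < 5) || any(tab == 0)) {
      p_exact <- stats::fisher.test(tab)$p.value
    }
  }
  adj <- bonferroni(alpha, m)
  out <- data.frame(
    snp_id = c1$snp_id,
    pop1 = c1$population, pop2 = c2$population,
    freq_pop1 = c1$risk_allele_freq, freq_pop2 = c2$risk_allele_freq,
    chi2 = chi2, p_value = p, p_exact = p_exact,
    alpha_adjusted = adj,
    significant_after_bonferroni = is.finite(p) && p < adj,
    stringsAsFactors = FALSE
  )
  class(out) <- c("freq_comparison", "data.frame")
  out
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Base level, in (0, 1).
#' @param m Number of tests, >= 1.
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  stopifnot(length(alpha) == 1L, length(m) == 1L)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

# Report ----------------------------------------------------------------------

#' Frequency, HWE and allelic-association report for a two-population cohort
#'
#' One row per (SNP, population) with genotype counts, risk-allele
#' frequency and exact HWE p-value, joined with the between-population
#' allelic test and its Bonferroni verdict.
#'
#' @param cohort A cohort table containing both populations.
#' @param alpha Base significance level for the allelic comparisons.
#' @return A `data.frame`; allelic-test columns are repeated on both rows
#'   of each SNP.
#' @export
popgen_report <- function(cohort, alpha = 0.05) {
  panel <- cohort_panel(cohort)
  m <- nrow(panel)
  out <- do.call(rbind, lapply(panel$snp_id, function(s) {
    cg <- allele_counts(cohort, s, "general")
    cr <- allele_counts(cohort, s, "roma")
    cmp <- allelic_chi2_test(cg, cr, alpha = alpha, m = m)
    rows <- rbind(as.data.frame(cg), as.data.frame(cr))
    rows$hwe_p <- c(suppressMessages(hwe_exact_test(cg)),
                    suppressMessages(hwe_exact_test(cr)))
    rows$allelic_chi2 <- cmp$chi2
    rows$allelic_p <- cmp$p_value
    rows$allelic_p_exact <- cmp$p_exact
    rows$alpha_adjusted <- cmp$alpha_adjusted
    rows$significant_after_bonferroni <- cmp$significant_after_bonferroni
    rows
  }))
  rownames(out) <- NULL
  out
}

#' Round a p-value the way association tables print it
#'
#' Two significant figures, e.g. 0.0373 -> 0.037 and 0.169 -> 0.17;
#' full precision should be retained for computation and only formatted
#' at report time.
#'
#' @param p Numeric vector of p-values.
#' @param digits Significant figures (default 2).
#' @return Numeric vector.
#' @export
round_p <- function(p, digits = 2) signif(p, digits)
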