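# 2x2 odds ratios -------------------------------------------------------------

#' Odds ratio from a 2x2 table with Woolf confidence interval
#'
#' Cross-product odds ratio `(a d)/(b c)` for the table
#' \preformatted{          case  non-case
#'   exposed     a       b
#'   unexposed   c       d }
#' When any cell is zero the Haldane-Anscombe correction (0.5 added to all
#' four cells) is applied, which keeps the estimate finite and positive,
#' and the result is flagged. The CI is Woolf's log-normal interval,
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` on the (possibly
#' corrected) cells.
#'
#' @param a,b,c,d Cell counts (exposed cases, exposed non-cases,
#'   unexposed cases, unexposed non-cases).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `or`, `ci_lo`, `ci_hi`, `p` (Wald), `corrected`
#'   (Haldane applied) and `separation` (a zero case or non-case margin in
#'   the exposed row).
#' @export
or_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  a <- unname(a); b <- unname(b); c <- unname(c); d <- unname(d)
  stopifnot(all(c(a, b, c, d) >= 0))
  corrected <- any(c(a, b, c, d) == 0)
  separation <- (a == 0 || b == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  lor <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(lor), ci_lo = exp(lor - z * se), ci_hi = exp(lor + z * se),
       p = 2 * stats::pnorm(-abs(lor / se)),
       corrected = corrected, separation = separation)
}

# Logistic regression ---------------------------------------------------------

#' Maximum-likelihood logistic regression with separation diagnostics
#'
#' Fits a binomial GLM by iteratively-reweighted least squares. Constant
#' predictor columns are dropped (and reported) before fitting; complete or
#' quasi-complete separation is declared when any fitted coefficient
#' exceeds `coef_bound` in absolute value, in which case the estimates are
#' diverging rather than converged and should not be quoted as odds
#' ratios.
#'
#' @param design Data frame or matrix of predictors (no intercept column;
#'   one is added).
#' @param outcome Logical or 0/1 vector.
#' @param coef_bound Absolute log-odds bound beyond which a coefficient is
#'   treated as diverging (default 15).
#' @param conf_level Confidence level for Wald intervals.
#' @return List of class `"logistic_fit"`: `coef`, `se`, `z`, `p`,
#'   `ci_lo`, `ci_hi` (log-odds scale), `or` (`exp(coef)`), `converged`,
#'   `separated`, `separated_terms`, `dropped` (constant columns),
#'   `iterations`, `n`.
#' @export
fit_logistic <- function(design, outcome, coef_bound = 15,
                         conf_level = 0.95) {
  design <- as.data.frame(design)
  y <- as.integer(as.logical(outcome))
  stopifnot(nrow(design) == length(y))
  keep <- vapply(design, function(x) length(unique(x[!is.na(x)])) > 1L,
                 logical(1L))
  dropped <- names(design)[!keep]
  design <- design[, keep, drop = FALSE]
  if (length(y) == 0L || length(unique(y)) < 2L) {
    return(structure(list(coef = numeric(0), se = numeric(0),
                          z = numeric(0), p = numeric(0),
                          ci_lo = numeric(0), ci_hi = numeric(0),
                          or = numeric(0), converged = TRUE,
                          separated = TRUE,
                          separated_terms = character(0),
                          dropped = dropped, iterations = 0L,
                          n = length(y), degenerate = TRUE),
                     class = "logistic_fit"))
  }
  dat <- cbind(design, .y = y)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    stop("rank-deficient design: ", paste(names(cf)[is.na(cf)],
         collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  slope <- setdiff(names(cf), "(Intercept)")
  separated_terms <- slope[abs(cf[slope]) > coef_bound]
  separated <- length(separated_terms) > 0L
  if (!fit$converged && !separated) {
    stop("logistic fit failed to converge after ", fit$iter,
         " IRLS iterations without evidence of separation", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    coef = cf, se = sm[, "Std. Error"], z = sm[, "z value"],
    p = sm[, "Pr(>|z|)"],
    ci_lo = cf - z * sm[, "Std. Error"],
    ci_hi = cf + z * sm[, "Std. Error"],
    or = exp(cf),
    converged = fit$converged, separated = separated,
    separated_terms = separated_terms, dropped = dropped,
    iterations = fit$iter, n = nrow(dat), degenerate = FALSE
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Degenerate logistic fit (constant outcome); n =", x$n, "\n")
    return(invisible(x))
  }
  tab <- data.frame(coef = x$coef, se = x$se, or = x$or, p = x$p)
  print(tab, digits = 4)
  if (x$separated) {
    cat("NOTE: separation detected for:",
        paste(x$separated_terms, collapse = ", "), "\n")
  }
  if (length(x$dropped)) {
    cat("dropped constant column(s):", paste(x$dropped, collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Genotype-level association table --------------------------------------------

#' Genotype-level case-control odds ratios for one SNP in one population
#'
#' Builds the per-genotype association table: each non-reference genotype
#' (heterozygote, risk homozygote) is compared with the non-risk
#' homozygote reference. Crude odds ratios come from the 2x2
#' cross-product with Woolf CI (Haldane-corrected and flagged when a cell
#' is zero). With `adjust_age = TRUE` an age-adjusted logistic odds ratio
#' is fitted per genotype contrast. A genotype with zero cases is a
#' complete-separation stratum: the maximum-likelihood estimate diverges,
#' so the row carries `separation = TRUE` and the adjusted OR is reported
#' as 0 (a sentinel, not an estimate) unless `compat_raw = TRUE`, in which
#' case the raw diverged `exp(coef)` is printed for table-compatibility
#' display only.
#'
#' @param cohort A cohort table.
#' @param snp_id rsID in the cohort's panel.
#' @param population `"general"` or `"roma"`.
#' @param adjust_age Also fit an age-adjusted logistic OR.
#' @param compat_raw Report raw diverged estimates for separated strata
#'   instead of the 0 sentinel.
#' @return A `data.frame` of class `"association_result"`, one row per
#'   genotype present in the stratum: counts, crude OR and CI, optional
#'   adjusted OR and CI, and flags. The reference row has OR 1 exactly.
#' @export
genotype_or_table <- function(cohort, snp_id, population,
                              adjust_age = FALSE, compat_raw = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  panel <- cohort_panel(cohort)
  pr <- panel[panel$snp_id == snp_id, , drop = FALSE]
  if (nrow(pr) != 1L) stop("'", snp_id, "' not in panel", call. = FALSE)
  sub <- cohort[cohort$population == population & !is.na(cohort[[snp_id]]),
                , drop = FALSE]
  d <- sub[[snp_id]]
  if (sum(d == 0L) < 1L) {
    stop("reference genotype absent for ", snp_id, " in '", population,
         "'", call. = FALSE)
  }
  rows <- list()
  for (g in 0:2) {
    idx <- d == g
    n_g <- sum(idx)
    if (n_g == 0L) next  # genotype absent: row omitted
    cases <- sum(sub$vte[idx])
    noncases <- n_g - cases
    row <- data.frame(
      snp_id = snp_id, population = population,
      genotype = dosage_to_genotype(g, pr), dosage = g,
      cases = cases, noncases = noncases,
      case_pct = 100 * cases / n_g,
      reference = g == 0L, stringsAsFactors = FALSE
    )
    if (g == 0L) {
      row$or_crude <- 1; row$ci_lo <- NA_real_; row$ci_hi <- NA_real_
      row$p_crude <- NA_real_
      row$haldane <- FALSE; row$separation <- FALSE
    } else {
      ref_cases <- sum(sub$vte[d == 0L])
      ref_noncases <- sum(d == 0L) - ref_cases
      est <- or_2x2(cases, noncases, ref_cases, ref_noncases)
      row$or_crude <- est$or; row$ci_lo <- est$ci_lo; row$ci_hi <- est$ci_hi
      row$p_crude <- est$p
      row$haldane <- est$corrected
      row$separation <- cases == 0L || noncases == 0L
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)

  if (adjust_age) {
    out$or_adj <- NA_real_; out$ci_lo_adj <- NA_real_
    out$ci_hi_adj <- NA_real_; out$p_adj <- NA_real_
    for (i in which(!out$reference)) {
      g <- out$dosage[i]
      keep <- d %in% c(0L, g)
      des <- data.frame(G = as.integer(d[keep] == g), age = sub$age[keep])
      fit <- fit_logistic(des, sub$vte[keep])
      if (isTRUE(fit$degenerate)) next
      sep_g <- "G" %in% fit$separated_terms
      out$separation[i] <- out$separation[i] || sep_g
      if (sep_g && !compat_raw) {
        out$or_adj[i] <- 0  # sentinel: MLE diverges towards 0 or Inf
      } else {
        out$or_adj[i] <- fit$or[["G"]]
        out$ci_lo_adj[i] <- exp(fit$ci_lo[["G"]])
        out$ci_hi_adj[i] <- exp(fit$ci_hi[["G"]])
        out$p_adj[i] <- fit$p[["G"]]
      }
    }
    out$or_adj[out$reference] <- 1
  }
  rownames(out) <- NULL
  class(out) <- c("association_result", "data.frame")
  out
}

#' Genotype association tables for the whole panel in both populations
#' @param cohort A cohort table.
#' @param adjust_age Passed to [genotype_or_table()].
#' @return Row-bound association tables.
#' @export
association_report <- function(cohort, adjust_age = TRUE) {
  panel <- cohort_panel(cohort)
  pops <- intersect(c("general", "roma"), unique(cohort$population))
  out <- do.call(rbind, lapply(panel$snp_id, function(s) {
    do.call(rbind, lapply(pops, function(p) {
      tryCatch(genotype_or_table(cohort, s, p, adjust_age = adjust_age),
               error = function(e) NULL)
    }))
  }))
  rownames(out) <- NULL
  out
}
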