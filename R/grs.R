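# Dosage coding ---------------------------------------------------------------

#' Code a raw risk-allele dosage for risk scoring
#'
#' Dosage codes 0/1/2 count copies of the risk allele. At a locus where
#' the nominal risk allele is in fact protective (`flip = TRUE` in the SNP
#' definition) the coding is reversed, so the homozygous "risk" genotype
#' codes 0 and the opposite homozygote codes 2; the heterozygote is a
#' fixed point. Missing dosage propagates as missing.
#'
#' @param snp A one-row [snp_def()].
#' @param raw_dosage Integer vector with values in `{0, 1, 2, NA}`.
#' @return Integer vector of coded dosages.
#' @export
code_dosage <- function(snp, raw_dosage) {
  stopifnot(all(raw_dosage %in% c(0:2, NA)))
  if (isTRUE(snp$flip)) 2L - as.integer(raw_dosage)
  else as.integer(raw_dosage)
}

# Score computation -----------------------------------------------------------

#' Compute unweighted or weighted genetic risk scores
#'
#' The unweighted score (uGRS) is the sum of coded risk-allele dosages
#' over the panel; the weighted score (wGRS) is the dosage sum weighted by
#' each SNP's external log-odds weight (natural-log odds ratio), so SNPs
#' with larger published effects contribute more. Weighted mode requires
#' every included SNP to carry a weight; SNPs without one must be dropped
#' from the panel first (the default six-SNP panel's founder mutation has
#' no published weight, so weighted scores conventionally use the other
#' five SNPs).
#'
#' Subjects missing any panel dosage receive `NA` and are counted in
#' `n_excluded`.
#'
#' @param cohort A cohort table.
#' @param panel Panel of SNPs to include (default: the cohort's own panel;
#'   in weighted mode, its weighted members).
#' @param mode `"unweighted"` or `"weighted"`.
#' @return List of class `"grs_result"`: `score` (per subject, aligned
#'   with `cohort` rows), `mode`, `panel`, `n_excluded`, and `summary`
#'   (per-population n, mean, sd, 95% CI of the mean, median, min, max).
#' @export
compute_grs <- function(cohort, panel = NULL,
                        mode = c("unweighted", "weighted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "cohort"))
  full <- cohort_panel(cohort)
  if (is.null(panel)) {
    panel <- if (mode == "weighted") {
      full[!is.na(full$weight), , drop = FALSE]
    } else full
  }
  stopifnot(nrow(panel) >= 1L)
  if (mode == "weighted" && anyNA(panel$weight)) {
    stop("weighted mode requires a weight for every panel SNP; missing ",
         "for: ", paste(panel$snp_id[is.na(panel$weight)], collapse = ", "),
         call. = FALSE)
  }
  coded <- sapply(seq_len(nrow(panel)), function(i) {
    s <- panel[i, , drop = FALSE]
    code_dosage(s, cohort[[s$snp_id]])
  })
  coded <- matrix(coded, nrow = nrow(cohort))
  w <- if (mode == "weighted") panel$weight else rep(1, nrow(panel))
  score <- as.numeric(coded %*% w)
  score[rowSums(is.na(coded)) > 0L] <- NA_real_

  pops <- intersect(c("general", "roma"), unique(cohort$population))
  summ <- do.call(rbind, lapply(pops, function(p) {
    x <- score[cohort$population == p]
    x <- x[!is.na(x)]
    n <- length(x)
    m <- if (n) mean(x) else NA_real_
    s <- if (n > 1) stats::sd(x) else NA_real_
    se <- if (n > 1) s / sqrt(n) else NA_real_
    data.frame(population = p, n = n, mean = m, sd = s,
               ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se,
               median = if (n) stats::median(x) else NA_real_,
               min = if (n) min(x) else NA_real_,
               max = if (n) max(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(score = score, mode = mode, panel = panel,
                 n_excluded = sum(is.na(score)), summary = summ),
            class = "grs_result")
}

#' @export
print.grs_result <- function(x, ...) {
  cat(sprintf("%s genetic risk score over %d SNPs (%d subject(s) excluded)\n",
              x$mode, nrow(x$panel), x$n_excluded))
  print(x$summary, digits = 3)
  invisible(x)
}

# Dichotomization -------------------------------------------------------------

#' Assign subjects to low/high score bands
#'
#' Two dichotomy rules: `"explicit"` uses a low band (closed interval) and
#' a high cut (score >= cut is high; subjects in neither band are `NA` and
#' excluded downstream); `"median"` splits at the per-population or pooled
#' median with ties assigned to the high group (score >= median is high).
#'
#' @param score Numeric score vector.
#' @param rule `"explicit"` or `"median"`.
#' @param low_band Length-2 numeric, the closed low interval (explicit
#'   rule; default `c(0, 1)`).
#' @param high_cut Scalar high threshold (explicit rule; default 3).
#' @return Factor with levels `low`, `high` (NA outside both bands).
#' @export
grs_band <- function(score, rule = c("explicit", "median"),
                     low_band = c(0, 1), high_cut = 3) {
  rule <- match.arg(rule)
  if (rule == "median") {
    med <- stats::median(score, na.rm = TRUE)
    band <- ifelse(score >= med, "high", "low")
  } else {
    band <- rep(NA_character_, length(score))
    band[score >= low_band[1] & score <= low_band[2]] <- "low"
    band[score >= high_cut] <- "high"
  }
  factor(band, levels = c("low", "high"))
}

# Stratified association ------------------------------------------------------

#' Odds ratio of VTE for high- vs low-score subjects
#'
#' Compares VTE odds between the high band (score >= `high_cut`) and the
#' low band; subjects between the bands are excluded and counted. Crude
#' estimation uses the 2x2 cross-product with Woolf CI (Haldane-corrected
#' when a cell is zero); with `adjust_age = TRUE` the odds ratio comes
#' from an age-adjusted logistic fit.
#'
#' @param cohort A cohort table.
#' @param result A [compute_grs()] result (or a raw score vector aligned
#'   with the cohort).
#' @param low_band,high_cut Band definition, see [grs_band()].
#' @param adjust_age Adjust for age via logistic regression.
#' @param population Optional single population to restrict to.
#' @return List of class `"grs_or"`: `or`, `ci_lo`, `ci_hi`, `p`, cell
#'   `counts`, `n_excluded_band`, `separation`, `undefined` (no cases in
#'   either band), `adjusted`.
#' @export
grs_stratified_or <- function(cohort, result, low_band = c(0, 1),
                              high_cut = 3, adjust_age = FALSE,
                              population = NULL) {
  score <- if (inherits(result, "grs_result")) result$score else result
  stopifnot(length(score) == nrow(cohort))
  keep <- !is.na(score)
  if (!is.null(population)) keep <- keep & cohort$population == population
  band <- grs_band(score, "explicit", low_band = low_band,
                   high_cut = high_cut)
  n_excluded_band <- sum(keep & is.na(band))
  keep <- keep & !is.na(band)
  band <- band[keep]
  vte <- cohort$vte[keep]
  age <- cohort$age[keep]
  if (!any(band == "low") || !any(band == "high")) {
    stop("a score band is empty", call. = FALSE)
  }
  counts <- c(high_cases = sum(vte[band == "high"]),
              high_noncases = sum(band == "high") - sum(vte[band == "high"]),
              low_cases = sum(vte[band == "low"]),
              low_noncases = sum(band == "low") - sum(vte[band == "low"]))
  undefined <- counts["high_cases"] + counts["low_cases"] == 0
  if (undefined) {
    warning("no VTE cases in either band: OR undefined", call. = FALSE)
    return(structure(list(or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                          p = NA_real_, counts = counts,
                          n_excluded_band = n_excluded_band,
                          separation = TRUE, undefined = TRUE,
                          adjusted = adjust_age), class = "grs_or"))
  }
  if (adjust_age) {
    fit <- fit_logistic(data.frame(high = as.integer(band == "high"),
                                   age = age), vte)
    est <- list(or = fit$or[["high"]], ci_lo = exp(fit$ci_lo[["high"]]),
                ci_hi = exp(fit$ci_hi[["high"]]), p = fit$p[["high"]],
                separation = "high" %in% fit$separated_terms)
  } else {
    e <- or_2x2(counts["high_cases"], counts["high_noncases"],
                counts["low_cases"], counts["low_noncases"])
    est <- list(or = e$or, ci_lo = e$ci_lo, ci_hi = e$ci_hi, p = e$p,
                separation = e$separation)
  }
  structure(c(est, list(counts = counts, n_excluded_band = n_excluded_band,
                        undefined = FALSE, adjusted = adjust_age)),
            class = "grs_or")
}

#' @export
print.grs_or <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("OR undefined: no cases in either band\n")
    return(invisible(x))
  }
  cat(sprintf("high- vs low-score OR = %.3g (95%% CI %.3g-%.3g), p = %.2g%s\n",
              x$or, x$ci_lo, x$ci_hi, x$p,
              if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' Environmental-factor odds ratio within the high-score stratum
#'
#' Screens for joint (additive-style) effects: among subjects with score
#' >= `high_cut`, the odds ratio of VTE for carriers of an environmental
#' factor versus non-carriers, optionally age-adjusted.
#'
#' @param cohort A cohort table.
#' @param result A [compute_grs()] result or score vector.
#' @param env_flag Name of a logical cohort column, or a logical vector
#'   aligned with the cohort.
#' @param high_cut High-band threshold.
#' @param adjust_age Adjust for age.
#' @param population Optional single population to restrict to.
#' @return List of class `"grs_or"` (as [grs_stratified_or()]), with
#'   `counts` holding exposed/unexposed case splits within the stratum.
#' @export
grs_env_joint_or <- function(cohort, result, env_flag, high_cut = 3,
                             adjust_age = FALSE, population = NULL) {
  score <- if (inherits(result, "grs_result")) result$score else result
  env <- if (is.character(env_flag)) cohort[[env_flag]] else env_flag
  if (is.null(env)) stop("unknown environmental flag", call. = FALSE)
  stopifnot(length(score) == nrow(cohort), length(env) == nrow(cohort))
  keep <- !is.na(score) & score >= high_cut & !is.na(env)
  if (!is.null(population)) keep <- keep & cohort$population == population
  if (!any(keep)) stop("empty high-score stratum", call. = FALSE)
  env <- as.logical(env[keep])
  vte <- cohort$vte[keep]
  age <- cohort$age[keep]
  if (length(unique(env)) < 2L) {
    stop("environmental flag is constant within the stratum", call. = FALSE)
  }
  counts <- c(exp_cases = sum(vte[env]), exp_noncases = sum(env) - sum(vte[env]),
              unexp_cases = sum(vte[!env]),
              unexp_noncases = sum(!env) - sum(vte[!env]))
  if (adjust_age) {
    fit <- fit_logistic(data.frame(E = as.integer(env), age = age), vte)
    if (isTRUE(fit$degenerate)) {
      warning("no outcome variation in stratum", call. = FALSE)
      return(structure(list(or = NA_real_, ci_lo = NA_real_,
                            ci_hi = NA_real_, p = NA_real_, counts = counts,
                            n_excluded_band = NA_integer_, separation = TRUE,
                            undefined = TRUE, adjusted = TRUE),
                       class = "grs_or"))
    }
    est <- list(or = fit$or[["E"]], ci_lo = exp(fit$ci_lo[["E"]]),
                ci_hi = exp(fit$ci_hi[["E"]]), p = fit$p[["E"]],
                separation = "E" %in% fit$separated_terms)
  } else {
    e <- or_2x2(counts["exp_cases"], counts["exp_noncases"],
                counts["unexp_cases"], counts["unexp_noncases"])
    est <- list(or = e$or, ci_lo = e$ci_lo, ci_hi = e$ci_hi, p = e$p,
                separation = e$separation)
  }
  structure(c(est, list(counts = counts, n_excluded_band = NA_integer_,
                        undefined = FALSE, adjusted = adjust_age)),
            class = "grs_or")
}
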