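# Two-step rank-based inverse-normal transformation ---------------------------

#' Two-step rank-based inverse-normal transformation
#'
#' Normalises a skewed variable in two steps: (1) fractional ranks
#' (mean rank for ties) are mapped to percentiles `r / (n + 1)` in (0, 1);
#' (2) the standard-normal quantiles of those percentiles are rescaled to
#' the original mean and standard deviation. Rank order is preserved, and
#' the output mean and SD equal the input's exactly (the quantiles are
#' centred and scaled before rescaling).
#'
#' @param values Numeric vector with at least 3 distinct finite values.
#' @return Numeric vector of the same length.
#' @export
templeton_transform <- function(values) {
  x <- values
  ok <- is.finite(x)
  if (length(unique(x[ok])) < 3L) {
    stop("transformation undefined: fewer than 3 distinct values",
         call. = FALSE)
  }
  r <- rank(x[ok], ties.method = "average")
  n <- sum(ok)
  z <- stats::qnorm(r / (n + 1))
  z <- (z - mean(z)) / stats::sd(z)
  out <- x
  out[ok] <- mean(x[ok]) + stats::sd(x[ok]) * z
  out
}

# Exposure definitions --------------------------------------------------------

#' Dichotomization cut-offs for continuous exposures
#'
#' Clinical cut-offs used to binarise lipid, glucose and anthropometric
#' exposures: total cholesterol >= 5.2 mmol/L, LDL-C >= 3.4 mmol/L,
#' HDL-C < 1.3 mmol/L (low HDL is the risk direction), triglycerides
#' >= 1.7 mmol/L, BMI > 30 kg/m^2 (obesity).
#'
#' @return Named list of functions mapping a numeric vector to a logical
#'   exposure flag.
#' @export
exposure_cutoffs <- function() {
  list(
    tc_high = function(x) x >= 5.2,
    ldl_high = function(x) x >= 3.4,
    hdl_low = function(x) x < 1.3,
    tg_high = function(x) x >= 1.7,
    obesity_bmi = function(x) x > 30
  )
}

#' Resolve an exposure name to a binary flag over a cohort
#'
#' Condition flags (`cancer`, `dm`, `cad`, `ckd`, `migraine`,
#' `depression`, `current_smoker`, `quit_lt1y`, `quit_ge1y`, `obesity`)
#' are taken directly; `tc_high`, `ldl_high`, `hdl_low`, `tg_high` and
#' `obesity_bmi` are derived from the continuous covariates at the
#' standard cut-offs ([exposure_cutoffs()]).
#'
#' @param cohort A cohort table.
#' @param exposure Exposure name, or a logical vector used as-is.
#' @return Logical vector aligned with the cohort.
#' @export
exposure_flag <- function(cohort, exposure) {
  if (is.logical(exposure)) {
    stopifnot(length(exposure) == nrow(cohort))
    return(exposure)
  }
  cuts <- exposure_cutoffs()
  src <- c(tc_high = "tc", ldl_high = "ldl_c", hdl_low = "hdl_c",
           tg_high = "tg", obesity_bmi = "bmi")
  if (exposure %in% names(cuts)) {
    return(cuts[[exposure]](cohort[[src[[exposure]]]]))
  }
  if (exposure %in% condition_flags()) return(cohort[[exposure]])
  stop("unknown exposure '", exposure, "'", call. = FALSE)
}

# Design construction ---------------------------------------------------------

#' Build the regression design for one SNP x exposure interaction
#'
#' Produces the predictor table with columns `G` (genetic term: risk-allele
#' dosage, or carrier indicator under dominant coding), `E` (binary
#' exposure), `GxE` (their elementwise product), the requested covariates
#' (age by default), and optionally an ethnicity indicator
#' (`roma` = 1) for combined-population models. Constant columns are
#' dropped with a report in attribute `"dropped"`. Rows with any missing
#' value are removed.
#'
#' @param cohort A cohort table.
#' @param snp_id rsID in the cohort's panel.
#' @param exposure Exposure name or logical vector (see [exposure_flag()]).
#' @param covariates Character vector of cohort columns to carry (default
#'   `"age"`).
#' @param genetic_coding `"dosage"` (0/1/2) or `"dominant"` (carrier 0/1).
#' @param include_ethnicity Add a `roma` indicator column.
#' @return Data frame with attributes `"outcome"` (VTE indicator for the
#'   retained rows) and `"dropped"` (names of dropped constant columns).
#' @export
build_interaction_design <- function(cohort, snp_id, exposure,
                                     covariates = "age",
                                     genetic_coding = c("dosage", "dominant"),
                                     include_ethnicity = FALSE) {
  genetic_coding <- match.arg(genetic_coding)
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort[[snp_id]]
  if (is.null(d)) stop("'", snp_id, "' not in cohort", call. = FALSE)
  G <- if (genetic_coding == "dominant") as.integer(d >= 1L) else as.integer(d)
  E <- as.integer(exposure_flag(cohort, exposure))
  if (length(unique(E[!is.na(E)])) < 2L) {
    stop("exposure has a single level after dichotomization", call. = FALSE)
  }
  des <- data.frame(G = G, E = E, GxE = G * E)
  for (v in covariates) des[[v]] <- cohort[[v]]
  if (include_ethnicity) des$roma <- as.integer(cohort$population == "roma")
  y <- as.integer(cohort$vte)
  keep <- stats::complete.cases(des) & !is.na(y)
  des <- des[keep, , drop = FALSE]
  y <- y[keep]
  const <- vapply(des, function(x) length(unique(x)) == 1L, logical(1L))
  dropped <- names(des)[const]
  des <- des[, !const, drop = FALSE]
  attr(des, "outcome") <- y
  attr(des, "dropped") <- dropped
  des
}

# Linear-probability interaction fit ------------------------------------------

#' Linear-probability regression with standardized coefficients
#'
#' Ordinary least squares of the 0/1 outcome on the design
#' (a linear-probability model). For each term the standardized
#' coefficient is the raw coefficient times SD(predictor)/SD(outcome);
#' two-sided p-values come from the t statistics.
#'
#' @param design Predictor data frame (e.g. from
#'   [build_interaction_design()]).
#' @param outcome 0/1 or logical outcome vector; defaults to the design's
#'   `"outcome"` attribute.
#' @return List of class `"gxe_fit"`: `coef`, `se`, `t`, `p`, `beta_std`
#'   (named by term), `sigma`, `df`, `n`, `fitted`.
#' @export
fit_gxe_linear <- function(design, outcome = attr(design, "outcome")) {
  if (is.null(outcome)) stop("no outcome supplied", call. = FALSE)
  y <- as.numeric(as.logical(outcome))
  des <- as.data.frame(design)
  stopifnot(nrow(des) == length(y))
  if (nrow(des) <= ncol(des) + 2L) {
    stop("too few observations for the number of terms", call. = FALSE)
  }
  dat <- cbind(des, .y = y)
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design: collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  sdy <- stats::sd(y)
  terms <- setdiff(names(cf), "(Intercept)")
  beta_std <- vapply(terms, function(tm) {
    cf[[tm]] * stats::sd(des[[tm]]) / sdy
  }, numeric(1L))
  structure(list(
    coef = cf, se = sm[, "Std. Error"], t = sm[, "t value"],
    p = sm[, "Pr(>|t|)"], beta_std = beta_std,
    sigma = summary(fit)$sigma, df = fit$df.residual, n = length(y),
    fitted = stats::fitted(fit)
  ), class = "gxe_fit")
}

#' @export
print.gxe_fit <- function(x, ...) {
  tab <- data.frame(coef = x$coef[-1L],
                    beta_std = x$beta_std[names(x$coef)[-1L]],
                    p = x$p[-1L])
  print(tab, digits = 3)
  invisible(x)
}

# Joint-exposure stratum odds ratios ------------------------------------------

#' Odds ratios over the four joint genetic/environmental strata
#'
#' Cross-classifies subjects by a binary genetic exposure G (dominant
#' carrier coding by default) and a binary environmental exposure E, and
#' estimates the odds ratio of each stratum against the doubly-unexposed
#' reference (G=0, E=0): OR01 (genetic only), OR10 (environmental only)
#' and OR11 (joint), by 2x2 cross-products with Haldane correction and
#' Woolf CIs. Cell counts are retained.
#'
#' @param cohort A cohort table.
#' @param snp_id rsID in the cohort's panel.
#' @param exposure Exposure name or logical vector.
#' @param genetic_coding `"dominant"` (carrier, default), `"recessive"`
#'   (two risk alleles), or `"dosage_threshold"` with `g_threshold`.
#' @param g_threshold Dosage threshold for `"dosage_threshold"` coding.
#' @param population Optional single population to restrict to.
#' @return List of class `"stratum_ors"`: `or00` (1), `or01`, `or10`,
#'   `or11`, each with CI; `cells` (case/non-case counts per stratum);
#'   `empty_cells`; `flagged`.
#' @export
stratum_ors <- function(cohort, snp_id, exposure,
                        genetic_coding = c("dominant", "recessive",
                                           "dosage_threshold"),
                        g_threshold = 1L, population = NULL) {
  genetic_coding <- match.arg(genetic_coding)
  stopifnot(inherits(cohort, "cohort"))
  sub <- cohort
  if (!is.null(population)) {
    sub <- sub[sub$population == population, , drop = FALSE]
  }
  d <- sub[[snp_id]]
  E <- exposure_flag(sub, if (is.logical(exposure)) {
    exposure[if (is.null(population)) TRUE else
      cohort$population == population]
  } else exposure)
  thr <- switch(genetic_coding, dominant = 1L, recessive = 2L,
                dosage_threshold = g_threshold)
  G <- as.integer(d >= thr)
  keep <- !is.na(G) & !is.na(E)
  G <- G[keep]; E <- as.integer(E[keep]); vte <- sub$vte[keep]

  cells <- expand.grid(G = 0:1, E = 0:1)
  cells <- cells[order(cells$E, cells$G), ]
  counts <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    idx <- G == cells$G[i] & E == cells$E[i]
    data.frame(G = cells$G[i], E = cells$E[i], n = sum(idx),
               cases = sum(vte[idx]), noncases = sum(idx) - sum(vte[idx]))
  }))
  empty <- counts$n == 0L
  get <- function(g, e) counts[counts$G == g & counts$E == e, ]
  ref <- get(0, 0)
  one_or <- function(g, e) {
    cell <- get(g, e)
    if (cell$n == 0L || ref$n == 0L) {
      return(list(or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                  corrected = NA, flagged = TRUE))
    }
    est <- or_2x2(cell$cases, cell$noncases, ref$cases, ref$noncases)
    list(or = est$or, ci_lo = est$ci_lo, ci_hi = est$ci_hi,
         corrected = est$corrected, flagged = FALSE)
  }
  or01 <- one_or(1, 0); or10 <- one_or(0, 1); or11 <- one_or(1, 1)
  structure(list(
    or00 = 1, or01 = or01$or, or10 = or10$or, or11 = or11$or,
    ci01 = c(or01$ci_lo, or01$ci_hi), ci10 = c(or10$ci_lo, or10$ci_hi),
    ci11 = c(or11$ci_lo, or11$ci_hi),
    cells = counts, empty_cells = any(empty),
    flagged = or01$flagged || or10$flagged || or11$flagged,
    snp_id = snp_id, genetic_coding = genetic_coding
  ), class = "stratum_ors")
}

#' Construct a stratum odds-ratio set from given values
#'
#' Convenience constructor for classification and testing: wraps
#' hand-specified OR01/OR10/OR11 into the structure returned by
#' [stratum_ors()].
#'
#' @param or01,or10,or11 Stratum odds ratios versus the doubly-unexposed
#'   reference.
#' @return A `"stratum_ors"` object without cell counts.
#' @export
make_stratum_ors <- function(or01, or10, or11) {
  stopifnot(or01 > 0, or10 > 0, or11 > 0)
  structure(list(or00 = 1, or01 = or01, or10 = or10, or11 = or11,
                 ci01 = c(NA, NA), ci10 = c(NA, NA), ci11 = c(NA, NA),
                 cells = NULL, empty_cells = FALSE, flagged = FALSE,
                 snp_id = NA_character_, genetic_coding = NA_character_),
            class = "stratum_ors")
}

# Interaction classification --------------------------------------------------

#' Classify interaction on multiplicative and additive scales
#'
#' Multiplicative scale: no interaction when OR11 = OR01 x OR10;
#' synergistic when OR11 exceeds the product, antagonistic when below.
#' Additive scale: the relative excess risk due to interaction,
#' RERI = OR11 - OR01 - OR10 + 1; no interaction at RERI = 0, synergy
#' when positive, antagonism when negative. `tolerance` is a relative
#' band: departures within `tolerance * |expected|` (multiplicative) or
#' `tolerance * (OR01 + OR10 - 1)` (additive) count as none.
#'
#' @param s A `"stratum_ors"` object ([stratum_ors()] or
#'   [make_stratum_ors()]).
#' @param tolerance Relative tolerance band (default 0: point
#'   comparison).
#' @return List of class `"interaction_class"`: `multiplicative_verdict`,
#'   `additive_verdict` (each `"none"`, `"synergistic"` or
#'   `"antagonistic"`), `reri`, `mult_excess` (OR11 - OR01 x OR10),
#'   `flagged` (propagated from the input).
#' @export
classify_interaction <- function(s, tolerance = 0) {
  stopifnot(inherits(s, "stratum_ors"))
  if (s$flagged || anyNA(c(s$or01, s$or10, s$or11))) {
    return(structure(list(multiplicative_verdict = NA_character_,
                          additive_verdict = NA_character_,
                          reri = NA_real_, mult_excess = NA_real_,
                          flagged = TRUE), class = "interaction_class"))
  }
  mult_expect <- s$or01 * s$or10
  mult_excess <- s$or11 - mult_expect
  mult_band <- tolerance * abs(mult_expect)
  mult <- if (mult_excess > mult_band) "synergistic"
          else if (mult_excess < -mult_band) "antagonistic" else "none"
  reri <- s$or11 - s$or01 - s$or10 + 1
  add_band <- tolerance * abs(s$or01 + s$or10 - 1)
  add <- if (reri > add_band) "synergistic"
         else if (reri < -add_band) "antagonistic" else "none"
  structure(list(multiplicative_verdict = mult, additive_verdict = add,
                 reri = reri, mult_excess = mult_excess, flagged = FALSE),
            class = "interaction_class")
}

#' @export
print.interaction_class <- function(x, ...) {
  cat(sprintf("multiplicative: %s (excess %.3g); additive: %s (RERI %.3g)\n",
              x$multiplicative_verdict, x$mult_excess,
              x$additive_verdict, x$reri))
  invisible(x)
}

# Bootstrap verdicts ----------------------------------------------------------

#' Bootstrap confidence intervals for the interaction contrasts
#'
#' Percentile bootstrap (resampling subjects) of the multiplicative excess
#' OR11 - OR01 x OR10 and of RERI, giving CI-aware verdicts alongside the
#' point verdicts of [classify_interaction()]: a scale is called
#' synergistic/antagonistic only when its bootstrap interval excludes 0.
#'
#' @param cohort A cohort table.
#' @param snp_id,exposure,genetic_coding,population As [stratum_ors()].
#' @param n_boot Number of resamples (default 2000).
#' @param conf_level Interval level.
#' @param seed Integer seed for the resampling stream.
#' @return List: `point` (the [classify_interaction()] result),
#'   `mult_ci`, `reri_ci`, `mult_verdict_ci`, `additive_verdict_ci`,
#'   `n_boot_used` (resamples with all four cells populated).
#' @export
bootstrap_interaction <- function(cohort, snp_id, exposure,
                                  genetic_coding = "dominant",
                                  population = NULL, n_boot = 2000,
                                  conf_level = 0.95, seed = 1L) {
  s0 <- stratum_ors(cohort, snp_id, exposure,
                    genetic_coding = genetic_coding,
                    population = population)
  point <- classify_interaction(s0)
  sub <- cohort
  if (!is.null(population)) {
    sub <- sub[sub$population == population, , drop = FALSE]
  }
  rng <- local({ set.seed(seed); NULL })
  n <- nrow(sub)
  mult <- reri <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    sb <- sub[idx, , drop = FALSE]
    class(sb) <- class(sub); attr(sb, "panel") <- cohort_panel(cohort)
    sbo <- tryCatch(
      stratum_ors(sb, snp_id, exposure, genetic_coding = genetic_coding),
      error = function(e) NULL)
    if (is.null(sbo) || sbo$flagged) next
    mult[b] <- sbo$or11 - sbo$or01 * sbo$or10
    reri[b] <- sbo$or11 - sbo$or01 - sbo$or10 + 1
  }
  ok <- !is.na(mult)
  qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  mult_ci <- stats::quantile(mult[ok], qs, names = FALSE)
  reri_ci <- stats::quantile(reri[ok], qs, names = FALSE)
  verdict_from_ci <- function(ci) {
    if (anyNA(ci)) NA_character_
    else if (ci[1] > 0) "synergistic"
    else if (ci[2] < 0) "antagonistic" else "none"
  }
  list(point = point, mult_ci = mult_ci, reri_ci = reri_ci,
       mult_verdict_ci = verdict_from_ci(mult_ci),
       additive_verdict_ci = verdict_from_ci(reri_ci),
       n_boot_used = sum(ok))
}

# Full interaction scan -------------------------------------------------------

#' Interaction report over a SNP x exposure grid
#'
#' For each (SNP, exposure, population) combination: the standardized
#' interaction coefficient and p-value from the linear-probability fit
#' (G, E, GxE, age), the four stratum odds ratios, RERI, and the point
#' verdicts on both scales. No multiple-testing adjustment is applied to
#' the grid; an optional Benjamini-Hochberg column can be added.
#'
#' @param cohort A cohort table.
#' @param exposures Character vector of exposure names (default: the
#'   condition flags plus the lipid cut-offs).
#' @param snp_ids rsIDs to scan (default: the whole panel).
#' @param genetic_coding Coding for the stratum ORs (the regression G term
#'   uses dosage coding).
#' @param populations Populations to stratify by (default both,
#'   separately).
#' @param add_bh Append Benjamini-Hochberg adjusted interaction p-values.
#' @return A `data.frame`, one row per combination.
#' @export
gxe_report <- function(cohort, exposures = NULL, snp_ids = NULL,
                       genetic_coding = "dominant",
                       populations = c("general", "roma"),
                       add_bh = FALSE) {
  panel <- cohort_panel(cohort)
  if (is.null(snp_ids)) snp_ids <- panel$snp_id
  if (is.null(exposures)) {
    exposures <- c(setdiff(condition_flags(), "obesity"),
                   names(exposure_cutoffs()))
  }
  populations <- intersect(populations, unique(cohort$population))
  rows <- list()
  for (p in populations) {
    sub <- cohort[cohort$population == p, , drop = FALSE]
    class(sub) <- class(cohort); attr(sub, "panel") <- panel
    for (s in snp_ids) {
      for (e in exposures) {
        res <- tryCatch({
          des <- build_interaction_design(sub, s, e)
          beta <- p_int <- NA_real_
          if ("GxE" %in% names(des)) {
            fit <- fit_gxe_linear(des)
            beta <- fit$beta_std[["GxE"]]
            p_int <- fit$p[["GxE"]]
          }
          so <- stratum_ors(sub, s, e, genetic_coding = genetic_coding)
          cl <- classify_interaction(so)
          data.frame(snp_id = s, exposure = e, population = p,
                     beta_std = beta, p_interaction = p_int,
                     or00 = so$or00, or01 = so$or01, or10 = so$or10,
                     or11 = so$or11, reri = cl$reri,
                     multiplicative_verdict = cl$multiplicative_verdict,
                     additive_verdict = cl$additive_verdict,
                     flagged = cl$flagged, stringsAsFactors = FALSE)
        }, error = function(err) {
          data.frame(snp_id = s, exposure = e, population = p,
                     beta_std = NA_real_, p_interaction = NA_real_,
                     or00 = 1, or01 = NA_real_, or10 = NA_real_,
                     or11 = NA_real_, reri = NA_real_,
                     multiplicative_verdict = NA_character_,
                     additive_verdict = NA_character_, flagged = TRUE,
                     stringsAsFactors = FALSE)
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  if (add_bh) {
    out$p_bh <- stats::p.adjust(out$p_interaction, method = "BH")
  }
  rownames(out) <- NULL
  out
}
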