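# Generator specification -----------------------------------------------------

#' Specification for the synthetic two-population cohort generator
#'
#' Defaults reproduce the statistical structure the analysis assumes for
#' the study setting: two populations (~400 subjects each), genotypes in
#' Hardy-Weinberg proportions at the published per-population risk-allele
#' frequencies (including a founder allele at 1% in the roma population
#' and absent in the general one), quantitative covariates at the
#' published means (SDs back-calculated from the published 95% CIs of the
#' means), and a logistic VTE outcome model whose intercept puts baseline
#' prevalence in the observed 1.5-3% range. Condition prevalences are not
#' published for this cohort; the defaults are nominal adult-population
#' values and are labelled as such.
#'
#' @param n Named integer vector: subjects per population.
#' @param freqs Named list (by population) of named numeric vectors (by
#'   rsID): risk-allele frequencies.
#' @param covariates Named list (by population) of data frames with
#'   columns `mean` and `sd`, rownames age/bmi/wc/tc/ldl_c/hdl_c/tg/fbg.
#' @param prop_female Named numeric: female share per population.
#' @param prevalences Named numeric: Bernoulli prevalence per condition
#'   flag (obesity is derived from BMI > 30, not drawn).
#' @param outcome Outcome model: `intercept` (log-odds), optional named
#'   vectors `genetic` (per-allele log-OR by rsID), `env` (log-OR by
#'   condition flag), `age` (log-OR per year, centred), and `gxe` (list of
#'   `list(snp=, env=, beta=)` product terms on carrier x flag or
#'   dosage x flag per `gxe_coding`).
#' @param gxe_coding `"dosage"` or `"dominant"`: genetic coding of the
#'   generator's interaction terms.
#' @param tg_lognormal Draw triglycerides from a log-normal matched to the
#'   target mean/SD (the realistic right-skew) instead of a normal.
#' @param panel SNP panel (default [default_snp_panel()]).
#' @return List of class `"generator_spec"`.
#' @export
generator_spec <- function(n = c(general = 406L, roma = 395L),
                           freqs = NULL, covariates = NULL,
                           prop_female = c(general = 0.554, roma = 0.739),
                           prevalences = NULL, outcome = NULL,
                           gxe_coding = c("dosage", "dominant"),
                           tg_lognormal = TRUE,
                           panel = default_snp_panel()) {
  gxe_coding <- match.arg(gxe_coding)
  if (is.null(freqs)) {
    freqs <- list(
      general = c(rs121909567 = 0.00, rs1799963 = 0.02, rs2036914 = 0.54,
                  rs2066865 = 0.23, rs6025 = 0.07, rs8176719 = 0.47),
      roma = c(rs121909567 = 0.01, rs1799963 = 0.01, rs2036914 = 0.51,
               rs2066865 = 0.28, rs6025 = 0.09, rs8176719 = 0.48)
    )
  }
  if (is.null(covariates)) covariates <- default_covariate_params()
  if (is.null(prevalences)) {
    # nominal adult prevalences; not cohort-derived
    prevalences <- c(cancer = 0.03, dm = 0.10, cad = 0.08, ckd = 0.03,
                     migraine = 0.12, depression = 0.10,
                     current_smoker = 0.35, quit_lt1y = 0.05,
                     quit_ge1y = 0.15)
  }
  if (is.null(outcome)) {
    outcome <- list(intercept = stats::qlogis(0.02), genetic = NULL,
                    env = NULL, age = 0, gxe = NULL)
  }
  if (is.null(outcome$intercept)) stop("outcome$intercept required",
                                       call. = FALSE)
  for (p in names(freqs)) {
    f <- freqs[[p]]
    if (any(f < 0 | f > 1)) stop("frequencies must lie in [0,1]",
                                 call. = FALSE)
  }
  stopifnot(all(n >= 1L))
  base <- stats::plogis(outcome$intercept)
  if (!(base > 0 && base < 1)) {
    stop("baseline outcome prevalence must be in (0,1)", call. = FALSE)
  }
  structure(list(n = n, freqs = freqs, covariates = covariates,
                 prop_female = prop_female, prevalences = prevalences,
                 outcome = outcome, gxe_coding = gxe_coding,
                 tg_lognormal = tg_lognormal, panel = panel),
            class = "generator_spec")
}

# Population means with 95% CI half-widths of the mean, as published for
# the study samples (N = 406 general, 395 roma); SD = hw / 1.96 * sqrt(N).
# The SDs are population properties, so the published Ns are used here
# regardless of the simulated cohort size.
default_covariate_params <- function() {
  mk <- function(means, hw, N) {
    data.frame(mean = means, sd = hw / 1.96 * sqrt(N),
               row.names = c("age", "bmi", "wc", "tc", "ldl_c", "hdl_c",
                             "tg", "fbg"))
  }
  list(
    general = mk(c(44.3, 27.2, 96.0, 5.0, 3.1, 1.4, 1.6, 5.3),
                 c(1.2, 0.5, 1.5, 0.1, 0.1, 0.05, 0.1, 0.2), 406L),
    roma = mk(c(43.5, 27.5, 95.0, 4.9, 3.1, 1.3, 1.7, 5.2),
              c(1.25, 0.7, 1.7, 0.1, 0.1, 0.05, 0.15, 0.2), 395L)
  )
}

# Genotypes -------------------------------------------------------------------

#' Generate Hardy-Weinberg genotype dosages for one population
#'
#' Each SNP's dosage is drawn independently as binomial(2, p) across
#' subjects (HWE, no linkage disequilibrium).
#'
#' @param spec A [generator_spec()].
#' @param population Population name present in `spec$freqs`.
#' @param n Number of subjects (default from the spec).
#' @return Integer matrix, subjects x SNPs, columns named by rsID.
#' @export
generate_genotypes <- function(spec, population,
                               n = spec$n[[population]]) {
  stopifnot(inherits(spec, "generator_spec"))
  f <- spec$freqs[[population]]
  if (is.null(f)) stop("no frequencies for population '", population, "'",
                       call. = FALSE)
  g <- vapply(spec$panel$snp_id, function(s) {
    stats::rbinom(n, 2L, f[[s]])
  }, integer(n))
  matrix(as.integer(g), nrow = n,
         dimnames = list(NULL, spec$panel$snp_id))
}

# Phenotypes ------------------------------------------------------------------

#' Generate phenotypes and outcomes for a dosage matrix
#'
#' Quantitative covariates are normal at the spec means/SDs (TG optionally
#' log-normal, moment-matched); condition flags are Bernoulli at the spec
#' prevalences with obesity derived from BMI > 30; VTE is Bernoulli with
#' probability the inverse-logit of the outcome model's linear predictor
#' (intercept + genetic + environmental + interaction + age terms).
#'
#' @param spec A [generator_spec()].
#' @param population Population name.
#' @param dosages Matrix from [generate_genotypes()].
#' @param id_prefix Prefix for subject IDs.
#' @return A validated cohort table for this population.
#' @export
generate_phenotypes <- function(spec, population, dosages,
                                id_prefix = population) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- nrow(dosages)
  cv <- spec$covariates[[population]]
  draw <- function(v) {
    if (v == "tg" && isTRUE(spec$tg_lognormal) && cv["tg", "sd"] > 0) {
      m <- cv["tg", "mean"]; s <- cv["tg", "sd"]
      sigma2 <- log(1 + (s / m)^2)
      stats::rlnorm(n, meanlog = log(m) - sigma2 / 2,
                    sdlog = sqrt(sigma2))
    } else {
      stats::rnorm(n, cv[v, "mean"], cv[v, "sd"])
    }
  }
  df <- data.frame(
    subject_id = sprintf("%s_%06d", id_prefix, seq_len(n)),
    population = population,
    sex = ifelse(stats::runif(n) < spec$prop_female[[population]],
                 "female", "male"),
    age = pmin(pmax(draw("age"), 20), 64),
    stringsAsFactors = FALSE
  )
  for (v in quantitative_covariates()) df[[v]] <- draw(v)
  df$bmi <- pmax(df$bmi, 15)
  for (v in c("wc", "tc", "ldl_c", "hdl_c", "tg", "fbg")) {
    df[[v]] <- pmax(df[[v]], 0.1)
  }
  for (fl in setdiff(condition_flags(), "obesity")) {
    df[[fl]] <- stats::runif(n) < spec$prevalences[[fl]]
  }
  df$obesity <- df$bmi > 30

  om <- spec$outcome
  lp <- rep(om$intercept, n)
  for (s in names(om$genetic)) lp <- lp + om$genetic[[s]] * dosages[, s]
  for (e in names(om$env)) lp <- lp + om$env[[e]] * as.numeric(df[[e]])
  if (!is.null(om$age) && om$age != 0) {
    lp <- lp + om$age * (df$age - cv["age", "mean"])
  }
  for (term in om$gxe) {
    g <- dosages[, term$snp]
    if (spec$gxe_coding == "dominant") g <- as.integer(g >= 1L)
    lp <- lp + term$beta * g * as.numeric(df[[term$env]])
  }
  pr <- stats::plogis(lp)
  if (any(pr <= 0 | pr >= 1)) {
    stop("outcome probability left (0,1); adjust the intercept or ",
         "coefficients", call. = FALSE)
  }
  df$vte <- stats::runif(n) < pr
  for (s in colnames(dosages)) df[[s]] <- dosages[, s]
  as_cohort(df, spec$panel)
}

#' Simulate a complete two-population cohort
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed; the same spec and seed give an identical
#'   cohort.
#' @return A cohort table combining all populations in the spec.
#' @export
simulate_cohort <- function(spec = generator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(seed)
  parts <- lapply(names(spec$n), function(p) {
    g <- generate_genotypes(spec, p)
    as.data.frame(generate_phenotypes(spec, p, g))
  })
  as_cohort(do.call(rbind, parts), spec$panel)
}

# Deterministic table-derived fixture ------------------------------------------

# per-genotype (dosage 0/1/2) case and non-case counts, per population
fixture_counts <- function() {
  list(
    general = list(
      rs121909567 = list(cases = c(6, 0, 0), noncases = c(400, 0, 0)),
      rs1799963 = list(cases = c(6, 0, 0), noncases = c(384, 16, 0)),
      rs2036914 = list(cases = c(1, 4, 1), noncases = c(83, 201, 116)),
      rs2066865 = list(cases = c(2, 3, 1), noncases = c(233, 149, 18)),
      rs6025 = list(cases = c(4, 2, 0), noncases = c(347, 52, 1)),
      rs8176719 = list(cases = c(5, 1, 0), noncases = c(114, 193, 93))
    ),
    roma = list(
      rs121909567 = list(cases = c(12, 0, 0), noncases = c(372, 11, 0)),
      rs1799963 = list(cases = c(12, 0, 0), noncases = c(377, 6, 0)),
      rs2036914 = list(cases = c(3, 6, 3), noncases = c(97, 184, 102)),
      rs2066865 = list(cases = c(5, 4, 3), noncases = c(201, 156, 26)),
      rs6025 = list(cases = c(8, 4, 0), noncases = c(323, 56, 4)),
      rs8176719 = list(cases = c(5, 5, 2), noncases = c(101, 192, 90))
    )
  )
}

# VTE cases / non-cases by sex, per population
fixture_sex <- function() {
  list(general = list(cases = c(male = 4, female = 2),
                      noncases = c(male = 177, female = 223)),
       roma = list(cases = c(male = 4, female = 8),
                   noncases = c(male = 99, female = 284)))
}

#' Deterministic cohort reproducing the published marginal counts
#'
#' Builds a synthetic cohort whose per-SNP genotype x VTE x population
#' counts equal the published genotype-level association table cell for
#' cell (406 general, 395 roma subjects; 6 and 12 VTE cases), and whose
#' sex x VTE split matches the published distribution. Genotypes are
#' assigned independently per SNP within the case and non-case blocks, so
#' all single-SNP margins are exact while between-SNP joint distributions
#' are arbitrary; ages and quantitative covariates are filled with the
#' population means and all condition flags are FALSE. Suitable for
#' count-level computations (frequencies, HWE, crude ORs, prevalences)
#' only.
#'
#' @return A validated cohort table.
#' @export
make_paper_fixture <- function() {
  counts <- fixture_counts()
  sexes <- fixture_sex()
  cv <- default_covariate_params()
  parts <- lapply(names(counts), function(p) {
    cc <- counts[[p]]
    n_cases <- sum(cc[[1L]]$cases)
    n_non <- sum(cc[[1L]]$noncases)
    n <- n_cases + n_non
    vte <- c(rep(TRUE, n_cases), rep(FALSE, n_non))
    sx <- sexes[[p]]
    sex <- c(rep(names(sx$cases), sx$cases),
             rep(names(sx$noncases), sx$noncases))
    df <- data.frame(
      subject_id = sprintf("%s_fix_%04d", p, seq_len(n)),
      population = p, sex = sex,
      age = cv[[p]]["age", "mean"], stringsAsFactors = FALSE
    )
    for (v in quantitative_covariates()) df[[v]] <- cv[[p]][v, "mean"]
    for (fl in condition_flags()) df[[fl]] <- FALSE
    df$vte <- vte
    for (s in names(cc)) {
      df[[s]] <- c(rep(0:2, cc[[s]]$cases), rep(0:2, cc[[s]]$noncases))
    }
    df
  })
  as_cohort(do.call(rbind, parts), default_snp_panel())
}
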