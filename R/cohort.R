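#' @keywords internal
"_PACKAGE"

# Canonical cohort columns ----------------------------------------------------

#' Names of the quantitative covariates carried by a cohort table
#' @return Character vector of column names (units in parentheses): bmi
#'   (kg/m^2), wc (cm), tc, ldl_c, hdl_c, tg, fbg (all mmol/L).
#' @export
quantitative_covariates <- function() {
  c("bmi", "wc", "tc", "ldl_c", "hdl_c", "tg", "fbg")
}

#' Names of the binary condition/behaviour flags carried by a cohort table
#' @return Character vector of column names.
#' @export
condition_flags <- function() {
  c("cancer", "dm", "cad", "ckd", "migraine", "depression",
    "current_smoker", "quit_lt1y", "quit_ge1y", "obesity")
}

required_cohort_columns <- function() {
  c("subject_id", "population", "sex", "age",
    quantitative_covariates(), condition_flags(), "vte")
}

# Genotype parsing ------------------------------------------------------------

#' Convert genotype text to risk-allele dosage
#'
#' Accepts three dialects for a biallelic genotype and normalises all of
#' them to the count of risk-allele copies (0, 1 or 2):
#' \itemize{
#'   \item allele pairs separated by `/` or `|` (e.g. `"G/A"`),
#'   \item concatenated single-character alleles (e.g. `"GA"`),
#'   \item integer dosage strings (`"0"`, `"1"`, `"2"`).
#' }
#' Empty strings, `"NA"`, `"./."` and `NA` become missing dosage.
#'
#' @param x Character (or numeric) vector of genotypes.
#' @param snp A one-row [snp_def()] giving alleles and risk orientation.
#' @return Integer vector of dosages in `{0, 1, 2, NA}`.
#' @export
parse_genotypes <- function(x, snp) {
  alleles <- c(snp$allele1, snp$allele2)
  risk <- snp$risk_allele
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  for (i in seq_along(x)) {
    g <- x[i]
    if (is.na(g) || g == "" || g %in% c("NA", "./.", ".", ".|.")) next
    if (grepl("^[0-2]$", g)) {
      out[i] <- as.integer(g)
      next
    }
    if (grepl("^-?[0-9]+$", g)) {
      stop("dosage outside {0,1,2} at entry ", i, ": '", g, "'",
           call. = FALSE)
    }
    pair <- if (grepl("[/|]", g)) {
      strsplit(g, "[/|]")[[1L]]
    } else if (all(nchar(alleles) == 1L) && nchar(g) == 2L) {
      strsplit(g, "")[[1L]]
    } else {
      stop("cannot parse genotype '", g, "' at entry ", i, " for ",
           snp$snp_id, call. = FALSE)
    }
    if (length(pair) != 2L || !all(pair %in% alleles)) {
      stop("unknown allele symbol in genotype '", g, "' at entry ", i,
           " for ", snp$snp_id, " (alleles ",
           paste(alleles, collapse = "/"), ")", call. = FALSE)
    }
    out[i] <- sum(pair == risk)
  }
  out
}

dosage_to_genotype <- function(d, snp) {
  nonrisk <- setdiff(c(snp$allele1, snp$allele2), snp$risk_allele)
  lab <- c(paste(nonrisk, nonrisk, sep = "/"),
           paste(nonrisk, snp$risk_allele, sep = "/"),
           paste(snp$risk_allele, snp$risk_allele, sep = "/"))
  ifelse(is.na(d), NA_character_, lab[d + 1L])
}

# Cohort construction ---------------------------------------------------------

#' Build a cohort table from a data frame of subject records
#'
#' Validates the schema (all demographic, covariate, condition and outcome
#' columns present; one genotype column per panel SNP), coerces types, and
#' attaches the SNP panel. Genotype columns must already hold dosages in
#' `{0, 1, 2, NA}`; use [read_cohort()] to ingest allele-pair text.
#'
#' @param df Data frame with the columns named by
#'   [quantitative_covariates()], [condition_flags()], plus `subject_id`,
#'   `population` (`"general"`/`"roma"`), `sex` (`"male"`/`"female"`),
#'   `age`, `vte`, and one column per `panel$snp_id`.
#' @param panel A [snp_panel()].
#' @param age_range Plausible age range; values outside it trigger a
#'   warning (the study design enrols adults aged 20-64).
#' @return A `data.frame` with class `"cohort"` and the panel attached as
#'   attribute `"panel"`.
#' @export
as_cohort <- function(df, panel = default_snp_panel(),
                      age_range = c(20, 64)) {
  stopifnot(is.data.frame(df), inherits(panel, "snp_panel"))
  missing_cols <- setdiff(required_cohort_columns(), names(df))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  missing_snps <- setdiff(panel$snp_id, names(df))
  if (length(missing_snps)) {
    stop("cohort lacks genotype column(s): ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop("subject_id values are not unique", call. = FALSE)
  }
  df$population <- as.character(df$population)
  bad_pop <- setdiff(unique(df$population), c("general", "roma"))
  if (length(bad_pop)) {
    stop("unknown population label(s): ", paste(bad_pop, collapse = ", "),
         call. = FALSE)
  }
  df$sex <- as.character(df$sex)
  bad_sex <- setdiff(unique(df$sex), c("male", "female"))
  if (length(bad_sex)) {
    stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  }
  df$age <- as.numeric(df$age)
  n_out <- sum(df$age < age_range[1] | df$age > age_range[2], na.rm = TRUE)
  if (n_out > 0) {
    warning(n_out, " subject(s) have age outside the plausible range [",
            age_range[1], ", ", age_range[2], "]", call. = FALSE)
  }
  for (v in quantitative_covariates()) df[[v]] <- as.numeric(df[[v]])
  for (v in c(condition_flags(), "vte")) {
    x <- df[[v]]
    if (is.character(x)) x <- x %in% c("1", "TRUE", "true", "yes")
    df[[v]] <- as.logical(x)
  }
  for (s in panel$snp_id) {
    d <- df[[s]]
    if (!is.numeric(d) && !is.integer(d) && !is.logical(d)) {
      stop("genotype column '", s, "' is not numeric dosage; use ",
           "read_cohort() for allele-pair text", call. = FALSE)
    }
    d <- as.integer(d)
    bad <- which(!is.na(d) & !(d %in% 0:2))
    if (length(bad)) {
      stop("dosage outside {0,1,2} for ", s, " at row ", bad[1L],
           call. = FALSE)
    }
    df[[s]] <- d
  }
  rownames(df) <- NULL
  attr(df, "panel") <- panel
  class(df) <- c("cohort", "data.frame")
  df
}

#' Extract the SNP panel attached to a cohort
#' @param cohort A cohort from [as_cohort()] or [read_cohort()].
#' @return The [snp_panel()].
#' @export
cohort_panel <- function(cohort) {
  p <- attr(cohort, "panel")
  if (is.null(p)) stop("object carries no SNP panel", call. = FALSE)
  p
}

# IO --------------------------------------------------------------------------

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a cohort table from delimited text
#'
#' The file is UTF-8 delimited text (comma or tab, autodetected from the
#' header row) with one row per subject. Genotype columns (one per panel
#' SNP, named by rsID) may hold allele pairs (`"G/A"`, `"GA"`) or integer
#' dosages; both are normalised to risk-allele dosage according to the
#' panel's orientation.
#'
#' @param path Path to the cohort file.
#' @param snp_config Either a [snp_panel()] or a path to a YAML SNP
#'   configuration (see [read_snp_config()]).
#' @param age_range Passed to [as_cohort()].
#' @return A validated cohort table.
#' @export
read_cohort <- function(path, snp_config = default_snp_panel(),
                        age_range = c(20, 64)) {
  panel <- if (inherits(snp_config, "snp_panel")) snp_config
           else read_snp_config(snp_config)
  df <- utils::read.table(path, header = TRUE, sep = detect_delim(path),
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  missing_cols <- setdiff(required_cohort_columns(), names(df))
  if (length(missing_cols)) {
    stop("cohort file '", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(panel))) {
    s <- panel$snp_id[i]
    if (!s %in% names(df)) next  # caught by as_cohort
    df[[s]] <- parse_genotypes(df[[s]], panel[i, , drop = FALSE])
  }
  as_cohort(df, panel, age_range = age_range)
}

#' Write a cohort table to delimited text
#'
#' Genotypes are written as integer dosages, which [read_cohort()] accepts,
#' so write/read round-trips preserve every dosage and flag exactly.
#'
#' @param cohort A cohort table.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = "\t") {
  stopifnot(inherits(cohort, "cohort"))
  df <- as.data.frame(cohort)
  for (v in c(condition_flags(), "vte")) df[[v]] <- as.integer(df[[v]])
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Descriptive summary ---------------------------------------------------------

#' Per-population descriptive statistics for a cohort
#'
#' For each population: N, percentage of females, and mean with normal 95%
#' confidence interval (mean +/- 1.96 SE) for age and every quantitative
#' covariate; plus VTE case counts and percentages split by sex.
#'
#' @param cohort A cohort table.
#' @return A list of class `"cohort_summary"` with elements
#'   `characteristics` (one row per population x variable) and `vte` (one
#'   row per population x sex stratum plus totals).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  pops <- c("general", "roma")
  vars <- c("age", quantitative_covariates())

  chr <- do.call(rbind, lapply(pops, function(p) {
    sub <- cohort[cohort$population == p, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0L) {
      return(data.frame(population = p, n = 0L, pct_female = NA_real_,
                        variable = vars, mean = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, stringsAsFactors = FALSE))
    }
    pct_f <- 100 * mean(sub$sex == "female")
    do.call(rbind, lapply(vars, function(v) {
      x <- sub[[v]][!is.na(sub[[v]])]
      m <- mean(x)
      se <- if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
      data.frame(population = p, n = n, pct_female = pct_f, variable = v,
                 mean = m, ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se,
                 stringsAsFactors = FALSE)
    }))
  }))

  vte <- do.call(rbind, lapply(pops, function(p) {
    sub <- cohort[cohort$population == p, , drop = FALSE]
    strata <- list(male = sub[sub$sex == "male", , drop = FALSE],
                   female = sub[sub$sex == "female", , drop = FALSE],
                   total = sub)
    do.call(rbind, lapply(names(strata), function(s) {
      x <- strata[[s]]
      n <- nrow(x)
      cases <- sum(x$vte, na.rm = TRUE)
      data.frame(population = p, sex = s, n = n, vte_cases = cases,
                 vte_pct = if (n > 0) 100 * cases / n else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))

  structure(list(characteristics = chr, vte = vte),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort characteristics (mean, 95% CI):\n")
  print(x$characteristics, digits = 4)
  cat("\nVTE cases by population and sex:\n")
  print(x$vte, digits = 3)
  invisible(x)
}
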