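# Shared fixtures and oracles for the test suite.

# Minimal valid cohort data frame: all required columns with benign
# defaults, overridable per test.
mk_cohort_df <- function(n, population = "roma", vte = FALSE,
                         dosages = list(), ...) {
  df <- data.frame(
    subject_id = sprintf("s%06d", seq_len(n)),
    population = population, sex = "female", age = 40,
    bmi = 25, wc = 90, tc = 4.5, ldl_c = 3.0, hdl_c = 1.4, tg = 1.2,
    fbg = 5.0,
    cancer = FALSE, dm = FALSE, cad = FALSE, ckd = FALSE,
    migraine = FALSE, depression = FALSE, current_smoker = FALSE,
    quit_lt1y = FALSE, quit_ge1y = FALSE, obesity = FALSE,
    vte = vte, stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  panel <- default_snp_panel()
  for (s in panel$snp_id) {
    df[[s]] <- if (!is.null(dosages[[s]])) dosages[[s]] else 0L
  }
  df
}

mk_cohort <- function(n, ...) as_cohort(mk_cohort_df(n, ...))

# Independent HWE oracle: conditional distribution of the heterozygote
# count built from a lchoose-based combinatorial decomposition (choose the
# minor-allele homozygotes, then the heterozygotes), normalised directly.
hwe_oracle <- function(n1, h, n2) {
  n <- n1 + h + n2
  nm <- h + 2L * min(n1, n2)
  if (nm == 0L) return(1)
  hs <- seq.int(nm %% 2L, min(nm, 2L * n - nm), by = 2L)
  lw <- lchoose(n, (nm - hs) / 2) +
    lchoose(n - (nm - hs) / 2, hs) + hs * log(2)
  p <- exp(lw - max(lw))
  p <- p / sum(p)
  obs <- p[match(h, hs)]
  sum(p[p <= obs * (1 + 1e-9)])
}

# Sample skewness (g1).
skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}
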