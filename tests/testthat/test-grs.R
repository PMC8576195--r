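test_that("dosage coding reverses at flipped loci and propagates missing", {
  plain <- snp_def("rs1", "X", c("G", "A"), "A")
  flipped <- snp_def("rs2", "X", c("G", "A"), "A", flip = TRUE)
  expect_identical(code_dosage(plain, c(0L, 1L, 2L, NA)),
                   c(0L, 1L, 2L, NA))
  expect_identical(code_dosage(flipped, c(0L, 1L, 2L, NA)),
                   c(2L, 1L, 0L, NA))
  expect_error(code_dosage(plain, 3L))
})

test_that("score arithmetic matches its definition", {
  panel <- snp_panel(
    snp_def("s1", "A", c("G", "A"), "A", weight = 0.5),
    snp_def("s2", "B", c("G", "A"), "A", weight = 0.3),
    snp_def("s3", "C", c("G", "A"), "A", weight = 0.2),
    snp_def("s4", "D", c("G", "A"), "A", weight = 0.1),
    snp_def("s5", "E", c("G", "A"), "A", weight = 0.4)
  )
  df <- mk_cohort_df(1)
  for (s in panel$snp_id) df[[s]] <- NULL
  d <- c(1L, 0L, 2L, 0L, 1L)
  for (i in 1:5) df[[panel$snp_id[i]]] <- d[i]
  cohort <- as_cohort(df, panel)
  expect_equal(compute_grs(cohort, mode = "weighted")$score, 1.3)
  expect_equal(compute_grs(cohort, mode = "unweighted")$score, 4)
})

test_that("unweighted scores are integers within [0, 2m]; missing excluded", {
  spec <- generator_spec(n = c(general = 150L, roma = 150L))
  cohort <- simulate_cohort(spec, seed = 3L)
  cohort$rs6025[1:5] <- NA
  u <- compute_grs(cohort, mode = "unweighted")
  expect_equal(u$n_excluded, 5L)
  sc <- u$score[!is.na(u$score)]
  expect_true(all(sc == round(sc)))
  expect_true(all(sc >= 0 & sc <= 12))
  # weighted mode refuses a weightless SNP in the panel
  expect_error(compute_grs(cohort, panel = cohort_panel(cohort),
                           mode = "weighted"), "requires a weight")
  # default weighted panel excludes the unweighted founder SNP
  w <- compute_grs(cohort, mode = "weighted")
  expect_equal(nrow(w$panel), 5)
})

test_that("relabelling alleles while toggling flip leaves scores unchanged", {
  set.seed(21)
  n <- 200
  geno_text <- sample(c("G/G", "G/A", "A/A"), n, replace = TRUE)
  base_df <- mk_cohort_df(n)
  p1 <- snp_panel(snp_def("rs2066865", "FGG", c("G", "A"), "A"))
  p2 <- snp_panel(snp_def("rs2066865", "FGG", c("G", "A"), "G",
                          flip = TRUE))
  for (s in setdiff(default_snp_panel()$snp_id, "rs2066865")) {
    base_df[[s]] <- NULL
  }
  df1 <- base_df; df1$rs2066865 <- parse_genotypes(geno_text, p1[1, ])
  df2 <- base_df; df2$rs2066865 <- parse_genotypes(geno_text, p2[1, ])
  s1 <- compute_grs(as_cohort(df1, p1), mode = "unweighted")$score
  s2 <- compute_grs(as_cohort(df2, p2), mode = "unweighted")$score
  expect_equal(s1, s2)
})

test_that("median dichotomization sends ties to the high group", {
  sc <- c(0, 1, 3, 3, 3, 5, 6)
  band <- grs_band(sc, "median")
  expect_true(all(band[sc >= 3] == "high"))
  expect_true(all(band[sc < 3] == "low"))
  expect_gte(mean(band == "high"), 0.5)
})

test_that("uGRS distribution matches the binomial convolution", {
  spec <- generator_spec(n = c(roma = 100000L))
  set.seed(8)
  g <- generate_genotypes(spec, "roma")
  score <- rowSums(g)
  freqs <- spec$freqs$roma
  pmf <- 1
  for (p in freqs) pmf <- convolve(pmf, rev(dbinom(0:2, 2, p)),
                                   type = "open")
  expected <- pmf * length(score)
  obs <- tabulate(score + 1L, nbins = length(pmf))
  keep <- expected >= 5
  chi2 <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  p_gof <- pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p_gof, 0.001)
})

test_that("band odds ratio recovers a planted band effect", {
  set.seed(77)
  n <- 50000
  score <- sample(0:6, n, replace = TRUE)
  band_high <- score >= 3
  band_low <- score <= 1
  p <- ifelse(band_high, plogis(qlogis(0.02) + 1.0), 0.02)
  df <- mk_cohort_df(n, vte = runif(n) < p)
  cohort <- as_cohort(df)
  est <- grs_stratified_or(cohort, score, low_band = c(0, 1), high_cut = 3)
  expect_true(est$or >= 2.3 && est$or <= 3.2)
  expect_equal(sum(est$counts),
               sum(band_high) + sum(band_low))
})

test_that("equal band prevalence gives OR near 1; empty-case bands flag", {
  set.seed(123)
  n <- 40000
  score <- sample(0:6, n, replace = TRUE)
  df <- mk_cohort_df(n, vte = runif(n) < 0.05)
  est <- grs_stratified_or(as_cohort(df), score)
  expect_equal(est$or, 1, tolerance = 0.25)
  # zero cases in the high band: Haldane keeps the OR finite and flags
  vte2 <- runif(n) < 0.01
  vte2[score >= 3] <- FALSE
  est2 <- grs_stratified_or(as_cohort(mk_cohort_df(n, vte = vte2)), score)
  expect_true(is.finite(est2$or) && est2$or < 1)
  expect_true(est2$separation)
  # no cases anywhere: undefined
  expect_warning(
    est3 <- grs_stratified_or(as_cohort(mk_cohort_df(n, vte = FALSE)),
                              score),
    "undefined")
  expect_true(est3$undefined)
})

test_that("environment OR within the high-score stratum behaves", {
  set.seed(55)
  n <- 50000
  score <- sample(0:6, n, replace = TRUE)
  mig <- runif(n) < 0.3
  p <- plogis(qlogis(0.03) + 1.2 * (mig & score >= 3))
  cohort <- as_cohort(mk_cohort_df(n, migraine = mig, vte = runif(n) < p))
  est <- grs_env_joint_or(cohort, score, "migraine", high_cut = 3)
  expect_lt(abs(log(est$or) - 1.2), 0.15)
  # constant flag in stratum errors
  expect_error(
    grs_env_joint_or(cohort, score, rep(TRUE, n), high_cut = 3),
    "constant")
})

test_that("null-effect CIs cover 1 at close to nominal rate", {
  set.seed(404)
  cover <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    n <- 2000
    score <- sample(0:6, n, replace = TRUE)
    env <- runif(n) < 0.4
    cohort <- as_cohort(mk_cohort_df(n, migraine = env,
                                     vte = runif(n) < 0.08))
    est <- grs_env_joint_or(cohort, score, "migraine", high_cut = 3)
    if (est$ci_lo <= 1 && 1 <= est$ci_hi) cover <- cover + 1L
  }
  expect_gte(cover / n_rep, 0.9)
})
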