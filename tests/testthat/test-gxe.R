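test_that("rank-based inverse-normal transform keeps moments and order", {
  x <- c(1, 2, 3, 4, 5)
  tx <- templeton_transform(x)
  expect_equal(tx[3], 3)  # median maps to the mean
  expect_equal(mean(tx), mean(x), tolerance = 1e-9)
  expect_equal(sd(tx), sd(x), tolerance = 1e-9)
  set.seed(9)
  y <- rexp(500)
  ty <- templeton_transform(y)
  expect_identical(order(ty), order(y))
  expect_equal(mean(ty), mean(y), tolerance = 1e-6 * abs(mean(y)))
  expect_equal(sd(ty), sd(y), tolerance = 1e-6 * sd(y))
  expect_error(templeton_transform(rep(2, 10)), "distinct")
})

test_that("transform normalises a log-normal sample", {
  set.seed(31)
  x <- rlnorm(10000, 0, 1)
  tx <- templeton_transform(x)
  expect_gt(skewness(x), 2)
  expect_lt(abs(skewness(tx)), 0.05)
  # oracle: the skewness of the exact normal quantiles at those ranks
  z <- qnorm(rank(x) / (length(x) + 1))
  expect_equal(skewness(tx), skewness(z), tolerance = 1e-8)
})

test_that("interaction design holds the elementwise product and cut-offs", {
  df <- mk_cohort_df(3, dosages = list(rs2066865 = c(0L, 1L, 2L)),
                     ldl_c = c(3.0, 3.4, 4.0), age = c(30, 40, 50))
  # single-level exposures are rejected
  cohort <- as_cohort(df)
  expect_error(build_interaction_design(cohort, "rs2066865", "migraine"),
               "single level")
  des <- build_interaction_design(cohort, "rs2066865", "ldl_high")
  expect_equal(des$E, c(0L, 1L, 1L))
  expect_equal(des$GxE, des$G * des$E)
  expect_equal(des$GxE, c(0L, 1L, 2L) * c(0L, 1L, 1L))
  dom <- build_interaction_design(cohort, "rs2066865", "ldl_high",
                                  genetic_coding = "dominant")
  expect_equal(dom$G, c(0L, 1L, 1L))
  # explicit product example
  df2 <- mk_cohort_df(3, dosages = list(rs6025 = c(0L, 1L, 2L)),
                      migraine = c(TRUE, FALSE, TRUE))
  des2 <- build_interaction_design(as_cohort(df2), "rs6025", "migraine")
  expect_equal(des2$GxE, c(0L, 0L, 2L))
  # constant columns (age here) are dropped with a report
  expect_true("age" %in% attr(des2, "dropped"))
})

test_that("linear-probability fit standardizes coefficients correctly", {
  set.seed(12)
  n <- 400
  x <- rnorm(n)
  y <- as.integer(runif(n) < plogis(-2 + x))
  xs <- (x - mean(x)) / sd(x)
  fit <- fit_gxe_linear(data.frame(x = xs), y)
  expect_equal(fit$beta_std[["x"]], fit$coef[["x"]] * sd(xs) / sd(y),
               tolerance = 1e-12)
  # with an SD-1 predictor, beta_std = coef / sd(y)
  expect_equal(fit$beta_std[["x"]] * sd(y), fit$coef[["x"]],
               tolerance = 1e-10)
  expect_error(fit_gxe_linear(data.frame(a = x, b = 2 * x), y),
               "collinear")
})

test_that("saturated binary design reproduces the cell prevalences", {
  set.seed(44)
  n <- 2000
  G <- rbinom(n, 1, 0.5)
  E <- rbinom(n, 1, 0.4)
  y <- as.integer(runif(n) < (0.05 + 0.03 * G + 0.02 * E + 0.05 * G * E))
  des <- data.frame(G = G, E = E, GxE = G * E)
  fit <- fit_gxe_linear(des, y)
  for (g in 0:1) for (e in 0:1) {
    idx <- G == g & E == e
    expect_equal(unique(round(fit$fitted[idx], 10)),
                 round(mean(y[idx]), 10))
  }
})

test_that("interaction term sign tracks a planted joint excess risk", {
  set.seed(272)
  n_rep <- 200L
  pos <- 0L
  for (r in seq_len(n_rep)) {
    n <- 5000
    G <- rbinom(n, 2, 0.28)
    E <- as.integer(runif(n) < 0.3)
    p <- 0.02 + 0.005 * G + 0.01 * E + 0.02 * G * E
    y <- as.integer(runif(n) < p)
    fit <- fit_gxe_linear(data.frame(G = G, E = E, GxE = G * E), y)
    if (fit$beta_std[["GxE"]] > 0) pos <- pos + 1L
  }
  expect_gte(pos / n_rep, 0.95)
})

test_that("stratum odds ratios are exact cross-products of the cells", {
  n_cell <- c(`00` = 102, `01` = 104, `10` = 104, `11` = 116)
  G <- c(rep(0, 102), rep(1, 104), rep(0, 104), rep(1, 116))
  E <- c(rep(FALSE, 102 + 104), rep(TRUE, 104 + 116))
  vte <- c(rep(TRUE, 2), rep(FALSE, 100),   # G=0 E=0: 2/100
           rep(TRUE, 4), rep(FALSE, 100),   # G=1 E=0: 4/100
           rep(TRUE, 4), rep(FALSE, 100),   # G=0 E=1: 4/100
           rep(TRUE, 16), rep(FALSE, 100))  # G=1 E=1: 16/100
  cohort <- as_cohort(mk_cohort_df(sum(n_cell), migraine = E, vte = vte,
                                   dosages = list(rs6025 = as.integer(G))))
  s <- stratum_ors(cohort, "rs6025", "migraine")
  expect_equal(s$or00, 1)
  expect_equal(s$or01, 2)
  expect_equal(s$or10, 2)
  expect_equal(s$or11, 8)
  cl <- classify_interaction(s)
  expect_equal(cl$reri, s$or11 - s$or01 - s$or10 + 1)
  expect_equal(cl$multiplicative_verdict, "synergistic")
})

test_that("classifier verdict grid follows the defining inequalities", {
  cases <- list(
    list(2, 3, 6, "none", "synergistic"),        # product; RERI = 2
    list(2, 3, 8, "synergistic", "synergistic"),
    list(2, 3, 4, "antagonistic", "none"),       # RERI = 0
    list(2, 3, 3, "antagonistic", "antagonistic"),
    list(1, 1, 1, "none", "none"),
    list(0.5, 0.5, 0.25, "none", "synergistic"), # 0.25 > 0.5+0.5-1
    list(2, 2, 3, "antagonistic", "none"),
    list(2, 2, 5, "synergistic", "synergistic"),
    list(3, 2, 2, "antagonistic", "antagonistic")
  )
  for (cs in cases) {
    cl <- classify_interaction(make_stratum_ors(cs[[1]], cs[[2]], cs[[3]]))
    expect_equal(cl$multiplicative_verdict, cs[[4]],
                 label = paste(unlist(cs[1:3]), collapse = ","))
    expect_equal(cl$additive_verdict, cs[[5]],
                 label = paste(unlist(cs[1:3]), collapse = ","))
  }
  # verdicts are invariant to swapping the roles of G and E
  cl_a <- classify_interaction(make_stratum_ors(2, 5, 7))
  cl_b <- classify_interaction(make_stratum_ors(5, 2, 7))
  expect_equal(cl_a$multiplicative_verdict, cl_b$multiplicative_verdict)
  expect_equal(cl_a$additive_verdict, cl_b$additive_verdict)
  expect_equal(cl_a$reri, cl_b$reri)
})

test_that("flagged stratum sets propagate through classification", {
  n <- 50
  cohort <- as_cohort(mk_cohort_df(n, migraine = rep(c(TRUE, FALSE), 25),
                                   vte = rep(c(TRUE, FALSE), c(5, 45)),
                                   dosages = list(rs6025 = 0L)))
  s <- stratum_ors(cohort, "rs6025", "migraine")  # no carriers: empty cells
  expect_true(s$flagged)
  cl <- classify_interaction(s)
  expect_true(cl$flagged)
  expect_true(is.na(cl$multiplicative_verdict))
})

test_that("logistic main-effects data are multiplicative-null, additive-synergistic", {
  set.seed(606)
  n <- 200000
  G <- as.integer(rbinom(n, 2, 0.3) >= 1)
  E <- as.integer(runif(n) < 0.3)
  p <- plogis(qlogis(0.05) + 0.8 * G + 0.9 * E)
  cohort <- as_cohort(mk_cohort_df(n, migraine = E == 1,
                                   vte = runif(n) < p,
                                   dosages = list(rs6025 = G)))
  s <- stratum_ors(cohort, "rs6025", "migraine")
  expect_equal(s$or11 / (s$or01 * s$or10), 1, tolerance = 0.1)
  # the known scale-dependence: odds-multiplicative data are
  # additive-synergistic
  cl <- classify_interaction(s)
  expect_equal(cl$additive_verdict, "synergistic")
  expect_gt(cl$reri, 0)
})

test_that("bootstrap verdicts agree with a strongly planted interaction", {
  set.seed(31415)
  n <- 4000
  G <- as.integer(rbinom(n, 2, 0.3) >= 1)
  E <- as.integer(runif(n) < 0.3)
  p <- 0.02 + 0.01 * G + 0.01 * E + 0.20 * G * E
  cohort <- as_cohort(mk_cohort_df(n, migraine = E == 1,
                                   vte = runif(n) < p,
                                   dosages = list(rs6025 = G)))
  bs <- bootstrap_interaction(cohort, "rs6025", "migraine",
                              n_boot = 200, seed = 5L)
  expect_equal(bs$point$multiplicative_verdict, "synergistic")
  expect_equal(bs$mult_verdict_ci, "synergistic")
  expect_equal(bs$additive_verdict_ci, "synergistic")
  expect_gt(bs$n_boot_used, 150)
})

test_that("gxe report covers the SNP x exposure x population grid", {
  fx <- make_paper_fixture()
  rep <- gxe_report(fx, exposures = c("ldl_high", "tc_high"),
                    snp_ids = c("rs2066865", "rs6025"), add_bh = TRUE)
  expect_equal(nrow(rep), 8)  # 2 SNPs x 2 exposures x 2 populations
  expect_true(all(c("beta_std", "p_interaction", "reri", "p_bh")
                  %in% names(rep)))
  # fixture covariates are constant at the population mean, so the lipid
  # exposures have a single level and every row is flagged, not dropped
  expect_true(all(rep$flagged))
})
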