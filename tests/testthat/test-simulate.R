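test_that("generation is deterministic under a fixed seed", {
  spec <- generator_spec(n = c(general = 100L, roma = 100L))
  c1 <- simulate_cohort(spec, seed = 42L)
  c2 <- simulate_cohort(spec, seed = 42L)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- simulate_cohort(spec, seed = 43L)
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
})

test_that("genotypes honour the specified frequencies and HWE", {
  spec <- generator_spec(n = c(roma = 100000L))
  set.seed(17)
  g <- generate_genotypes(spec, "roma")
  # the founder allele is absent where its frequency is zero
  spec0 <- generator_spec(n = c(general = 5000L))
  set.seed(18)
  g0 <- generate_genotypes(spec0, "general")
  expect_true(all(g0[, "rs121909567"] == 0L))
  # sample frequency within binomial error of the target
  f_hat <- mean(g[, "rs2066865"]) / 2
  expect_lt(abs(f_hat - 0.28), 0.005)
  counts <- tabulate(g[, "rs2066865"] + 1L, nbins = 3L)
  expect_gt(hwe_exact_test(counts), 0.001)
})

test_that("generated genotypes pass the HWE exact test at high rate", {
  set.seed(29)
  spec <- generator_spec(n = c(roma = 10000L))
  n_pass <- 0L
  n_tot <- 0L
  for (r in 1:20) {
    g <- generate_genotypes(spec, "roma")
    for (s in colnames(g)) {
      counts <- tabulate(g[, s] + 1L, nbins = 3L)
      if (counts[2] + 2 * min(counts[1], counts[3]) == 0) next
      n_tot <- n_tot + 1L
      if (suppressMessages(hwe_exact_test(counts)) > 0.001) {
        n_pass <- n_pass + 1L
      }
    }
  }
  expect_gte(n_pass / n_tot, 0.99)
})

test_that("outcome prevalence follows the intercept; covariates follow spec", {
  spec <- generator_spec(
    n = c(roma = 100000L),
    outcome = list(intercept = qlogis(0.03), genetic = NULL, env = NULL,
                   age = 0, gxe = NULL)
  )
  cohort <- simulate_cohort(spec, seed = 101L)
  expect_equal(100 * mean(cohort$vte), 3.0, tolerance = 0.2)
  # moment-matched log-normal TG keeps the target mean and right skew
  expect_equal(mean(cohort$tg), 1.7, tolerance = 0.05)
  expect_gt(skewness(cohort$tg), 0.5)
  expect_equal(mean(cohort$ldl_c), 3.1, tolerance = 0.05)
  # obesity is BMI-derived, not drawn
  expect_identical(cohort$obesity, cohort$bmi > 30)
})

test_that("zero-variance covariates stay constant and are reported dropped", {
  cv <- generator_spec()$covariates
  cv$roma["ldl_c", "sd"] <- 0
  spec <- generator_spec(n = c(roma = 300L), covariates = cv)
  cohort <- simulate_cohort(spec, seed = 7L)
  expect_equal(length(unique(cohort$ldl_c)), 1L)
  des <- build_interaction_design(cohort, "rs2066865", "current_smoker",
                                  covariates = c("age", "ldl_c"))
  expect_false("ldl_c" %in% names(des))
  expect_true("ldl_c" %in% attr(des, "dropped"))
})

test_that("an infeasible outcome model is rejected with advice", {
  expect_error(generator_spec(outcome = list(intercept = Inf)),
               "prevalence")
})

test_that("the table-derived fixture reproduces every published cell", {
  fx <- make_paper_fixture()
  expect_equal(sum(fx$population == "general"), 406)
  expect_equal(sum(fx$population == "roma"), 395)
  expect_equal(sum(fx$vte[fx$population == "general"]), 6)
  expect_equal(sum(fx$vte[fx$population == "roma"]), 12)
  # spot-check full genotype x outcome cells
  roma <- fx[fx$population == "roma", ]
  cells <- function(s, d) {
    c(sum(roma[[s]] == d & roma$vte), sum(roma[[s]] == d & !roma$vte))
  }
  expect_equal(cells("rs2066865", 0), c(5, 201))
  expect_equal(cells("rs2066865", 1), c(4, 156))
  expect_equal(cells("rs2066865", 2), c(3, 26))
  expect_equal(cells("rs6025", 1), c(4, 56))
  expect_equal(cells("rs121909567", 1), c(0, 11))
  gen <- fx[fx$population == "general", ]
  expect_true(all(gen$rs121909567 == 0L))  # founder allele absent
  expect_equal(sum(gen$rs1799963 == 1 & !gen$vte), 16)
  # sex x outcome margins
  expect_equal(sum(roma$sex == "female" & roma$vte), 8)
  expect_equal(sum(gen$sex == "male" & !gen$vte), 177)
})

test_that("a planted interaction is recovered by the logistic mirror", {
  spec <- generator_spec(
    n = c(roma = 150000L),
    outcome = list(intercept = qlogis(0.02),
                   genetic = c(rs2066865 = 0.3),
                   env = c(current_smoker = 0.4), age = 0,
                   gxe = list(list(snp = "rs2066865",
                                   env = "current_smoker", beta = 1.0)))
  )
  cohort <- simulate_cohort(spec, seed = 2025L)
  des <- build_interaction_design(cohort, "rs2066865", "current_smoker",
                                  covariates = character(0))
  fit <- fit_logistic(des, attr(des, "outcome") == 1L)
  expect_lt(abs(fit$coef[["GxE"]] - 1.0), 0.1)
  expect_lt(abs(fit$coef[["G"]] - 0.3), 0.1)
  expect_lt(abs(fit$coef[["E"]] - 0.4), 0.1)
})
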