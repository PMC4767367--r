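test_that("two-sample regression matches closed form and hand sandwich", {
  tab <- toy_table(a = c(1, 2, 3), b = c(2, 3, 4))
  cmp <- fit_adjusted_comparison(tab[rep(1:6, 2), ] |>
                                   dplyr::mutate(family_id = sprintf("F%02d", 1:12)),
                                 "outcome", covariates = character(0))
  expect_equal(cmp$beta, 1.0, tolerance = 1e-12)

  # conventional OLS SE for the duplicated design and robust SE vs the
  # hand-computed sandwich with the same small-sample factor
  tab12 <- tab[rep(1:6, 2), ]
  tab12$family_id <- sprintf("F%02d", 1:12)
  X <- cbind(1, as.numeric(tab12$risk_group))
  colnames(X) <- c("(Intercept)", ".group")
  se_hand <- naive_cluster_se(X, tab12$outcome, tab12$family_id, ".group")
  expect_equal(cmp$se_robust, se_hand, tolerance = 1e-10)

  # classical SE on the 3v3 toy equals sqrt(s2*(1/3+1/3)) = 0.8165
  fit <- lm(outcome ~ risk_group, data = toy_table())
  expect_equal(unname(sqrt(diag(vcov(fit)))[2]), sqrt(2 / 3),
               tolerance = 1e-9)
  expect_equal(round(sqrt(2 / 3), 4), 0.8165)
})

test_that("degenerate outcomes are handled: constant and log-constant", {
  tab <- toy_table(a = rep(4, 5), b = rep(4, 5))
  tab$family_id <- sprintf("F%02d", 1:10)
  cmp <- suppressWarnings(
    fit_adjusted_comparison(tab, "outcome", covariates = character(0)))
  expect_equal(cmp$beta, 0, tolerance = 1e-12)
  expect_equal(cmp$p_model, 1)

  tab2 <- toy_table(a = rep(2, 5), b = rep(2, 5))
  tab2$family_id <- sprintf("F%02d", 1:10)
  gm <- suppressWarnings(
    fit_adjusted_comparison(tab2, "outcome", covariates = character(0),
                            log_scale = TRUE))
  expect_equal(gm$group_means$mean, c(2, 2), tolerance = 1e-12)
  expect_equal(gm$group_means$upr - gm$group_means$lwr, c(0, 0),
               tolerance = 1e-12)
})

test_that("cluster-robust SE equals HC1 with singleton clusters", {
  withr::local_seed(55)
  n <- 60
  tab <- tibble::tibble(
    outcome = rnorm(n, 5),
    risk_group = rep(c(FALSE, TRUE), n / 2),
    age = rnorm(n, 60, 5),
    family_id = sprintf("F%03d", 1:n)
  )
  cmp <- fit_adjusted_comparison(tab, "outcome", covariates = "age")
  vc_hc1 <- sandwich::vcovHC(cmp$model, type = "HC1")
  expect_equal(cmp$se_robust, sqrt(vc_hc1[".group", ".group"]),
               tolerance = 1e-10)
})

test_that("singular designs fail with the collinear column named", {
  tab <- toy_table(a = c(1, 2, 3, 4, 5), b = c(2, 3, 4, 5, 6))
  tab$family_id <- sprintf("F%02d", 1:10)
  tab$dup <- as.numeric(tab$risk_group)
  expect_error(fit_adjusted_comparison(tab, "outcome", covariates = "dup"),
               "collinear.*dup")
})

test_that("geometric means converge to the sample geometric mean", {
  withr::local_seed(66)
  n <- 400
  tab <- tibble::tibble(
    outcome = exp(rnorm(n, log(2.2), 0.4)),
    risk_group = rep(c(FALSE, TRUE), n / 2),
    family_id = sprintf("F%03d", 1:n)
  )
  cmp <- fit_adjusted_comparison(tab, "outcome", covariates = character(0),
                                 log_scale = TRUE)
  gmean_cc <- exp(mean(log(tab$outcome[!tab$risk_group])))
  expect_equal(cmp$group_means$mean[1], gmean_cc, tolerance = 1e-10)
  expect_true(cmp$group_means$lwr[1] <= cmp$group_means$mean[1])
  expect_true(cmp$group_means$upr[1] >= cmp$group_means$mean[1])
})

test_that("permutation p agrees with exhaustive enumeration on 6 singletons", {
  tab <- toy_table(a = c(1.2, 2.1, 2.9), b = c(2.2, 3.1, 3.8))
  # exhaustive reference over all choose(6,3) = 20 label arrangements
  y <- tab$outcome
  combs <- utils::combn(6, 3)
  betas <- apply(combs, 2, function(idx) {
    g <- rep(0, 6); g[idx] <- 1
    abs(coef(lm(y ~ g))[2])
  })
  obs <- abs(coef(lm(y ~ as.numeric(tab$risk_group)))[2])
  p_exact <- mean(betas >= obs - 1e-12)

  suppressWarnings(
    p_mc <- permutation_pvalue(tab, "outcome", covariates = character(0),
                               n_perm = 2000, seed = 77))
  # MC estimate within 3 binomial SE of the exhaustive value
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(p_mc - p_exact), 3 * se + 1 / 2001)
})

test_that("permutation p-value is deterministic given a seed and add-one bounded", {
  withr::local_seed(88)
  tab <- simulate_outcome_table(cohort_config(n_participants = 60, seed = 3),
                                seed = 3)
  p1 <- permutation_pvalue(tab, "mean_nocturnal", n_perm = 99, seed = 5)
  p2 <- permutation_pvalue(tab, "mean_nocturnal", n_perm = 99, seed = 5)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 100)
  expect_lte(p1, 1)

  # perfectly separated outcome: p at the add-one floor
  sep <- toy_table(a = c(1, 1.1, 0.9, 1.05, 0.95),
                   b = c(9, 9.1, 8.9, 9.05, 8.95))
  sep$family_id <- sprintf("F%02d", 1:10)
  p_sep <- permutation_pvalue(sep, "outcome", covariates = character(0),
                              n_perm = 200, seed = 9)
  # only the identity and complement relabelings (2 of choose(10,5) = 252)
  # reach |beta|; the add-one estimator keeps p above 1/201 and tiny
  expect_gte(p_sep, 1 / 201)
  expect_lt(p_sep, 0.05)
})

test_that("interaction test flags real interactions and rejects collinear ones", {
  withr::local_seed(99)
  n <- 200
  tab <- tibble::tibble(
    risk_group = rep(c(FALSE, TRUE), n / 2),
    med = rnorm(n, 10, 2),
    family_id = sprintf("F%03d", 1:n)
  )
  # pure multiplicative outcome
  tab$outcome <- as.numeric(tab$risk_group) * tab$med + rnorm(n, 0, 0.1)
  p <- interaction_test(tab, "outcome", mediator = "med",
                        covariates = character(0))
  expect_lt(p, 1e-6)

  # additive outcome: interaction null
  tab$outcome2 <- as.numeric(tab$risk_group) + 0.5 * tab$med + rnorm(n)
  p2 <- interaction_test(tab, "outcome2", mediator = "med",
                         covariates = character(0))
  expect_gt(p2, 0.001)

  tab$const <- 3
  expect_error(interaction_test(tab, "outcome", mediator = "const",
                                covariates = character(0)),
               "collinear")
})

test_that("percent mediated matches hand arithmetic and is scale-invariant", {
  expect_equal(round(percent_mediated(0.17, 0.11), 2), 35.29)
  expect_equal(percent_mediated(0.4, 0.4), 0)
  expect_equal(percent_mediated(0.2, 0), 100)
  expect_error(percent_mediated(0, 0.1), "undefined")
  # rescaling the outcome rescales both coefficients, not the percentage
  expect_equal(percent_mediated(0.17 * 18, 0.11 * 18),
               percent_mediated(0.17, 0.11), tolerance = 1e-12)
})

test_that("mediation recovers null, partial and full mediation structures", {
  withr::local_seed(111)
  # null mediators: independent of group and outcome
  n <- 600
  tab <- tibble::tibble(
    risk_group = rep(c(FALSE, TRUE), n / 2),
    weight = rnorm(n, 77, 12),
    pbf = rnorm(n, 31, 8),
    age = rnorm(n, 64, 6),
    sex = sample(c("female", "male"), n, TRUE),
    offspring = sample(c("offspring", "partner"), n, TRUE),
    family_id = sprintf("F%03d", 1:n)
  )
  tab$outcome <- 4.5 + 0.3 * tab$risk_group + rnorm(n, 0, 0.3)
  med <- run_mediation(tab, "outcome")
  expect_lt(abs(med$percent_mediated), 15)
  expect_equal(med$n_analyzed, n)

  # fully mediated generator: no direct effect
  cfg_full <- config_with_mediated_fraction(
    0.3, 1, cohort_config(n_participants = 1500, noise_sd = 0.3,
                          family_intercept_sd = 0))
  tab_full <- simulate_outcome_table(cfg_full, seed = 12)
  med_full <- run_mediation(tab_full, "mean_nocturnal")
  expect_gt(med_full$percent_mediated, 80)
  expect_lt(med_full$percent_mediated, 120)
})

test_that("complete-case mediation uses identical rows for both models", {
  withr::local_seed(123)
  tab <- simulate_outcome_table(cohort_config(n_participants = 80, seed = 8),
                                seed = 8)
  tab$weight[1:10] <- NA
  med <- run_mediation(tab, "mean_nocturnal")
  expect_equal(med$n_analyzed, sum(!is.na(tab$weight) &
                                     !is.na(tab$mean_nocturnal)))
})

test_that("HWE chi-square test matches hand-computed values", {
  exact <- hwe_test(25, 50, 25)
  expect_equal(exact$chisq, 0)
  expect_equal(exact$p_value, 1)

  dev <- hwe_test(30, 40, 30)
  expect_equal(dev$chisq, 4.0, tolerance = 1e-12)
  expect_equal(dev$p_value, pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(dev$p_value, 4), 0.0455)

  expect_lt(hwe_test(100, 0, 100)$p_value, 1e-40)
  expect_message(mono <- hwe_test(50, 0, 0), "monomorphic")
  expect_equal(mono$p_value, 1)
})
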