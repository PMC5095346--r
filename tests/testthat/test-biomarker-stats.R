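test_that("median dichotomization assigns ties to low and preserves missing", {
  expect_identical(as.character(dichotomize_median(c(1, 2, 3, 4))),
                   c("low", "low", "high", "high"))
  # median 2: ties at the median go to low
  expect_identical(as.character(dichotomize_median(c(1, 2, 2, 3))),
                   c("low", "low", "low", "high"))
  lab <- dichotomize_median(c(1, NA, 3, 4))
  expect_true(is.na(lab[2]))
  expect_error(dichotomize_median(c(2, 2, 2)), "identical")
  expect_error(dichotomize_median(c(1, NA, NA)), "at least 2")

  # counting property: with ties sent to "low", the split imbalance for an
  # odd-sized sample is n_low - n_high = 2 * #(<= median) - n, which is at
  # least 1 and at most 2 * ties - 1
  set.seed(3)
  for (i in 1:5) {
    v <- sample(1:40, 291, replace = TRUE)
    lab <- dichotomize_median(v)
    ties <- sum(v == median(v))
    imb <- sum(lab == "low") - sum(lab == "high")
    expect_gte(imb, 1L)
    expect_lte(imb, 2L * ties - 1L)
  }
})

test_that("Spearman correlation matches the hand-ranked oracle", {
  expect_equal(spearman_corr(1:4 * 1.0, c(10, 20, 30, 40) * 1.0)$rho, 1)
  expect_equal(spearman_corr(1:4 * 1.0, c(30, 20, 10, 5))$rho, -1)
  # tie fixture: ranks x = (1, 2.5, 2.5, 4), y = (1, 3, 2, 4)
  # hand computation: cov = 4.5, var_x = 4.5, var_y = 5 -> rho = 0.9486833
  got <- spearman_corr(c(1, 2, 2, 3), c(1, 3, 2, 4))
  expect_equal(got$rho, 4.5 / sqrt(4.5 * 5), tolerance = 1e-9)
  expect_p_value(got$p)
  expect_error(spearman_corr(c(1, 1, 1, 1), 1:4), "constant")
  expect_error(spearman_corr(1:3, 1:3), "4 complete pairs")
})

test_that("group comparisons choose the right test and calibrate under the null", {
  # identical groups: no evidence, p = 1
  same <- group_compare(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_identical(same$method, "mann-whitney")
  expect_equal(same$p, 1, tolerance = 0.05)

  # fully separated 3 vs 3: U = 0, smallest exact two-sided p = 2/choose(6,3) = 0.1
  sep <- group_compare(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_identical(unname(sep$statistic), 0)
  expect_equal(sep$p, 0.1, tolerance = 1e-9)

  kk <- group_compare(c(1, 5, 2, 8, 3, 9), rep(c("a", "b", "c"), each = 2))
  expect_identical(kk$method, "kruskal-wallis")
  expect_p_value(kk$p)

  expect_error(group_compare(1:4, c("a", "a", "a", NA)), "2 non-empty groups")

  # type-I error of the three-group test at alpha = 0.05 over 1000 sims
  set.seed(77)
  rej <- mean(replicate(1000, {
    group_compare(rnorm(30), rep(c("a", "b", "c"), each = 10))$p < 0.05
  }))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("Kaplan-Meier product-limit and log-rank match hand computation", {
  # 5-subject fixture: times 1,2,3,4,5; events 1,1,0,1,0
  # S(t>=4) = 4/5 * 3/4 * 1/2 = 0.3
  km <- km_logrank(c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5),
                   c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0),
                   rep(c("g1", "g2"), each = 5))
  s <- summary(km$fit, times = 5, extend = TRUE)
  expect_equal(unname(s$surv), c(0.3, 0.3), tolerance = 1e-9)
  # identical groups: chi-square 0, p = 1
  expect_equal(km$chisq, 0, tolerance = 1e-9)
  expect_equal(km$p, 1, tolerance = 1e-9)

  # power: true HR 2 with n = 500/arm is detected at p < 0.001
  set.seed(15)
  hits <- replicate(20, {
    t1 <- rexp(500, 0.01); t2 <- rexp(500, 0.02)
    km_logrank(c(t1, t2), rep(1, 1000), rep(c("a", "b"), each = 500))$p < 0.001
  })
  expect_gte(mean(hits), 0.99)

  expect_error(km_logrank(1:3, c(1, 1, 1), c("a", "a", "a")), "2 non-empty groups")
})

test_that("Cox models recover planted hazard ratios and behave symmetrically", {
  d <- gen_cohort(n = 2000, marker_loghr = log(2), seed = 42)
  fit <- cox_model(d, "TTR", "marker_high")
  hr <- fit$table$hazard_ratio
  expect_gt(hr, 1.8); expect_lt(hr, 2.2)
  expect_true(fit$table$ci95_lower <= hr && hr <= fit$table$ci95_upper)
  expect_lt(fit$table$p_value, 0.001)

  # recoding the covariate inverts the hazard ratio exactly
  d$marker_low <- 1L - d$marker_high
  fit2 <- cox_model(d, "TTR", "marker_low")
  expect_equal(fit2$table$hazard_ratio, 1 / hr, tolerance = 1e-6)

  # case-order permutation invariance
  set.seed(9)
  fit3 <- cox_model(d[sample(nrow(d)), ], "TTR", "marker_high")
  expect_equal(fit3$table$hazard_ratio, hr, tolerance = 1e-8)

  # coverage under the null: the 95% CI contains 1 in about 95% of fits
  set.seed(31)
  cover <- mean(replicate(300, {
    dn <- gen_cohort(n = 150, seed = sample.int(1e6, 1))
    tb <- cox_model(dn, "TTR", "marker_high")$table
    tb$ci95_lower <= 1 && 1 <= tb$ci95_upper
  }))
  expect_gt(cover, 0.90); expect_lt(cover, 0.99)

  expect_error(cox_model(d, "TTR", "nonexistent"))
  d$const <- 1
  expect_error(cox_model(d, "TTR", "const"), "constant covariate")
})

test_that("multivariate Cox handles the standard covariate set with listwise deletion", {
  d <- gen_cohort(n = 600, marker_loghr = log(2.5), seed = 77)
  d$age_ge_66 <- ifelse(d$age_years >= 66, "ge66", "lt66")
  d$mmr[1:25] <- NA
  fit <- cox_model(d, "TTR",
                   c("marker_high", "stage", "sex", "age_ge_66", "mmr",
                     "site", "tbc"))
  expect_identical(fit$n_used, 575L)
  expect_true(all(fit$table$hazard_ratio > 0))
  expect_true(all(fit$table$ci95_lower <= fit$table$ci95_upper))
  expect_true(all(fit$table$p_value >= 0 & fit$table$p_value <= 1))
  # the planted marker effect survives adjustment for null covariates
  mk <- fit$table[grep("marker_high", fit$table$term), ]
  expect_gt(mk$hazard_ratio, 1.8)
})

test_that("the interaction test is symmetric, calibrated, and names empty cells", {
  d <- gen_cohort(n = 500, interaction_loghr = log(0.4), seed = 13)
  res <- interaction_test(d, d$marker_high, "TTR")
  expect_p_value(res$p_value)
  expect_identical(nrow(res$stratum_hr), 2L)

  # relabeling high <-> low flips the coefficient, p unchanged
  res2 <- interaction_test(d, 1L - d$marker_high, "TTR")
  expect_lt(abs(res$p_value - res2$p_value), 1e-9)
  expect_equal(res$coefficient, -res2$coefficient, tolerance = 1e-6)

  # empty cell is reported by name
  d2 <- d[!(d$marker_high == 1 & d$adjuvant == "yes"), ]
  expect_error(interaction_test(d2, d2$marker_high, "TTR"),
               "marker-high / treatment-yes")

  # planted interaction is detected with high power at n = 2000
  set.seed(21)
  hits <- replicate(20, {
    dp <- gen_cohort(n = 2000, interaction_loghr = log(0.5),
                     seed = sample.int(1e6, 1))
    interaction_test(dp, dp$marker_high, "TTR")$p_value < 0.01
  })
  expect_gte(mean(hits), 0.9)
})
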