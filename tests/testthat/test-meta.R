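test_that("log risk ratio and its standard error follow the count formulas", {
  e <- rr_effect(10, 100, 20, 100)
  expect_equal(e$log_effect, log(0.5))
  expect_equal(e$se, sqrt(1 / 10 - 1 / 100 + 1 / 20 - 1 / 100))
  expect_equal(rr_effect(15, 60, 15, 60)$log_effect, 0)
  # continuity correction applied to all four cells only on zero cells
  e0 <- rr_effect(0, 50, 5, 50, cc = 0.5)
  expect_equal(e0$log_effect, log((0.5 / 50.5) / (5.5 / 50.5)))
  expect_equal(e0$se, sqrt(1 / 0.5 - 1 / 50.5 + 1 / 5.5 - 1 / 50.5))
  expect_true(is.finite(e0$log_effect) && e0$se > 0)
  expect_error(rr_effect(0, 50, 0, 50, cc = 0), "undefined")
  expect_error(rr_effect(60, 50, 5, 50), "arm size")
})

test_that("log hazard ratio back-calculates its SE from the 95% CI", {
  e <- hr_effect(1.0, 0.5, 2.0)
  expect_equal(e$log_effect, 0)
  expect_equal(e$se, log(4) / (2 * 1.959964))
  e2 <- hr_effect(0.96, 0.77, 1.19)
  expect_equal(e2$log_effect, log(0.96))
  expect_equal(e2$se, (log(1.19) - log(0.77)) / (2 * 1.959964))
  expect_error(hr_effect(1, 1, 1), "degenerate")
  expect_error(hr_effect(-1, 0.5, 2), "positive")
  expect_error(hr_effect(1, 1.2, 2), "bracket")
})

test_that("fixed-effect pooling matches hand and brute-force oracles", {
  one <- as_estimates(0.25, 0.4)
  f1 <- pool_fixed(one)
  expect_equal(f1$log_pooled, 0.25)
  expect_equal(f1$se_pooled, 0.4)
  two <- as_estimates(c(0, log(2)), c(0.5, 0.5))
  f2 <- pool_fixed(two)
  expect_equal(f2$log_pooled, log(2) / 2)
  expect_equal(f2$se_pooled, 0.5 / sqrt(2))
  # brute-force oracle equivalence on rational inputs, k <= 3
  cases <- list(
    list(y = c(1 / 3), se = c(1 / 7)),
    list(y = c(-1 / 2, 3 / 4), se = c(2 / 5, 1 / 3)),
    list(y = c(1 / 9, -2 / 7, 5 / 11), se = c(1 / 2, 3 / 8, 5 / 13))
  )
  for (cs in cases) {
    bf <- brute_force_pool(cs$y, cs$se)
    f <- pool_fixed(as_estimates(cs$y, cs$se))
    expect_equal(f$log_pooled, bf$mu, tolerance = 1e-12)
    expect_equal(f$se_pooled, bf$se, tolerance = 1e-12)
    expect_equal(f$q, bf$q, tolerance = 1e-12)
  }
  expect_error(pool_fixed(as_estimates(numeric(0), numeric(0))), "no estimates")
  mixed <- rbind(as_estimates(0.1, 0.2, "RR"), as_estimates(0.2, 0.3, "HR"))
  expect_error(pool_fixed(mixed), "mixed")
})

test_that("pooled ratio stays within the range of study ratios", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    est <- as_estimates(rnorm(k, 0, 0.5), runif(k, 0.05, 0.6))
    f <- pool_fixed(est)
    expect_gte(exp(f$log_pooled), min(exp(est$log_effect)) - 1e-12)
    expect_lte(exp(f$log_pooled), max(exp(est$log_effect)) + 1e-12)
  }
})

test_that("adding a study above the pooled mean pulls the mean up", {
  set.seed(12)
  for (i in 1:10) {
    est <- as_estimates(rnorm(5, 0, 0.4), runif(5, 0.1, 0.5))
    mu <- pool_fixed(est)$log_pooled
    bigger <- rbind(est, as_estimates(mu + 0.3, 0.3))
    bigger$study_id <- paste0("s", seq_len(6))
    expect_gt(pool_fixed(bigger)$log_pooled, mu)
  }
})

test_that("DerSimonian-Laird pooling matches oracles and degenerates to fixed", {
  # homogeneous input: Q <= df, tau2 truncated to zero, equals fixed model
  hom <- as_estimates(c(0.1, 0.1, 0.1), c(0.3, 0.4, 0.5))
  r <- pool_random_dl(hom)
  f <- pool_fixed(hom)
  expect_identical(r$tau2, 0)
  expect_equal(r$log_pooled, f$log_pooled)
  expect_equal(r$se_pooled, f$se_pooled)
  # brute-force oracle equivalence
  y <- c(-1 / 2, 3 / 4, 1 / 5); se <- c(2 / 5, 1 / 3, 1 / 4)
  bf <- brute_force_pool(y, se, random = TRUE)
  rd <- pool_random_dl(as_estimates(y, se))
  expect_equal(rd$log_pooled, bf$mu, tolerance = 1e-12)
  expect_equal(rd$se_pooled, bf$se, tolerance = 1e-12)
  expect_equal(rd$tau2, bf$tau2, tolerance = 1e-12)
  # random-effects SE never beats the fixed-effect SE
  set.seed(13)
  for (i in 1:20) {
    est <- as_estimates(rnorm(6, 0, 0.8), runif(6, 0.1, 0.5))
    expect_gte(pool_random_dl(est)$se_pooled, pool_fixed(est)$se_pooled - 1e-15)
  }
  expect_error(pool_random_dl(as_estimates(0.2, 0.1)), "fixed")
})

test_that("pooling agrees with metafor as an independent reference", {
  skip_if_not_installed("metafor")
  set.seed(14)
  est <- as_estimates(rnorm(8, -0.1, 0.4), runif(8, 0.08, 0.45))
  f <- pool_fixed(est)
  r <- pool_random_dl(est)
  mf <- metafor::rma(yi = est$log_effect, sei = est$se, method = "FE")
  mr <- metafor::rma(yi = est$log_effect, sei = est$se, method = "DL")
  expect_equal(f$log_pooled, as.numeric(mf$beta), tolerance = 1e-10)
  expect_equal(f$se_pooled, mf$se, tolerance = 1e-10)
  expect_equal(f$q, mf$QE, tolerance = 1e-10)
  expect_equal(r$log_pooled, as.numeric(mr$beta), tolerance = 1e-10)
  expect_equal(r$se_pooled, mr$se, tolerance = 1e-10)
  expect_equal(r$tau2, mr$tau2, tolerance = 1e-10)
  expect_equal(100 * r$i2, mr$I2, tolerance = 1e-6)
})

test_that("heterogeneity statistics follow Q and the truncated I2", {
  ident <- as_estimates(c(0.2, 0.2, 0.2), c(0.3, 0.3, 0.3))
  h <- heterogeneity(ident)
  expect_equal(h$q, 0)
  expect_identical(h$i2, 0)
  h2 <- heterogeneity(as_estimates(c(0, 1), c(0.5, 0.5)))
  expect_equal(h2$q, 2)
  expect_identical(h2$df, 1L)
  expect_equal(h2$i2, 0.5)
  expect_equal(h2$p_q, pchisq(2, 1, lower.tail = FALSE))
  # Q below df truncates I2 at exactly zero
  h3 <- heterogeneity(as_estimates(c(0.1, 0.12, 0.11), c(0.5, 0.5, 0.5)))
  expect_lt(h3$q, h3$df)
  expect_identical(h3$i2, 0)
  expect_error(heterogeneity(as_estimates(0.1, 0.2)), "2")
})

test_that("contact-force subgroup split pools independently and drops unknowns", {
  est <- as_estimates(seq(-0.4, 0.4, length.out = 18), rep(0.3, 18))
  est$subgroup <- rep(c("CF", "non-CF", "unknown"), times = c(8, 6, 4))
  sg <- subgroup_pool(est)
  expect_identical(sg$CF$fixed$k, 8L)
  expect_identical(sg$`non-CF`$fixed$k, 6L)
  # all-CF input: CF subgroup equals the full pool, non-CF absent
  est$subgroup <- "CF"
  sg2 <- subgroup_pool(est)
  expect_null(sg2$`non-CF`)
  expect_equal(sg2$CF$fixed$log_pooled, pool_fixed(est)$log_pooled)
  expect_equal(sg2$CF$random$tau2, pool_random_dl(est)$tau2)
})

test_that("study tables convert to effects with the follow-up filter applied", {
  studies <- simulate_meta_dataset(meta_sim_spec(k = 10, seed = 3))
  studies$followup_months[1:2] <- 3   # below the 6-month inclusion floor
  studies$hr[3] <- 0.9; studies$hr_lcl[3] <- 0.7; studies$hr_ucl[3] <- 1.15
  est <- effects_from_studies(studies, "RR")
  expect_identical(nrow(est), 8L)
  expect_true(all(est$measure == "RR"))
  hr_est <- effects_from_studies(studies, "HR")
  expect_identical(nrow(hr_est), 1L)
  expect_equal(hr_est$log_effect, log(0.9))
  # round-trip through the CSV interface
  path <- withr::local_tempfile(fileext = ".csv")
  write_studies(studies, path)
  back <- read_studies(path)
  expect_equal(back$events_cba, studies$events_cba)
  expect_equal(back$hr, studies$hr)
  expect_identical(back$rfa_type, studies$rfa_type)
})

test_that("forest table carries ratios, CIs and normalized weights", {
  est <- as_estimates(c(-0.2, 0.1, 0.3), c(0.2, 0.3, 0.25))
  tab <- forest_table(est)
  expect_identical(nrow(tab), 5L)  # 3 studies + fixed + random rows
  expect_equal(sum(tab$weight_pct, na.rm = TRUE), 100)
  expect_equal(tab$ratio[1], exp(-0.2))
  expect_true(all(tab$ci_low < tab$ratio & tab$ratio < tab$ci_high))
})
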