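test_that("z-transform centres, scales, preserves missingness and is idempotent", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  x <- c(0.68 + rnorm(50, 0, 0.15), NA)
  z <- z_transform(x)
  expect_true(is.na(z[51]))
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_equal(z_transform(z), z, tolerance = 1e-12)
  expect_error(z_transform(rep(2, 10), name = "tl_raw"), "tl_raw.*zero variance")
  expect_error(z_transform(c(1, NA, NA)), "fewer than 2")
})

test_that("age groups follow the printed integer-year boundaries", {
  expect_equal(assign_age_group(c(14.1, 29.9, 30, 59, 60, 79.9, 80, 93.3)),
               c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_equal(assign_age_group(0), 1)
  expect_error(assign_age_group(-1), "negative")
})

test_that("least-squares fitting matches hand-computed and perfect-fit cases", {
  # perfect fit: zero residual, zero SE
  x <- rnorm(20)
  fit <- fit_linear(x, cbind(intercept = 1, x = x))
  expect_equal(fit$estimate$beta, 1, tolerance = 1e-12)
  expect_lt(fit$estimate$se, 1e-12)

  # three-point hand OLS: slope 0.5
  fit3 <- fit_linear(c(0, 2, 1), cbind(intercept = 1, x = c(0, 1, 2)))
  expect_equal(fit3$estimate$beta, 0.5, tolerance = 1e-12)

  # listwise deletion: same answer as fitting the complete rows by hand
  set.seed(42)
  X <- cbind(intercept = 1, x = rnorm(30), z = rnorm(30))
  y <- 0.3 * X[, "x"] + rnorm(30)
  y[c(3, 11)] <- NA; X[7, "z"] <- NA
  fit_na <- fit_linear(y, X)
  keep <- complete.cases(y, X)
  oracle <- ols_oracle(y[keep], X[keep, ])
  expect_equal(fit_na$estimate$beta, oracle$beta[2], tolerance = 1e-10)
  expect_equal(fit_na$estimate$se, unname(oracle$se[2]), tolerance = 1e-10)
  expect_equal(fit_na$n, sum(keep))

  # rank deficiency: duplicated column dropped with a warning, not an error
  Xd <- cbind(intercept = 1, x = X[, "x"], x2 = X[, "x"])
  expect_warning(fitd <- fit_linear(y, Xd), "rank-deficient")
  expect_equal(nrow(fitd$coefficients), 2)

  expect_error(fit_linear(rnorm(3), cbind(1, rnorm(3), rnorm(3))), "complete cases")
})

test_that("the three association models recover the simulation truth", {
  # unit-variance latent TL so the per-allele truth is on the standardized scale
  truth <- null_truth(theta = 0.05)
  cfg <- cohort_config("big", n = 20000, tl_noise_sd = sqrt(1 - 0.0056),
                       traits_available = "GENERAL")
  ch <- add_grs(simulate_cohort(cfg, truth = truth, seed = 9))
  est <- cohort_associations(ch, "GENERAL")
  expect_setequal(est$label, c("TL_trait", "GRS_TL", "GRS_trait"))

  grs_tl <- est[est$label == "GRS_TL", ]
  expect_lt(abs(grs_tl$beta - (-0.05)), 3 * grs_tl$se)

  # GRS-trait is theta x GRS-TL under the structural model
  grs_tr <- est[est$label == "GRS_trait", ]
  expect_lt(abs(grs_tr$beta - 0.05 * (-0.05)), 3 * grs_tr$se)

  # null instrument: zero per-allele effect recovered as zero
  snps0 <- default_snps(beta_tl = 0)
  ch0 <- add_grs(simulate_cohort(cfg, snps = snps0, truth = truth, seed = 10),
                 snps = snps0)
  est0 <- cohort_associations(ch0, "GENERAL")
  g0 <- est0[est0$label == "GRS_TL", ]
  expect_lt(abs(g0$beta), 3 * g0$se)
})

test_that("association preconditions are enforced", {
  ch <- add_grs(simulate_cohort(cohort_config("s", n = 200, has_apoe = FALSE),
                                seed = 11))
  expect_error(cohort_associations(ch, "NOT_A_TRAIT"), "not available")
  expect_error(cohort_associations(ch, "GENERAL", stratum = "e4_carrier"),
               "APOE genotype unavailable")
  small <- add_grs(simulate_cohort(cohort_config("t", n = 40), seed = 12))
  expect_error(cohort_associations(small[1:20, ], "GENERAL"), "cohort too small")
})

test_that("APOE stratification partitions the cohort exactly", {
  ch <- simulate_cohort(cohort_config("a", n = 2000), seed = 13)
  st <- stratify_apoe(ch)
  expect_equal(nrow(st$carrier) + nrow(st$noncarrier) + st$excluded, nrow(ch))
  expect_true(all(st$carrier$apoe %in% c("e3/e4", "e4/e4")))
  expect_true(all(st$noncarrier$apoe %in% c("e2/e2", "e2/e3", "e3/e3")))
  expect_false(any(c(st$carrier$apoe, st$noncarrier$apoe) == "e2/e4"))

  ch$apoe[1] <- "e5/e3"
  expect_error(stratify_apoe(ch), "unknown APOE")
  expect_error(stratify_apoe(ch[, setdiff(names(ch), "apoe")]), "no apoe")

  # all-e3/e3 cohort: empty carrier stratum refused downstream
  ch2 <- add_grs(simulate_cohort(cohort_config("b", n = 100), seed = 14))
  ch2$apoe <- "e3/e3"
  expect_error(cohort_associations(ch2, "GENERAL", stratum = "e4_carrier"),
               "cohort too small")
})

test_that("stratified estimates respond to a carrier-specific causal shift", {
  truth <- null_truth(theta = 0.05)
  truth$apoe_theta_modifier[] <- 3 # carriers: theta 0.15
  cfg <- cohort_config("strat", n = 30000, tl_noise_sd = 1,
                       traits_available = "DSST")
  ch <- add_grs(simulate_cohort(cfg, truth = truth, seed = 15))
  carrier <- cohort_associations(ch, "DSST", stratum = "e4_carrier")
  noncar <- cohort_associations(ch, "DSST", stratum = "e4_noncarrier")
  b_c <- carrier[carrier$label == "TL_trait", ]
  b_n <- noncar[noncar$label == "TL_trait", ]
  expect_gt(b_c$beta - b_n$beta, 2 * sqrt(b_c$se^2 + b_n$se^2))
  expect_lt(abs(b_n$beta - 0.05), 4 * b_n$se)
})
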