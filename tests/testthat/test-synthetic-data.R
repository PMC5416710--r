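test_that("genotype dosages are Hardy-Weinberg hard calls with the right mean", {
  snps <- default_snps()
  snps$eaf <- rep(0.5, 7)
  G <- simulate_genotypes(1000, snps, seed = 11)
  expect_true(all(G %in% 0:2))
  expect_lt(abs(mean(G[, 1]) - 1), 3 * sqrt(0.5 / 1000))

  # HWE genotype class frequencies at eaf = 0.3 vs exact multinomial oracle
  snps$eaf <- rep(0.3, 7)
  G <- simulate_genotypes(10000, snps, seed = 12)
  counts <- table(factor(G[, 3], levels = 0:2))
  expected <- c(0.7^2, 2 * 0.3 * 0.7, 0.3^2)
  chi <- suppressWarnings(stats::chisq.test(counts, p = expected))
  expect_gt(chi$p.value, 0.01)

  # near-degenerate frequency still legal; frequency of 1 is not
  snps$eaf <- rep(1 - 1e-12, 7)
  expect_true(all(simulate_genotypes(200, snps, seed = 13) == 2))
  snps$eaf <- rep(1, 7)
  expect_error(simulate_genotypes(10, snps), "frequencies")
  expect_error(simulate_genotypes(0, default_snps()), "at least 1")
})

test_that("multi-cohort simulation is a pure function of configs and seed", {
  cfgs <- tiny_configs(3, n = 120)
  a <- simulate_multi_cohort(cfgs, seed = 5)
  b <- simulate_multi_cohort(cfgs, seed = 5)
  expect_identical(a, b)
  c2 <- simulate_multi_cohort(cfgs, seed = 6)
  expect_false(identical(a, c2))

  dup <- tiny_configs(2)
  dup[[2]]$name <- dup[[1]]$name
  expect_error(simulate_multi_cohort(dup, seed = 1), "duplicate")
})

test_that("confounding biases the observational slope when the causal effect is zero", {
  truth <- null_truth(theta = 0, gamma = 0.5, lambda = 0.5)
  cfg <- cohort_config("conf", n = 5000, has_apoe = FALSE)
  ch <- simulate_cohort(cfg, truth = truth, seed = 21)
  fit <- fit_linear(z_transform(ch$GENERAL),
                    cbind(intercept = 1, tl = z_transform(ch$tl_raw)))
  # closed form: slope = gamma*lambda / (sd_tl * sd_trait) > 0 despite theta = 0
  expect_gt(fit$estimate$beta / fit$estimate$se, 5)
})

test_that("zero-noise unit-theta limit returns the standardized TL exactly", {
  truth <- null_truth(theta = 1)
  cfg <- cohort_config("det", n = 50, tl_noise_sd = 0, trait_noise_sd = 0,
                       traits_available = "GENERAL", has_apoe = FALSE)
  ch <- simulate_cohort(cfg, truth = truth, seed = 31)
  expect_equal(ch$GENERAL, z_transform(ch$tl_raw), tolerance = 1e-12)
})

test_that("raw T/S ratio reproduces the configured lab scale", {
  cfg <- cohort_config("hrs_like", n = 20000, age_mean = 70.4, age_sd = 9.4,
                       tl_scale_mu = 1.30, tl_scale_sigma = 0.30)
  ch <- simulate_cohort(cfg, seed = 41)
  expect_equal(mean(ch$tl_raw), 1.30, tolerance = 0.02)
  expect_equal(sd(ch$tl_raw), 0.30, tolerance = 0.03)
  expect_true(all(ch$tl_raw > 0))
})

test_that("standardized estimates are invariant to the raw T/S scale", {
  truth <- true_params()
  base <- cohort_config("low", n = 800, tl_scale_mu = 0.7, tl_scale_sigma = 0.15)
  high <- cohort_config("high", n = 800, tl_scale_mu = 3.7, tl_scale_sigma = 0.6)
  a <- add_grs(simulate_cohort(base, truth = truth, seed = 51))
  b <- add_grs(simulate_cohort(high, truth = truth, seed = 51))
  ea <- cohort_associations(a, "GENERAL")
  eb <- cohort_associations(b, "GENERAL")
  expect_equal(ea$beta, eb$beta, tolerance = 1e-10)
  expect_equal(ea$se, eb$se, tolerance = 1e-10)
})

test_that("Table-1 style configuration reproduces the published total N", {
  cfgs <- table1_configs()
  expect_equal(sum(vapply(cfgs, function(c) c$n, integer(1))), 17052L)
  cohorts <- simulate_multi_cohort(cfgs[1:3], seed = 61)
  expect_equal(sum(vapply(cohorts, nrow, integer(1))),
               sum(vapply(cfgs[1:3], function(c) c$n, integer(1))))
  # availability pattern carried through: BETULA rows lack STROOP
  expect_false("STROOP" %in% names(cohorts[[1]]))
  expect_true("MMSE" %in% names(cohorts[[1]]))
})

test_that("every simulated individual satisfies the cohort invariants", {
  cfg <- cohort_config("inv", n = 500, missing_rate = 0.3,
                       traits_available = c("MMSE", "DSST"))
  ch <- simulate_cohort(cfg, seed = 71)
  dos <- as.matrix(ch[, default_snps()$rsid])
  expect_true(all(dos >= 0 & dos <= 2))
  expect_true(all(ch$tl_raw > 0))
  expect_true(all(!is.na(ch$MMSE) | !is.na(ch$DSST)))
  expect_true(all(ch$apoe %in% c("e2/e2", "e2/e3", "e2/e4",
                                 "e3/e3", "e3/e4", "e4/e4")))
})

test_that("two-sample summary statistics carry the instrument and recover theta", {
  snps <- default_snps()
  ss <- simulate_two_sample_summary(snps, true_params(), n_x = 5000, n_y = 8000,
                                    seed = 81)
  expect_identical(ss$exposure$rsid, snps$rsid)
  expect_identical(ss$outcome$rsid, snps$rsid)
  expect_true(all(ss$exposure$se > 0) && all(ss$outcome$se > 0))

  # theta = 0: IVW centred at zero over replicates
  truth0 <- null_truth(theta = 0)
  est <- vapply(1:200, function(i) {
    s <- simulate_two_sample_summary(snps, truth0, n_x = 20000, n_y = 20000,
                                     seed = 1000 + i)
    two_sample_ivw(s$exposure$beta, s$exposure$se,
                   s$outcome$beta, s$outcome$se)$beta_iv
  }, numeric(1))
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(200))

  expect_error(simulate_two_sample_summary(snps, true_params(), n_x = 5),
               "at least 10")
})
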