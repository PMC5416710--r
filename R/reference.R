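#' Published cohort characteristics of the ENGAGE telomere-cognition study
#'
#' The printed per-cohort descriptive table of the 12-cohort (14 genotyping
#' strata: BETULA and the Leiden Longevity Study each contribute multiple
#' rows) European-ancestry meta-analysis of telomere length and cognition:
#' sample size, age, raw T/S-ratio telomere length, percent women, unweighted
#' 7-SNP GRS, which of the six cognitive traits each cohort measured, and
#' APOE availability. These printed values serve as inputs for worked-example
#' checks (e.g. the sample-size-weighted GRS mean) and as the template for
#' the synthetic multi-cohort configuration.
#'
#' @return A data.frame with one row per cohort stratum.
#' @export
engage_table1 <- function() {
  tab <- data.frame(
    cohort = c("BETULA1", "BETULA2", "BETULA3", "ERF", "FITSA", "Gender",
               "HRS", "LBC1936", "LLS1", "LLS2", "NSHD", "NTR", "QIMR", "SATSA"),
    n = c(163L, 396L, 315L, 2502L, 429L, 466L, 4117L, 999L, 2305L, 868L,
          2425L, 200L, 1280L, 587L),
    age_mean = c(50.9, 62.4, 60, 51.6, 68.6, 74.5, 70.4, 69.6, 59.2, 93.3,
                 53, 40.3, 14.1, 68.8),
    age_sd = c(7.8, 14.5, 15, 15.8, 3.4, 2.6, 9.4, 0.8, 6.8, 2.6, 0, 16.4,
               2.4, 9.6),
    tl_mean = c(1.01, 0.93, 0.97, 1.76, 0.9, 0.68, 1.3, 1.3, 1.46, 1.28,
                1.54, 2.72, 3.7, 0.76),
    tl_sd = c(0.17, 0.15, 0.17, 0.36, 0.19, 0.15, 0.3, 0.5, 0.26, 0.22,
              0.91, 0.56, 0.6, 0.27),
    pct_women = c(58.3, 54.8, 54, 55.6, 100, 49, 58, 49, 54.8, 61.6, 50,
                  66.5, 52.6, 58),
    grs_mean = c(8.5, 8.87, 8.65, 8.65, 8.52, 8.43, 8.6, 8.36, 8.47, 8.44,
                 8.55, 8.5, 8.5, 8.45),
    grs_sd = c(1.57, 1.56, 1.51, 1.57, 1.46, 1.34, 1.52, 1.56, 1.52, 1.57,
               1.4, 1.56, 1.5, 1.45),
    MMSE = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE,
             FALSE, FALSE, FALSE, FALSE),
    DSST = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE,
             FALSE, FALSE, FALSE, TRUE),
    BLOCK = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE,
              FALSE, FALSE, FALSE, FALSE, TRUE),
    MEMORY = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
               TRUE, FALSE, FALSE, TRUE),
    STROOP = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE,
               FALSE, FALSE, FALSE, FALSE, FALSE),
    GENERAL = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE,
                FALSE, TRUE, TRUE, TRUE, TRUE),
    has_apoe = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                 TRUE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  tab
}

#' Published predicted and observed effect estimates per cognitive trait
#'
#' Printed meta-analytic results of the telomere-cognition study: for each
#' cognitive trait the one-sample Wald-type IV ("predicted") estimate with
#' 95% CI and p-value, the pooled observational TL-trait estimate with 95%
#' CI and p-value, the Z-test p-value for their difference, and the
#' two-sample replication results on CHARGE consortium summary statistics
#' (beta with CI for general cognition; Z-scores only for DSST and STROOP,
#' whose outcome effect sizes were unavailable). Used as inputs to
#' worked-example reconstructions of the difference test and of two-sided
#' normal p-values from printed betas and CIs.
#'
#' @return A data.frame with one row per trait.
#' @export
engage_table2 <- function() {
  data.frame(
    trait = c("MMSE", "DSST", "BLOCK", "MEMORY", "STROOP", "GENERAL"),
    iv_n = c(7066L, 4419L, 5001L, 13060L, 2940L, 12283L),
    iv_beta = c(0.291, -0.016, -0.192, -0.022, -0.598, 0.039),
    iv_ci_low = c(-0.05, -0.437, -0.594, -0.264, -1.125, -0.229),
    iv_ci_high = c(0.631, 0.405, 0.21, 0.22, -0.072, 0.306),
    iv_p = c(0.095, 0.941, 0.349, 0.86, 0.026, 0.778),
    diff_p = c(0.13, 0.76, 0.34, 0.79, 0.04, 0.89),
    obs_beta = c(0.025, 0.051, 0.004, 0.011, -0.053, 0.02),
    obs_ci_low = c(0.002, 0.024, -0.024, -0.005, -0.087, -0.008),
    obs_ci_high = c(0.047, 0.077, 0.032, 0.028, -0.018, 0.047),
    obs_p = c(0.03, 0.0002, 0.781, 0.187, 0.003, 0.156),
    charge_n = c(NA, 32088L, NA, NA, 7726L, 53949L),
    charge_beta = c(NA, NA, NA, NA, NA, 0.086),
    charge_ci_low = c(NA, NA, NA, NA, NA, 0.016),
    charge_ci_high = c(NA, NA, NA, NA, NA, 0.156),
    charge_z = c(NA, 2.021, NA, NA, -0.78, NA),
    charge_p = c(NA, 0.043, NA, NA, 0.435, 0.016),
    stringsAsFactors = FALSE
  )
}

#' Cohort configurations mirroring the published study
#'
#' Builds the default 14-stratum simulation configuration from the printed
#' cohort characteristics: sizes, age distributions, sex ratios, lab-specific
#' raw T/S scales and trait availability all follow [engage_table1()];
#' residual noise levels are shared defaults.
#'
#' @param tl_noise_sd,trait_noise_sd,missing_rate Passed to [cohort_config()].
#' @return A list of `telomr_cohort_config`, one per cohort stratum.
#' @export
table1_configs <- function(tl_noise_sd = 0.9, trait_noise_sd = 0.95,
                           missing_rate = 0) {
  tab <- engage_table1()
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    traits <- TRAIT_NAMES[unlist(row[TRAIT_NAMES])]
    cohort_config(
      name = row$cohort, n = row$n,
      age_mean = row$age_mean, age_sd = row$age_sd,
      prop_female = row$pct_women / 100,
      tl_scale_mu = row$tl_mean, tl_scale_sigma = row$tl_sd,
      tl_noise_sd = tl_noise_sd, trait_noise_sd = trait_noise_sd,
      traits_available = traits, has_apoe = row$has_apoe,
      missing_rate = missing_rate, seed_offset = i
    )
  })
}
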