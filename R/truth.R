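TRAIT_NAMES <- c("MMSE", "DSST", "BLOCK", "MEMORY", "STROOP", "GENERAL")

named_trait_vector <- function(x, traits = TRAIT_NAMES) {
  if (is.null(names(x))) x <- stats::setNames(rep_len(x, length(traits)), traits)
  missing_traits <- setdiff(traits, names(x))
  if (length(missing_traits) > 0) {
    stop("trait map lacks entries for: ", paste(missing_traits, collapse = ", "))
  }
  x[traits]
}

#' Simulation truth for the structural model
#'
#' Parameters of the linear-Gaussian structural model the generator draws
#' from (genotype -> latent standardized TL -> trait, with a single standard
#' normal confounder U affecting both TL and every trait):
#' \deqn{TL = \sum_j \beta_j (G_j - 2 p_j) + \gamma U + s_a (age - \bar a) + \epsilon_{TL}}
#' \deqn{Y_t = \theta_t^* Z(TL) + \lambda U + a_t (age - \bar a) + b_t F + c_t E4 + \epsilon_t}
#' where \eqn{\theta_t^* = \theta_t \times} `apoe_theta_modifier[t]` for APOE
#' e4 carriers, F is a female indicator and E4 a carrier indicator.
#'
#' Defaults encode modest causal effects of TL on cognition (positive for
#' positively scored traits, negative for STROOP, where lower interference
#' time is better), moderate confounding, cognitive decline with age, and a
#' small carrier deficit; they can be overridden per element.
#'
#' @param theta Named map trait -> causal effect of standardized TL on the
#'   standardized trait; an unnamed scalar is recycled to all traits.
#' @param gamma_u_tl Effect of the confounder U on TL (s.d. units).
#' @param lambda_u_trait Effect of U on every trait.
#' @param age_tl_slope TL change in s.d. per year of age.
#' @param trait_age_effects,trait_sex_effects Named maps trait -> per-year
#'   age effect and female-sex effect on the trait.
#' @param apoe_freqs Allele frequencies of e2/e3/e4 (must sum to 1).
#' @param apoe_trait_shift Named map trait -> additive e4-carrier shift.
#' @param apoe_theta_modifier Named map trait -> multiplicative change of
#'   theta in e4 carriers (1 = no modification).
#' @return A list of class `telomr_truth`.
#' @export
true_params <- function(theta = c(MMSE = 0.03, DSST = 0.05, BLOCK = 0.01,
                                  MEMORY = 0.01, STROOP = -0.06, GENERAL = 0.05),
                        gamma_u_tl = 0.3,
                        lambda_u_trait = 0.3,
                        age_tl_slope = -0.02,
                        trait_age_effects = c(MMSE = -0.01, DSST = -0.015,
                                              BLOCK = -0.01, MEMORY = -0.01,
                                              STROOP = 0.015, GENERAL = -0.01),
                        trait_sex_effects = c(MMSE = 0, DSST = 0.05, BLOCK = -0.05,
                                              MEMORY = 0.1, STROOP = 0, GENERAL = 0),
                        apoe_freqs = c(e2 = 0.08, e3 = 0.77, e4 = 0.15),
                        apoe_trait_shift = c(MMSE = -0.05, DSST = -0.05,
                                             BLOCK = -0.05, MEMORY = -0.05,
                                             STROOP = 0.05, GENERAL = -0.05),
                        apoe_theta_modifier = 1) {
  if (abs(sum(apoe_freqs) - 1) > 1e-12) stop("apoe_freqs must sum to 1")
  if (any(apoe_freqs < 0)) stop("apoe_freqs must be non-negative")
  names(apoe_freqs) <- c("e2", "e3", "e4")
  truth <- list(
    theta = named_trait_vector(theta),
    gamma_u_tl = gamma_u_tl,
    lambda_u_trait = lambda_u_trait,
    age_tl_slope = age_tl_slope,
    trait_age_effects = named_trait_vector(trait_age_effects),
    trait_sex_effects = named_trait_vector(trait_sex_effects),
    apoe_freqs = apoe_freqs,
    apoe_trait_shift = named_trait_vector(apoe_trait_shift),
    apoe_theta_modifier = named_trait_vector(apoe_theta_modifier)
  )
  class(truth) <- "telomr_truth"
  truth
}

#' Configuration of one simulated cohort
#'
#' Describes one study: its size, age structure, sex ratio, the lab-specific
#' location/spread of the raw T/S-ratio scale, residual noise levels, which
#' cognitive traits it measured, and whether APOE genotype is available.
#'
#' @param name Cohort label (unique across a multi-cohort run).
#' @param n Number of individuals (>= 2).
#' @param age_mean,age_sd Age distribution in years (normal, floored at 0).
#' @param prop_female Proportion of women in (0, 1).
#' @param tl_scale_mu,tl_scale_sigma Location and spread of the raw T/S
#'   ratio; `tl_raw = tl_scale_mu + tl_scale_sigma * TL_std`, floored at 0.01.
#' @param tl_noise_sd Residual s.d. of the latent standardized TL.
#' @param trait_noise_sd Named map trait -> residual s.d.; scalar recycled.
#' @param traits_available Character subset of
#'   `c("MMSE","DSST","BLOCK","MEMORY","STROOP","GENERAL")`.
#' @param has_apoe Whether APOE genotype is observed in this cohort.
#' @param missing_rate Optional missing-at-random rate applied to available
#'   traits (each individual keeps at least one non-missing trait).
#' @param seed_offset Integer added to the master seed for this cohort.
#' @param covariates Character vector naming extra study-specific covariate
#'   columns to simulate as standard-normal noise covariates.
#' @return A list of class `telomr_cohort_config`.
#' @export
cohort_config <- function(name, n, age_mean = 60, age_sd = 10,
                          prop_female = 0.55,
                          tl_scale_mu = 1.3, tl_scale_sigma = 0.3,
                          tl_noise_sd = 0.9,
                          trait_noise_sd = 0.95,
                          traits_available = TRAIT_NAMES,
                          has_apoe = TRUE,
                          missing_rate = 0,
                          seed_offset = 0L,
                          covariates = character(0)) {
  if (n < 2) stop("cohort size must be at least 2")
  if (tl_scale_sigma <= 0) stop("tl_scale_sigma must be positive")
  if (prop_female < 0 || prop_female > 1) stop("prop_female must be in [0, 1]")
  bad <- setdiff(traits_available, TRAIT_NAMES)
  if (length(bad) > 0) stop("unknown trait(s): ", paste(bad, collapse = ", "))
  if (length(traits_available) == 0) stop("at least one trait must be available")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  cfg <- list(
    name = as.character(name), n = as.integer(n),
    age_mean = age_mean, age_sd = age_sd, prop_female = prop_female,
    tl_scale_mu = tl_scale_mu, tl_scale_sigma = tl_scale_sigma,
    tl_noise_sd = tl_noise_sd,
    trait_noise_sd = named_trait_vector(trait_noise_sd),
    traits_available = traits_available,
    has_apoe = isTRUE(has_apoe),
    missing_rate = missing_rate,
    seed_offset = as.integer(seed_offset),
    covariates = covariates
  )
  class(cfg) <- "telomr_cohort_config"
  cfg
}
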