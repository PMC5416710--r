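#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each individual's dosage at SNP j is the sum of two independent
#' Bernoulli(`eaf_j`) allele draws (a Binomial(2, `eaf_j`) hard call),
#' counting copies of the effect (telomere-shortening) allele. Loci are
#' simulated independently; no linkage disequilibrium, as the unweighted
#' score assumes.
#'
#' @param n Number of individuals (>= 1).
#' @param snps SNP definition table, see [default_snps()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers that have already seeded keep a single stream).
#' @return An `n x nrow(snps)` integer matrix with entries in `{0, 1, 2}`,
#'   columns named by rsid.
#' @export
simulate_genotypes <- function(n, snps = default_snps(), seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  validate_snps(snps)
  if (!is.null(seed)) set.seed(as.integer(seed))
  G <- vapply(snps$eaf, function(p) stats::rbinom(n, 2L, p), integer(n))
  G <- matrix(G, nrow = n, dimnames = list(NULL, snps$rsid))
  G
}

draw_apoe <- function(n, freqs) {
  alleles <- names(freqs)
  a1 <- sample(alleles, n, replace = TRUE, prob = freqs)
  a2 <- sample(alleles, n, replace = TRUE, prob = freqs)
  first <- pmin(a1, a2) # e2 < e3 < e4 lexicographically
  second <- pmax(a1, a2)
  paste(first, second, sep = "/")
}

is_e4_carrier <- function(apoe) apoe %in% c("e3/e4", "e4/e4")

#' Simulate one cohort under the confounded structural model
#'
#' Draws individual-level data following a linear-Gaussian structural model:
#' a latent standardized telomere length built from genotype, a standard
#' normal confounder U, an age trend and Gaussian noise; a raw T/S-ratio on
#' the cohort's lab-specific scale; and each available cognitive trait as a
#' linear function of the within-cohort standardized TL (slope theta,
#' multiplicatively modified in APOE e4 carriers), the same confounder U,
#' age, sex, an additive carrier shift, and Gaussian noise. With
#' `gamma_u_tl = lambda_u_trait = 0` and `theta = 0` the population TL-trait
#' correlation is zero; with nonzero confounding and `theta = 0` the
#' observational slope is biased away from zero while the genotype-based IV
#' estimate is not.
#'
#' @param config A [cohort_config()].
#' @param snps SNP definitions with simulation-truth `beta_tl`.
#' @param truth A [true_params()].
#' @param seed Integer seed; fully determines the cohort.
#' @return A data.frame (one row per individual) with columns `id`, one
#'   dosage column per rsid, `tl_raw`, `age`, `sex`, `apoe`, any simulated
#'   study covariates, and one column per available trait; cohort name and
#'   covariate names are carried in attributes `cohort` and `covariates`.
#' @export
simulate_cohort <- function(config, snps = default_snps(), truth = true_params(),
                            seed = 1L) {
  stopifnot(inherits(config, "telomr_cohort_config"))
  missing_noise <- setdiff(config$traits_available, names(config$trait_noise_sd))
  if (length(missing_noise) > 0) {
    stop("trait_noise_sd lacks: ", paste(missing_noise, collapse = ", "))
  }
  set.seed(as.integer(seed))
  n <- config$n

  G <- simulate_genotypes(n, snps)
  age <- pmax(0, stats::rnorm(n, config$age_mean, config$age_sd))
  sex <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
  U <- stats::rnorm(n)

  genetic <- as.vector(G %*% snps$beta_tl) - sum(2 * snps$eaf * snps$beta_tl)
  tl_std <- genetic + truth$gamma_u_tl * U +
    truth$age_tl_slope * (age - config$age_mean) +
    stats::rnorm(n, 0, config$tl_noise_sd)
  tl_raw <- pmax(0.01, config$tl_scale_mu + config$tl_scale_sigma * tl_std)

  apoe <- rep(NA_character_, n)
  if (config$has_apoe) apoe <- draw_apoe(n, truth$apoe_freqs)
  carrier <- !is.na(apoe) & is_e4_carrier(apoe)

  tl_z <- z_transform(tl_std)
  female <- as.numeric(sex == "female")

  traits <- lapply(config$traits_available, function(tr) {
    theta_star <- truth$theta[[tr]] *
      ifelse(carrier, truth$apoe_theta_modifier[[tr]], 1)
    theta_star * tl_z + truth$lambda_u_trait * U +
      truth$trait_age_effects[[tr]] * (age - config$age_mean) +
      truth$trait_sex_effects[[tr]] * female +
      truth$apoe_trait_shift[[tr]] * carrier +
      stats::rnorm(n, 0, config$trait_noise_sd[[tr]])
  })
  names(traits) <- config$traits_available

  if (config$missing_rate > 0) {
    for (tr in names(traits)) {
      drop <- stats::runif(n) < config$missing_rate
      traits[[tr]][drop] <- NA_real_
    }
    # preserve the at-least-one-trait invariant
    all_missing <- Reduce(`&`, lapply(traits, is.na))
    if (any(all_missing)) {
      keep <- sample(names(traits), sum(all_missing), replace = TRUE)
      for (tr in unique(keep)) {
        idx <- which(all_missing)[keep == tr]
        # re-draw the dropped value from the same conditional model noise
        traits[[tr]][idx] <- stats::rnorm(length(idx), 0, config$trait_noise_sd[[tr]])
      }
    }
  }

  out <- data.frame(
    id = sprintf("%s_%05d", config$name, seq_len(n)),
    G, tl_raw = tl_raw, age = age, sex = sex, apoe = apoe,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (cv in config$covariates) out[[cv]] <- stats::rnorm(n)
  for (tr in names(traits)) out[[tr]] <- traits[[tr]]
  attr(out, "cohort") <- config$name
  attr(out, "covariates") <- config$covariates
  out
}

#' Simulate several cohorts from one master seed
#'
#' Each cohort draws from its own RNG stream seeded at
#' `seed + seed_offset`, so heterogeneous labs are reproducible
#' independently and the full multi-cohort dataset is a pure function of
#' (`configs`, `snps`, `truth`, `seed`).
#'
#' @param configs List of [cohort_config()] with unique names.
#' @inheritParams simulate_cohort
#' @return Named list of cohort data.frames.
#' @export
simulate_multi_cohort <- function(configs, snps = default_snps(),
                                  truth = true_params(), seed = 1L) {
  if (length(configs) < 1) stop("at least one cohort config required")
  nm <- vapply(configs, function(cfg) cfg$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate cohort names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  cohorts <- lapply(configs, function(cfg) {
    simulate_cohort(cfg, snps = snps, truth = truth,
                    seed = as.integer(seed) + cfg$seed_offset)
  })
  names(cohorts) <- nm
  cohorts
}

#' Simulate two-sample GWAS summary statistics
#'
#' Emulates the summary data used in two-sample MR: per-SNP effects on the
#' exposure (standardized TL) estimated in one GWAS of size `n_x` and on the
#' outcome trait in a non-overlapping GWAS of size `n_y`. Estimated betas
#' are drawn around the truth with the usual GWAS sampling standard error
#' for a standardized phenotype, `se = 1/sqrt(2*eaf*(1-eaf)*n)`. The true
#' per-SNP outcome effect is `theta * beta_tl_j` (no pleiotropy).
#'
#' @param snps SNP definitions (exposure truth in `beta_tl`).
#' @param truth A [true_params()]; `truth$theta[[trait]]` is the causal
#'   effect used for the outcome.
#' @param n_x,n_y GWAS sample sizes (>= 10).
#' @param trait Outcome trait name.
#' @param seed Integer seed.
#' @param noise If `FALSE`, the drawn betas equal the true values (standard
#'   errors keep their sampling magnitude); useful for plug-in identities.
#' @return List with data.frames `exposure` and `outcome`, each with
#'   columns `rsid`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `n`.
#' @export
simulate_two_sample_summary <- function(snps = default_snps(),
                                        truth = true_params(),
                                        n_x = 37684, n_y = 53949,
                                        trait = "GENERAL",
                                        seed = 1L, noise = TRUE) {
  validate_snps(snps)
  if (n_x < 10 || n_y < 10) stop("n_x and n_y must be at least 10")
  if (any(snps$eaf < 1e-6 | snps$eaf > 1 - 1e-6)) {
    stop("degenerate effect-allele frequency")
  }
  set.seed(as.integer(seed))
  se_for <- function(n) 1 / sqrt(2 * snps$eaf * (1 - snps$eaf) * n)
  se_x <- se_for(n_x)
  se_y <- se_for(n_y)
  true_y <- truth$theta[[trait]] * snps$beta_tl
  beta_x <- if (noise) stats::rnorm(nrow(snps), snps$beta_tl, se_x) else snps$beta_tl
  beta_y <- if (noise) stats::rnorm(nrow(snps), true_y, se_y) else true_y
  row <- function(beta, se, n) data.frame(
    rsid = snps$rsid, effect_allele = snps$effect_allele,
    other_allele = snps$other_allele, eaf = snps$eaf,
    beta = beta, se = se, n = n, stringsAsFactors = FALSE
  )
  list(exposure = row(beta_x, se_x, n_x), outcome = row(beta_y, se_y, n_y))
}
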