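# Shared fixtures: small cohort configurations and a convenience truth with
# no confounding and a flat null, used across module tests.

all_trait_names <- c("MMSE", "DSST", "BLOCK", "MEMORY", "STROOP", "GENERAL")

null_truth <- function(theta = 0, gamma = 0, lambda = 0, age_slope = 0) {
  true_params(theta = theta, gamma_u_tl = gamma, lambda_u_trait = lambda,
              age_tl_slope = age_slope,
              trait_age_effects = 0, trait_sex_effects = 0,
              apoe_trait_shift = 0, apoe_theta_modifier = 1)
}

tiny_configs <- function(k = 3, n = 300, ...) {
  lapply(seq_len(k), function(i) {
    cohort_config(paste0("C", i), n = n, seed_offset = i, ...)
  })
}

# Independent normal-equations OLS oracle (explicit (X'X)^-1 X'y), kept
# deliberately separate from the package's QR fitting path.
ols_oracle <- function(y, X) {
  keep <- stats::complete.cases(y, X)
  y <- y[keep]; X <- as.matrix(X)[keep, , drop = FALSE]
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (length(y) - ncol(X))
  list(beta = as.vector(beta), se = unname(sqrt(diag(XtX_inv) * sigma2)))
}
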