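#' Inverse-variance fixed-effect pooling
#'
#' Pools study estimates with weights `w_i = 1/se_i^2`:
#' `beta = sum(w b)/sum(w)`, `se = 1/sqrt(sum(w))`.
#'
#' @param beta,se Numeric vectors of study estimates and standard errors.
#' @return List with `beta` and `se`.
#' @export
fixed_effect_meta <- function(beta, se) {
  check_meta_input(beta, se)
  w <- 1 / se^2
  list(beta = sum(w * beta) / sum(w), se = 1 / sqrt(sum(w)))
}

check_meta_input <- function(beta, se, min_k = 1) {
  if (length(beta) < min_k) stop("need at least ", min_k, " estimate(s)")
  if (length(beta) != length(se)) stop("beta and se lengths differ")
  if (any(!is.finite(beta)) || any(!is.finite(se))) stop("non-finite estimates")
  if (any(se <= 0)) stop("all standard errors must be positive")
  invisible(TRUE)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_i (b_i - b_fixed)^2` referred to a chi-square with k - 1
#' degrees of freedom, plus the I-squared percentage
#' `max(0, (Q - df)/Q) * 100`.
#'
#' @inheritParams fixed_effect_meta
#' @return List with `q`, `df`, `p`, `i2`.
#' @export
cochran_q <- function(beta, se) {
  check_meta_input(beta, se, min_k = 2)
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - pooled)^2)
  df <- length(beta) - 1
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE),
       i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, then
#' inverse-variance pooling with weights `1/(se_i^2 + tau2)`.
#'
#' @inheritParams fixed_effect_meta
#' @return List with `beta`, `se`, `tau2`.
#' @export
random_effects_meta <- function(beta, se) {
  check_meta_input(beta, se, min_k = 2)
  w <- 1 / se^2
  q <- cochran_q(beta, se)$q
  k <- length(beta)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (q - (k - 1)) / denom) else 0
  w_star <- 1 / (se^2 + tau2)
  list(beta = sum(w_star * beta) / sum(w_star),
       se = 1 / sqrt(sum(w_star)), tau2 = tau2)
}

#' Heterogeneity-switched meta-analysis
#'
#' Pools per-cohort estimates by fixed-effect inverse variance; when
#' Cochran's Q is significant at `switch_p` (default 0.05) the pooling is
#' redone as DerSimonian-Laird random effects. With a single study Q is
#' undefined and the fixed-effect result (the study itself) is returned
#' with a note. Confidence limits are `beta +/- 1.96 se` and the p-value is
#' two-sided normal.
#'
#' @param estimates Data.frame with columns `beta` and `se` (e.g. rows of
#'   [cohort_associations()] output for one trait/label/stratum), or `NULL`
#'   if `beta`/`se` given directly.
#' @param beta,se Alternative vector interface.
#' @param switch_p Heterogeneity p-value below which random effects is used.
#' @return One-row data.frame: `beta`, `se`, `ci_low`, `ci_high`, `p`, `k`,
#'   `q`, `q_df`, `q_p`, `i2`, `tau2`, `method`.
#' @export
pool_estimates <- function(estimates = NULL, beta = estimates$beta,
                           se = estimates$se, switch_p = 0.05) {
  check_meta_input(beta, se)
  k <- length(beta)
  fe <- fixed_effect_meta(beta, se)
  out <- list(beta = fe$beta, se = fe$se, k = k,
              q = NA_real_, q_df = NA_integer_, q_p = NA_real_,
              i2 = NA_real_, tau2 = 0, method = "fixed")
  if (k >= 2) {
    het <- cochran_q(beta, se)
    out$q <- het$q; out$q_df <- het$df; out$q_p <- het$p; out$i2 <- het$i2
    if (het$p < switch_p) {
      re <- random_effects_meta(beta, se)
      out$beta <- re$beta; out$se <- re$se; out$tau2 <- re$tau2
      out$method <- "random"
    }
  } else {
    message("single study: heterogeneity undefined, fixed-effect result returned")
  }
  data.frame(
    beta = out$beta, se = out$se,
    ci_low = out$beta - 1.96 * out$se, ci_high = out$beta + 1.96 * out$se,
    p = 2 * stats::pnorm(-abs(out$beta / out$se)),
    k = k, q = out$q, q_df = out$q_df, q_p = out$q_p, i2 = out$i2,
    tau2 = out$tau2, method = out$method, stringsAsFactors = FALSE
  )
}
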