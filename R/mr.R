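#' Recover a standard error from a printed confidence interval
#'
#' `se = (upper - lower) / (2 z)`, with `z = qnorm((1 + level)/2)` by
#' default. Published tables usually compute limits with the rounded
#' multiplier 1.96; pass `z = 1.96` to reproduce such printed arithmetic.
#'
#' @param lower,upper Interval endpoints (`upper > lower`).
#' @param level Nominal coverage, default 0.95.
#' @param z Normal multiplier; default the exact quantile.
#' @return Standard error.
#' @export
ci_to_se <- function(lower, upper, level = 0.95, z = NULL) {
  if (any(upper <= lower)) stop("upper must exceed lower")
  if (is.null(z)) z <- stats::qnorm((1 + level) / 2)
  (upper - lower) / (2 * z)
}

#' Instrument-strength F statistic
#'
#' For a single-coefficient first stage, `F = (beta/se)^2`, i.e. the squared
#' Wald z of the instrument-exposure association. Values well above 10
#' conventionally indicate a usable instrument.
#'
#' @param beta,se First-stage estimate and standard error (or a list/row
#'   with `beta`/`se` as first argument).
#' @return The F statistic.
#' @export
f_statistic <- function(beta, se = NULL) {
  if (is.null(se)) { se <- beta$se; beta <- beta$beta }
  if (any(se <= 0)) stop("se must be positive")
  (beta / se)^2
}

mr_result <- function(beta, se, mode, trait = NA_character_,
                      stratum = NA_character_, f_stat = NA_real_,
                      diff_z = NA_real_, diff_p = NA_real_) {
  data.frame(
    beta_iv = beta, se_iv = se,
    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
    p_iv = 2 * stats::pnorm(-abs(beta / se)),
    f_stat = f_stat, diff_z = diff_z, diff_p = diff_p,
    mode = mode, trait = trait, stratum = stratum,
    stringsAsFactors = FALSE
  )
}

#' One-sample Wald-ratio instrumental-variable estimate
#'
#' The causal effect of the exposure (standardized TL) on the trait is the
#' ratio of the pooled reduced-form and first-stage estimates,
#' `beta_iv = b_GRS-trait / b_GRS-TL`, with the first-order delta-method
#' standard error
#' `sqrt(se_GY^2 / b_GX^2 + b_GY^2 se_GX^2 / b_GX^4)`.
#' Weak instruments (first-stage |z| below `weak_z`) are refused, naming
#' the F statistic, since the ratio and its normal approximation degrade.
#'
#' @param grs_trait,grs_tl Pooled estimates (lists or one-row data.frames
#'   with `beta` and `se`; `n` optional) for the GRS-trait and GRS-TL
#'   associations.
#' @param trait,stratum Labels carried into the result.
#' @param weak_z Minimum first-stage |beta/se|; default 2.
#' @return One-row MR result data.frame (mode `"one_sample_wald"`).
#' @export
wald_iv <- function(grs_trait, grs_tl, trait = NA_character_,
                    stratum = NA_character_, weak_z = 2) {
  b_gy <- grs_trait$beta; se_gy <- grs_trait$se
  b_gx <- grs_tl$beta;    se_gx <- grs_tl$se
  if (se_gy <= 0 || se_gx <= 0) stop("standard errors must be positive")
  f <- f_statistic(b_gx, se_gx)
  if (b_gx == 0 || sqrt(f) < weak_z) {
    stop("weak instrument: first-stage F = ", format(f, digits = 4),
         " (|z| < ", weak_z, ")")
  }
  beta_iv <- b_gy / b_gx
  se_iv <- sqrt(se_gy^2 / b_gx^2 + b_gy^2 * se_gx^2 / b_gx^4)
  mr_result(beta_iv, se_iv, mode = "one_sample_wald", trait = trait,
            stratum = stratum, f_stat = f)
}

#' Z-test for the difference between observed and causal estimates
#'
#' `z = (b_obs - b_iv) / sqrt(se_obs^2 + se_iv^2)`, treating the two
#' estimates as independent, with a two-sided normal p-value. A small p
#' indicates the observational association is incompatible with the IV
#' (causal) estimate, e.g. residual confounding.
#'
#' @param observed,causal Lists or one-row data.frames with `beta` and `se`
#'   (`beta_iv`/`se_iv` accepted for MR results).
#' @return List with `z` and `p`.
#' @export
difference_test <- function(observed, causal) {
  get_bs <- function(x) {
    b <- x$beta %||% x$beta_iv
    s <- x$se %||% x$se_iv
    if (is.null(b) || is.null(s)) stop("need beta and se")
    list(b = b, s = s)
  }
  o <- get_bs(observed); c_ <- get_bs(causal)
  if (o$s <= 0 || c_$s <= 0) stop("standard errors must be positive")
  z <- (o$b - c_$b) / sqrt(o$s^2 + c_$s^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-sample inverse-variance-weighted causal estimate
#'
#' Combines per-SNP effects on the exposure (`x`, `sx`) and the outcome
#' (`y`, `sy`) from non-overlapping GWAS into a single causal estimate,
#' weighting by outcome precision:
#' `beta = sum(x y / sy^2) / sum(x^2 / sy^2)`,
#' `se = 1 / sqrt(sum(x^2 / sy^2))`.
#' When outcome effect sizes are only available as Z-scores (unknown
#' scale), `mode = "zscore"` sets unit outcome SEs and reports the
#' standardized statistic (`diff_z` slot unused; `beta_iv` is then on the
#' Z-score scale and `z` is the meaningful quantity).
#'
#' @param x,sx Per-SNP exposure betas and SEs.
#' @param y,sy Per-SNP outcome betas and SEs (for `mode = "zscore"`, pass
#'   the outcome Z-scores as `y` and omit `sy`).
#' @param mode `"ivw"` or `"zscore"`.
#' @param trait Label carried into the result.
#' @return One-row MR result data.frame with an extra `z` column.
#' @export
two_sample_ivw <- function(x, sx, y, sy = NULL, mode = c("ivw", "zscore"),
                           trait = NA_character_) {
  mode <- match.arg(mode)
  if (mode == "zscore") sy <- rep(1, length(y))
  if (length(unique(c(length(x), length(sx), length(y), length(sy)))) != 1) {
    stop("per-SNP vectors must have equal length")
  }
  if (length(x) < 1) stop("need at least one SNP")
  if (any(sy <= 0) || any(sx <= 0)) stop("standard errors must be positive")
  if (all(x == 0)) stop("all exposure effects are zero")
  w <- 1 / sy^2
  beta <- sum(x * y * w) / sum(x^2 * w)
  se <- 1 / sqrt(sum(x^2 * w))
  out <- mr_result(beta, se,
                   mode = if (mode == "ivw") "two_sample_ivw" else "two_sample_zscore",
                   trait = trait)
  out$z <- beta / se
  out
}

#' Per-SNP Wald ratios and heterogeneity across the instrument
#'
#' A generic pleiotropy diagnostic: each SNP's own causal ratio
#' `y_j / x_j` (delta-method SE) is compared against the IVW estimate via a
#' Cochran-type Q; a SNP with a direct (non-TL-mediated) effect on the
#' trait shows up as the dominant contributor to Q. SNPs with a zero
#' exposure effect are flagged and skipped with a warning.
#'
#' @inheritParams two_sample_ivw
#' @return List: `ratios` (data.frame rsid-less: `x`, `y`, `ratio`, `se`,
#'   `q_contribution`), `ivw` (the pooled estimate), `q`, `df`, `p`,
#'   `max_contributor` (row index of the largest Q contribution).
#' @export
per_snp_ratio_scan <- function(x, sx, y, sy) {
  if (length(x) < 2) stop("need at least two SNPs")
  usable <- x != 0
  if (any(!usable)) {
    warning(sum(!usable), " SNP(s) with zero exposure effect skipped")
  }
  ivw <- two_sample_ivw(x[usable], sx[usable], y[usable], sy[usable])
  ratio <- y[usable] / x[usable]
  se_r <- sqrt(sy[usable]^2 / x[usable]^2 +
                 y[usable]^2 * sx[usable]^2 / x[usable]^4)
  w <- 1 / se_r^2
  contrib <- w * (ratio - ivw$beta_iv)^2
  q <- sum(contrib)
  df <- sum(usable) - 1
  list(
    ratios = data.frame(index = which(usable), x = x[usable], y = y[usable],
                        ratio = ratio, se = se_r, q_contribution = contrib),
    ivw = ivw, q = q, df = df,
    p = stats::pchisq(q, df, lower.tail = FALSE),
    max_contributor = which(usable)[which.max(contrib)]
  )
}
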