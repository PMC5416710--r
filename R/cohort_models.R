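#' Z-transform a variable within cohort
#'
#' Centers and scales by the sample mean and sample standard deviation
#' (denominator n - 1) of the non-missing values, so raw telomere T/S
#' ratios and trait scores measured on lab- or test-specific scales become
#' comparable across cohorts. Missing values stay missing.
#'
#' @param values Numeric vector, `NA` allowed.
#' @param name Variable name used in error messages.
#' @return Standardized vector: non-missing entries have mean 0 and sample
#'   s.d. 1.
#' @export
z_transform <- function(values, name = deparse(substitute(values))) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("z_transform of '", name, "': fewer than 2 non-missing values")
  s <- stats::sd(values[ok])
  if (!is.finite(s) || s == 0) {
    stop("z_transform of '", name, "': zero variance")
  }
  (values - mean(values[ok])) / s
}

#' Assign the age-group covariate
#'
#' Age enters the association models as a four-level group rather than a
#' continuous term, allowing non-linear age effects: 1 = 0-29 years,
#' 2 = 30-59, 3 = 60-79, 4 = 80+.
#'
#' @param age Numeric vector of ages in years (>= 0).
#' @return Integer vector of codes 1-4 (`NA` preserved).
#' @export
assign_age_group <- function(age) {
  if (any(age < 0, na.rm = TRUE)) stop("negative age")
  findInterval(age, c(0, 30, 60, 80))
}

#' Ordinary least squares with listwise deletion
#'
#' Fits `y ~ X` by QR-based least squares, dropping rows with any missing
#' value and dropping rank-deficient columns (e.g. age-group dummies for
#' absent groups) with a warning. Coefficient standard errors come from
#' `sigma^2 (X'X)^{-1}` with `sigma^2 = RSS/(n - p)`.
#'
#' @param y Response vector.
#' @param X Design matrix including an intercept column; the first
#'   non-intercept column is the exposure of interest.
#' @return A list: `estimate` (a one-row data.frame `beta`, `se`, `n` for
#'   the first non-intercept column) and `coefficients` (the full table).
#' @export
fit_linear <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  complete <- stats::complete.cases(y, X)
  y <- y[complete]
  X <- X[complete, , drop = FALSE]
  n <- length(y)
  if (n < ncol(X) + 1) stop("too few complete cases (", n, ") for ",
                            ncol(X), " coefficients")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("dropping rank-deficient column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  }
  fit <- stats::lm.fit(X, y)
  p <- ncol(X)
  df <- n - p
  if (df < 1) stop("zero residual degrees of freedom")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(0, diag(XtX_inv) * sigma2))
  coefs <- data.frame(term = colnames(X), beta = unname(fit$coefficients),
                      se = se, stringsAsFactors = FALSE)
  is_intercept <- grepl("^\\(?[Ii]ntercept\\)?$", coefs$term)
  focal <- which(!is_intercept)[1]
  if (is.na(focal)) stop("design has no non-intercept column")
  list(
    estimate = data.frame(beta = coefs$beta[focal], se = coefs$se[focal],
                          n = n, stringsAsFactors = FALSE),
    coefficients = coefs, n = n, df = df, sigma2 = sigma2
  )
}

#' Split a cohort on APOE e4 carrier status
#'
#' Carriers are e3/e4 and e4/e4; non-carriers are e2/e2, e2/e3 and e3/e3.
#' The trans genotype e2/e4 is excluded (the protective e2 and risk e4
#' alleles would be mixed), as are individuals with missing genotype.
#'
#' @param cohort Cohort data.frame with an `apoe` column.
#' @return List with data.frames `carrier` and `noncarrier` and the integer
#'   `excluded` (e2/e4 plus missing).
#' @export
stratify_apoe <- function(cohort) {
  if (!("apoe" %in% names(cohort))) stop("cohort has no apoe column")
  apoe <- cohort$apoe
  known <- c("e2/e2", "e2/e3", "e2/e4", "e3/e3", "e3/e4", "e4/e4")
  bad <- setdiff(unique(apoe[!is.na(apoe)]), known)
  if (length(bad) > 0) stop("unknown APOE genotype: ", paste(bad, collapse = ", "))
  carrier <- !is.na(apoe) & apoe %in% c("e3/e4", "e4/e4")
  noncarrier <- !is.na(apoe) & apoe %in% c("e2/e2", "e2/e3", "e3/e3")
  list(
    carrier = cohort[carrier, , drop = FALSE],
    noncarrier = cohort[noncarrier, , drop = FALSE],
    excluded = sum(!carrier & !noncarrier)
  )
}

adjuster_matrix <- function(data, covariates = character(0)) {
  n <- nrow(data)
  X <- cbind(intercept = rep(1, n))
  X <- cbind(X, sex_female = as.numeric(data$sex == "female"))
  grp <- assign_age_group(data$age)
  present <- sort(unique(grp[!is.na(grp)]))
  if (length(present) > 1) {
    for (g in present[-1]) { # youngest present group is the reference
      X <- cbind(X, stats::setNames(data.frame(as.numeric(grp == g)),
                                    paste0("age_group", g))[[1]])
      colnames(X)[ncol(X)] <- paste0("age_group", g)
    }
  }
  for (cv in covariates) {
    X <- cbind(X, data[[cv]])
    colnames(X)[ncol(X)] <- cv
  }
  X
}

#' Fit the three per-cohort association models
#'
#' For one cohort, one trait and one stratum, fits the three adjusted linear
#' regressions of the MR design: (1) trait on TL (`TL_trait`, the
#' observational association), (2) TL on GRS (`GRS_TL`, the instrument
#' first stage) and (3) trait on GRS (`GRS_trait`, the reduced form). Raw
#' T/S-ratio TL and the trait are Z-transformed within the cohort and
#' stratum before fitting; the GRS stays on the raw allele-count scale, so
#' `GRS_TL` is the s.d. change in TL per counted allele. All models adjust
#' for sex, age group (youngest present group as reference) and any
#' declared study-specific covariates; rows with missing values are
#' dropped listwise.
#'
#' @param cohort Cohort data.frame with `grs` column (see [add_grs()]).
#' @param trait Trait column name.
#' @param stratum `"all"`, `"e4_carrier"` or `"e4_noncarrier"`.
#' @param covariates Study covariate column names; defaults to the cohort's
#'   `covariates` attribute.
#' @param min_n Minimum complete cases; smaller strata are refused.
#' @return A data.frame with one row per model: `cohort`, `trait`, `label`,
#'   `stratum`, `beta`, `se`, `n`.
#' @export
cohort_associations <- function(cohort, trait,
                                stratum = c("all", "e4_carrier", "e4_noncarrier"),
                                covariates = attr(cohort, "covariates"),
                                min_n = 30) {
  stratum <- match.arg(stratum)
  if (!(trait %in% names(cohort))) {
    stop("trait '", trait, "' not available in cohort ",
         attr(cohort, "cohort"))
  }
  if (is.null(covariates)) covariates <- character(0)
  data <- cohort
  if (stratum != "all") {
    if (!("apoe" %in% names(cohort)) || all(is.na(cohort$apoe))) {
      stop("APOE genotype unavailable in cohort ", attr(cohort, "cohort"))
    }
    strata <- stratify_apoe(cohort)
    data <- if (stratum == "e4_carrier") strata$carrier else strata$noncarrier
  }
  needed <- c("tl_raw", "grs", trait, "age", "sex", covariates)
  complete <- stats::complete.cases(data[, needed])
  if (sum(complete) < min_n) {
    stop("cohort too small: ", sum(complete), " complete cases in stratum '",
         stratum, "' of ", attr(cohort, "cohort"), " (minimum ", min_n, ")")
  }
  data <- data[complete, , drop = FALSE]
  tl_z <- z_transform(data$tl_raw, name = "tl_raw")
  trait_z <- z_transform(data[[trait]], name = trait)
  adj <- adjuster_matrix(data, covariates)

  one <- function(y, x, xname, label) {
    X <- cbind(adj[, 1, drop = FALSE], x, adj[, -1, drop = FALSE])
    colnames(X)[2] <- xname
    fit <- suppressWarnings(fit_linear(y, X))
    cbind(data.frame(cohort = attr(cohort, "cohort") %||% "cohort",
                     trait = trait, label = label, stratum = stratum,
                     stringsAsFactors = FALSE),
          fit$estimate)
  }
  rbind(
    one(trait_z, tl_z, "tl_z", "TL_trait"),
    one(tl_z, data$grs, "grs", "GRS_TL"),
    one(trait_z, data$grs, "grs", "GRS_trait")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trait-independent first-stage model
#'
#' Fits the GRS-to-TL regression on the cohort's full (trait-agnostic)
#' sample, so that a single pooled instrument first stage — and a single
#' instrument F statistic — can serve every trait's Wald ratio, as in a
#' design where all genotyped individuals contribute to the instrument
#' regardless of which cognitive tests they took.
#'
#' @inheritParams cohort_associations
#' @return A one-row data.frame like [cohort_associations()] with
#'   `label = "GRS_TL"` and `trait = "ALL"`.
#' @export
cohort_first_stage <- function(cohort,
                               stratum = c("all", "e4_carrier", "e4_noncarrier"),
                               covariates = attr(cohort, "covariates"),
                               min_n = 30) {
  stratum <- match.arg(stratum)
  if (is.null(covariates)) covariates <- character(0)
  data <- cohort
  if (stratum != "all") {
    if (!("apoe" %in% names(cohort)) || all(is.na(cohort$apoe))) {
      stop("APOE genotype unavailable in cohort ", attr(cohort, "cohort"))
    }
    strata <- stratify_apoe(cohort)
    data <- if (stratum == "e4_carrier") strata$carrier else strata$noncarrier
  }
  needed <- c("tl_raw", "grs", "age", "sex", covariates)
  complete <- stats::complete.cases(data[, needed])
  if (sum(complete) < min_n) {
    stop("cohort too small: ", sum(complete), " complete cases in stratum '",
         stratum, "' of ", attr(cohort, "cohort"), " (minimum ", min_n, ")")
  }
  data <- data[complete, , drop = FALSE]
  tl_z <- z_transform(data$tl_raw, name = "tl_raw")
  adj <- adjuster_matrix(data, covariates)
  X <- cbind(adj[, 1, drop = FALSE], grs = data$grs, adj[, -1, drop = FALSE])
  fit <- suppressWarnings(fit_linear(tl_z, X))
  cbind(data.frame(cohort = attr(cohort, "cohort") %||% "cohort",
                   trait = "ALL", label = "GRS_TL", stratum = stratum,
                   stringsAsFactors = FALSE),
        fit$estimate)
}
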