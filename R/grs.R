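COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a, b) identical(unname(COMPLEMENT[a]), b)

#' Orient a dosage column to a reference counted allele
#'
#' Harmonizes an observed genotype (or summary-statistic) allele coding to
#' the reference SNP definition before score building or two-sample MR:
#' dosages are left unchanged when the observed effect allele matches the
#' reference counted allele, recoded `d -> 2 - d` when the allele pair is
#' swapped, and strand flips (the observed pair reported on the opposite
#' strand) are resolved by complementing before matching. Palindromic SNPs
#' (A/T or C/G) with minor-allele frequency near 0.5 cannot be oriented
#' from allele labels and are refused; away from 0.5 the effect-allele
#' frequency decides orientation.
#'
#' @param dosages Numeric vector of dosages in `[0, 2]` (`NA` allowed).
#' @param effect_allele,other_allele Observed allele pair (single bases).
#' @param reference One row of a SNP definition table ([default_snps()]).
#' @param eaf Observed effect-allele frequency, required to orient
#'   palindromic SNPs.
#' @return Numeric vector of dosages counting the reference effect allele,
#'   with attribute `orientation` in `c("as-is", "flipped")`.
#' @export
align_alleles <- function(dosages, effect_allele, other_allele, reference,
                          eaf = NULL) {
  bases <- names(COMPLEMENT)
  if (!(effect_allele %in% bases) || !(other_allele %in% bases)) {
    stop("alleles must be single bases A/C/G/T")
  }
  ref_e <- reference$effect_allele
  ref_o <- reference$other_allele

  if (is_palindromic(effect_allele, other_allele)) {
    freq <- if (!is.null(eaf)) eaf else reference$eaf
    if (freq >= 0.4 && freq <= 0.6) {
      stop("ambiguous strand: palindromic SNP ", reference$rsid,
           " with allele frequency ", format(freq), " in [0.4, 0.6]")
    }
    # strand is unresolvable from labels; use frequency concordance
    same <- (eaf_side(freq) == eaf_side(reference$eaf))
    out <- if (same) dosages else 2 - dosages
    attr(out, "orientation") <- if (same) "as-is" else "flipped"
    return(out)
  }

  orientation <- if (effect_allele == ref_e && other_allele == ref_o) {
    "as-is"
  } else if (effect_allele == ref_o && other_allele == ref_e) {
    "flipped"
  } else if (identical(unname(COMPLEMENT[effect_allele]), ref_e) &&
             identical(unname(COMPLEMENT[other_allele]), ref_o)) {
    "as-is"
  } else if (identical(unname(COMPLEMENT[effect_allele]), ref_o) &&
             identical(unname(COMPLEMENT[other_allele]), ref_e)) {
    "flipped"
  } else {
    stop("alleles ", effect_allele, "/", other_allele,
         " match neither orientation of reference ", ref_e, "/", ref_o,
         " for ", reference$rsid)
  }
  out <- if (orientation == "as-is") dosages else 2 - dosages
  attr(out, "orientation") <- orientation
  out
}

eaf_side <- function(freq) if (freq >= 0.5) "high" else "low"

#' Build the additive unweighted genetic risk score
#'
#' Sums, per individual, the number of counted (telomere-shortening) alleles
#' across the instrument loci: `score_i = sum_j d_ij` for dosage columns
#' already oriented to the counted allele. The score ranges 0 to twice the
#' number of SNPs (0-14 for the default 7-SNP instrument). Missing dosages
#' are either mean-imputed at the Hardy-Weinberg expectation `2*eaf_j`
#' (default, mirroring score construction from imputed data) or, under
#' `"drop"`, propagate to a missing score for that individual.
#'
#' @param dosages Numeric matrix (individuals x SNPs), columns in the order
#'   of `snps`, entries in `[0, 2]` or `NA`.
#' @param snps SNP definition table supplying `eaf` for imputation.
#' @param missing_policy `"mean_impute"` or `"drop"`.
#' @return A data.frame with `score` and `n_snps_used` (number of observed,
#'   non-imputed dosages entering each score).
#' @export
build_grs <- function(dosages, snps = default_snps(),
                      missing_policy = c("mean_impute", "drop")) {
  missing_policy <- match.arg(missing_policy)
  dosages <- as.matrix(dosages)
  validate_snps(snps)
  if (ncol(dosages) != nrow(snps)) {
    stop("dosage matrix has ", ncol(dosages), " columns but ", nrow(snps),
         " SNPs are defined")
  }
  all_missing <- apply(dosages, 2, function(x) all(is.na(x)))
  if (any(all_missing)) {
    stop("all-missing dosage column(s): ",
         paste(snps$rsid[all_missing], collapse = ", "))
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  n_used <- rowSums(!is.na(dosages))
  if (missing_policy == "mean_impute") {
    for (j in seq_len(ncol(dosages))) {
      miss <- is.na(dosages[, j])
      if (any(miss)) dosages[miss, j] <- 2 * snps$eaf[j]
    }
    score <- rowSums(dosages)
  } else {
    score <- rowSums(dosages) # NA when any dosage missing
  }
  data.frame(score = score, n_snps_used = n_used)
}

#' Append a GRS column to a cohort table
#'
#' Convenience wrapper: extracts the dosage columns named by `snps$rsid`
#' from a cohort table and adds the unweighted allele count as column `grs`.
#'
#' @inheritParams build_grs
#' @param cohort Cohort data.frame containing one dosage column per rsid.
#' @return The cohort with an added `grs` column (attributes preserved).
#' @export
add_grs <- function(cohort, snps = default_snps(),
                    missing_policy = "mean_impute") {
  missing_cols <- setdiff(snps$rsid, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks dosage column(s): ", paste(missing_cols, collapse = ", "))
  }
  g <- build_grs(as.matrix(cohort[, snps$rsid]), snps, missing_policy)
  cohort$grs <- g$score
  cohort
}
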