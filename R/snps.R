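#' Default telomere-length instrument SNPs
#'
#' The seven loci used to build the unweighted genetic risk score (GRS) for
#' leukocyte telomere length: \emph{TERC, TERT, NAF1, OBFC1, ZNF208, RTEL1}
#' and \emph{ACYP2}. The counted ("risk") allele is the telomere-SHORTENING
#' allele, so each per-allele effect on standardized TL (`beta_tl`) is
#' negative and the pooled GRS-to-TL regression slope is negative.
#'
#' Effect-allele frequencies and per-allele effects are simulation truth, not
#' published estimates: the frequencies are chosen so that the population GRS
#' has mean `sum(2*eaf) = 8.55` and standard deviation
#' `sqrt(sum(2*eaf*(1-eaf)))` close to 1.5 under Hardy-Weinberg equilibrium,
#' and every per-allele effect defaults to -0.05 s.d. of TL.
#'
#' @param beta_tl Per-allele effect of the counted allele on TL in s.d.
#'   units; recycled across the seven loci. Default -0.05.
#' @return A data.frame with columns `rsid`, `gene_label`, `effect_allele`,
#'   `other_allele`, `eaf` and `beta_tl`, one row per locus.
#' @examples
#' snps <- default_snps()
#' sum(2 * snps$eaf) # expected GRS mean, 8.55
#' @export
default_snps <- function(beta_tl = -0.05) {
  snps <- data.frame(
    rsid = c("rs10936599", "rs2736100", "rs7675998", "rs9420907",
             "rs8105767", "rs755017", "rs11125529"),
    gene_label = c("TERC", "TERT", "NAF1", "OBFC1", "ZNF208", "RTEL1", "ACYP2"),
    effect_allele = c("C", "A", "G", "C", "G", "G", "A"),
    other_allele  = c("T", "C", "A", "A", "A", "A", "C"),
    eaf = c(0.18, 0.30, 0.50, 0.625, 0.78, 0.92, 0.97),
    stringsAsFactors = FALSE
  )
  snps$beta_tl <- rep_len(beta_tl, nrow(snps))
  validate_snps(snps)
  snps
}

validate_snps <- function(snps) {
  stopifnot(is.data.frame(snps), nrow(snps) >= 1)
  required <- c("rsid", "effect_allele", "other_allele", "eaf", "beta_tl")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    stop("SNP table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(snps$rsid)) stop("duplicate rsids in SNP table")
  if (any(snps$eaf <= 0 | snps$eaf >= 1)) {
    stop("effect-allele frequencies must lie strictly in (0, 1)")
  }
  if (any(snps$effect_allele == snps$other_allele)) {
    stop("effect allele must differ from other allele")
  }
  invisible(snps)
}
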