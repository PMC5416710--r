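APOE_GENOTYPES <- c("e2/e2", "e2/e3", "e2/e4", "e3/e3", "e3/e4", "e4/e4")

write_tsv_commented <- function(x, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_commented <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write / read a cohort table
#'
#' Tab-separated text with header columns `id`, one dosage column per rsid,
#' `tl_raw`, `age`, `sex`, `apoe`, optional covariates/`grs`, and one
#' column per trait; missing values are `NA` and an optional leading
#' comment line records the master seed. Reading validates the invariants
#' (dosages in `[0, 2]`, `tl_raw > 0`, known APOE strings) with
#' row-numbered messages.
#'
#' @param cohort Cohort data.frame (see [simulate_cohort()]).
#' @param path File path.
#' @param seed Optional seed recorded in a `# seed:` comment header.
#' @param name Cohort name attached as attribute on read.
#' @param covariates Covariate column names attached as attribute on read.
#' @param snps SNP definitions naming the expected dosage columns.
#' @return `write_cohort_table` the path, invisibly; `read_cohort_table`
#'   the validated data.frame.
#' @export
write_cohort_table <- function(cohort, path, seed = NULL) {
  write_tsv_commented(cohort, path, seed = seed)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path, snps = default_snps(),
                              name = sub("\\.[^.]*$", "", basename(path)),
                              covariates = character(0)) {
  tab <- read_tsv_commented(path)
  required <- c("id", snps$rsid, "tl_raw", "age", "sex")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("cohort file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (rsid in snps$rsid) {
    d <- tab[[rsid]]
    if (!is.numeric(d)) stop("non-numeric dosages in column ", rsid)
    bad <- which(!is.na(d) & (d < 0 | d > 2))
    if (length(bad) > 0) {
      stop("dosage out of [0, 2] at row ", bad[1], ", column ", rsid,
           " (value ", d[bad[1]], ")")
    }
  }
  bad_tl <- which(!is.na(tab$tl_raw) & tab$tl_raw <= 0)
  if (length(bad_tl) > 0) stop("non-positive tl_raw at row ", bad_tl[1])
  if ("apoe" %in% names(tab)) {
    bad_apoe <- which(!is.na(tab$apoe) & !(tab$apoe %in% APOE_GENOTYPES))
    if (length(bad_apoe) > 0) {
      stop("malformed APOE genotype '", tab$apoe[bad_apoe[1]], "' at row ",
           bad_apoe[1])
    }
  } else {
    tab$apoe <- NA_character_
  }
  attr(tab, "cohort") <- name
  attr(tab, "covariates") <- covariates
  tab
}

#' Write / read per-SNP GWAS summary statistics
#'
#' Tab-separated text with columns `rsid`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `n`. Reading rejects non-positive standard errors
#' and frequencies outside (0, 1).
#'
#' @param rows Summary-statistic data.frame.
#' @param path File path.
#' @param seed Optional seed recorded as a comment header.
#' @return `write_summary_stats` the path, invisibly; `read_summary_stats`
#'   the validated data.frame.
#' @export
write_summary_stats <- function(rows, path, seed = NULL) {
  write_tsv_commented(rows, path, seed = seed)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  tab <- read_tsv_commented(path)
  required <- c("rsid", "effect_allele", "other_allele", "eaf", "beta", "se", "n")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("summary-statistic file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_se <- which(!is.na(tab$se) & tab$se <= 0)
  if (length(bad_se) > 0) stop("non-positive se at row ", bad_se[1])
  bad_eaf <- which(!is.na(tab$eaf) & (tab$eaf <= 0 | tab$eaf >= 1))
  if (length(bad_eaf) > 0) stop("allele frequency outside (0, 1) at row ", bad_eaf[1])
  tab
}

#' Write per-cohort or pooled estimates
#'
#' @param rows Estimates data.frame (e.g. stacked [cohort_associations()]).
#' @param path File path.
#' @param seed Optional seed recorded as a comment header.
#' @return The path, invisibly.
#' @export
write_estimates <- function(rows, path, seed = NULL) {
  write_tsv_commented(rows, path, seed = seed)
}

#' Read a run configuration file
#'
#' YAML with top-level keys `seed`, `switch_p`, `weak_z`, `min_n`,
#' `traits`, `stratify_apoe`, a `truth` block (passed to [true_params()])
#' and a `cohorts` block: either `cohorts: table1` for the built-in
#' 14-stratum template or a named map of [cohort_config()] fields.
#'
#' @param path YAML file path.
#' @return A list ready for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  # YAML 1.1 would coerce the bare key "n" (cohort size) to FALSE; keep the
  # single letters as strings while leaving true/false/yes/no as logicals
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#no" = function(x) if (x %in% c("n", "N")) x else FALSE,
    "bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE
  ))
  cfg <- list(
    seed = raw$seed %||% 1L,
    switch_p = raw$switch_p %||% 0.05,
    weak_z = raw$weak_z %||% 2,
    min_n = raw$min_n %||% 30,
    traits = raw$traits %||% TRAIT_NAMES,
    stratify_apoe = raw$stratify_apoe %||% FALSE
  )
  cfg$truth <- if (is.null(raw$truth)) true_params() else {
    do.call(true_params, lapply(raw$truth, function(x) {
      if (is.list(x)) unlist(x) else x
    }))
  }
  cfg$configs <- if (is.null(raw$cohorts) || identical(raw$cohorts, "table1")) {
    table1_configs()
  } else {
    lapply(names(raw$cohorts), function(nm) {
      args <- raw$cohorts[[nm]]
      args$name <- nm
      args$traits_available <- unlist(args$traits_available %||% TRAIT_NAMES)
      do.call(cohort_config, args)
    })
  }
  cfg
}
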