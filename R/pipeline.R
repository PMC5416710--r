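#' Cohort descriptive summary with sample-size-weighted means
#'
#' Summarizes each cohort (n, mean age, raw T/S mean and s.d., GRS mean and
#' s.d., trait availability) and computes sample-size-weighted means of the
#' per-cohort statistics, `sum(n_c m_c) / sum(n_c)` — the convention used
#' for the study-wide mean age and mean GRS.
#'
#' @param cohorts Named list of cohort data.frames (with `grs` column), or
#'   a pre-computed per-cohort summary data.frame with columns `n` and the
#'   statistics to weight.
#' @return List: `cohorts` (per-cohort rows) and `weighted` (named vector
#'   of sample-size-weighted means, plus `total_n`).
#' @export
weighted_cohort_summary <- function(cohorts) {
  if (length(cohorts) == 0) stop("no cohorts supplied")
  if (is.data.frame(cohorts)) {
    tab <- cohorts
  } else {
    tab <- do.call(rbind, lapply(names(cohorts), function(nm) {
      ch <- cohorts[[nm]]
      traits <- intersect(TRAIT_NAMES, names(ch))
      data.frame(
        cohort = nm, n = nrow(ch),
        age_mean = mean(ch$age, na.rm = TRUE),
        tl_mean = mean(ch$tl_raw, na.rm = TRUE),
        tl_sd = stats::sd(ch$tl_raw),
        pct_women = 100 * mean(ch$sex == "female", na.rm = TRUE),
        grs_mean = if ("grs" %in% names(ch)) mean(ch$grs, na.rm = TRUE) else NA,
        grs_sd = if ("grs" %in% names(ch)) stats::sd(ch$grs) else NA,
        traits = paste(traits, collapse = ","),
        stringsAsFactors = FALSE
      )
    }))
  }
  num <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))], "n")
  weighted <- vapply(num, function(col) {
    ok <- !is.na(tab[[col]])
    sum(tab$n[ok] * tab[[col]][ok]) / sum(tab$n[ok])
  }, numeric(1))
  list(cohorts = tab,
       weighted = c(total_n = sum(tab$n), weighted))
}

pool_by_group <- function(estimates, switch_p = 0.05) {
  groups <- split(estimates,
                  list(estimates$trait, estimates$label, estimates$stratum),
                  drop = TRUE)
  do.call(rbind, lapply(groups, function(g) {
    pooled <- pool_estimates(g, switch_p = switch_p)
    cbind(data.frame(trait = g$trait[1], label = g$label[1],
                     stratum = g$stratum[1], n = sum(g$n),
                     stringsAsFactors = FALSE),
          pooled)
  }))
}

mr_from_pooled <- function(pooled, trait, stratum, weak_z = 2) {
  sel <- function(label, tr = trait) {
    row <- pooled[pooled$trait == tr & pooled$label == label &
                    pooled$stratum == stratum, ]
    if (nrow(row) != 1) return(NULL)
    row
  }
  gy <- sel("GRS_trait")
  obs <- sel("TL_trait")
  # common instrument first stage, pooled over every cohort in the stratum
  gx <- sel("GRS_TL", tr = "ALL") %||% sel("GRS_TL")
  if (is.null(gy) || is.null(gx) || is.null(obs)) return(NULL)
  iv <- wald_iv(gy, gx, trait = trait, stratum = stratum, weak_z = weak_z)
  d <- difference_test(obs, iv)
  iv$diff_z <- d$z
  iv$diff_p <- d$p
  iv$n <- gy$n
  iv$obs_beta <- obs$beta
  iv$obs_ci_low <- obs$ci_low
  iv$obs_ci_high <- obs$ci_high
  iv$obs_p <- obs$p
  iv
}

#' Run the full one-sample MR pipeline
#'
#' Orchestrates simulate/load -> GRS -> per-cohort association models
#' (overall and, where APOE is available, e4-carrier and non-carrier
#' strata) -> heterogeneity-switched pooling per trait and model -> Wald
#' IV estimate with instrument F statistic and observed-vs-causal
#' difference test per trait and stratum. Optionally writes the report
#' bundle as tab-separated files (cohort summary, per-cohort estimates,
#' pooled estimates, MR results) plus a run manifest, every file carrying
#' the master seed in a comment header.
#'
#' @param config A list as returned by [read_run_config()]; recognised
#'   elements: `configs` (list of [cohort_config()]) or `cohort_files`
#'   (paths read with [read_cohort_table()]), `truth`, `snps`, `traits`,
#'   `stratify_apoe`, `switch_p`, `weak_z`, `min_n`, `seed`.
#' @param out_dir Optional output directory for the report bundle.
#' @return List: `cohort_summary`, `estimates` (per cohort), `pooled`,
#'   `mr` (the trait-by-stratum results table), `skipped` (strata refused
#'   as too small or weak), `seed`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  seed <- as.integer(config$seed %||% 1L)
  snps <- config$snps %||% default_snps()
  truth <- config$truth %||% true_params()
  switch_p <- config$switch_p %||% 0.05
  weak_z <- config$weak_z %||% 2
  min_n <- config$min_n %||% 30
  strata <- if (isTRUE(config$stratify_apoe)) {
    c("all", "e4_carrier", "e4_noncarrier")
  } else "all"

  cohorts <- if (!is.null(config$cohort_files)) {
    stats::setNames(lapply(config$cohort_files, read_cohort_table, snps = snps),
                    vapply(config$cohort_files,
                           function(p) sub("\\.[^.]*$", "", basename(p)),
                           character(1)))
  } else {
    configs <- config$configs %||% table1_configs()
    simulate_multi_cohort(configs, snps = snps, truth = truth, seed = seed)
  }
  cohorts <- lapply(cohorts, add_grs, snps = snps)

  skipped <- character(0)
  rows <- list()
  for (nm in names(cohorts)) {
    ch <- cohorts[[nm]]
    traits <- intersect(config$traits %||% TRAIT_NAMES,
                        intersect(TRAIT_NAMES, names(ch)))
    for (st in strata) {
      if (st != "all" && all(is.na(ch$apoe))) next
      fs <- tryCatch(
        cohort_first_stage(ch, stratum = st, min_n = min_n),
        error = function(e) {
          skipped <<- c(skipped, paste0(nm, "/first-stage/", st, ": ",
                                        conditionMessage(e)))
          NULL
        })
      if (!is.null(fs)) rows[[length(rows) + 1]] <- fs
      for (tr in traits) {
        res <- tryCatch(
          cohort_associations(ch, tr, stratum = st, min_n = min_n),
          error = function(e) {
            skipped <<- c(skipped, paste0(nm, "/", tr, "/", st, ": ",
                                          conditionMessage(e)))
            NULL
          })
        if (!is.null(res)) rows[[length(rows) + 1]] <- res
      }
    }
  }
  if (length(rows) == 0) stop("association stage produced no estimates")
  estimates <- do.call(rbind, rows)
  pooled <- pool_by_group(estimates, switch_p = switch_p)

  mr_rows <- list()
  for (tr in setdiff(unique(pooled$trait), "ALL")) {
    for (st in unique(pooled$stratum)) {
      res <- tryCatch(mr_from_pooled(pooled, tr, st, weak_z = weak_z),
                      error = function(e) {
                        skipped <<- c(skipped, paste0("IV ", tr, "/", st, ": ",
                                                      conditionMessage(e)))
                        NULL
                      })
      if (!is.null(res)) mr_rows[[length(mr_rows) + 1]] <- res
    }
  }
  mr_tab <- if (length(mr_rows) > 0) do.call(rbind, mr_rows) else NULL

  summary <- weighted_cohort_summary(cohorts)
  bundle <- list(cohort_summary = summary, estimates = estimates,
                 pooled = pooled, mr = mr_tab, skipped = skipped, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_commented(summary$cohorts, file.path(out_dir, "cohort_summary.tsv"),
                        seed = seed)
    write_estimates(estimates, file.path(out_dir, "cohort_estimates.tsv"),
                    seed = seed)
    write_estimates(pooled, file.path(out_dir, "pooled_estimates.tsv"),
                    seed = seed)
    if (!is.null(mr_tab)) {
      write_estimates(mr_tab, file.path(out_dir, "mr_results.tsv"), seed = seed)
    }
    manifest <- c(paste0("seed: ", seed),
                  paste0("switch_p: ", switch_p),
                  paste0("weak_z: ", weak_z),
                  paste0("min_n: ", min_n),
                  paste0("n_cohorts: ", length(cohorts)),
                  paste0("skipped: ", length(skipped)))
    writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  }
  bundle
}
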