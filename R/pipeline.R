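# End-to-end protocol comparison: simulate (or ingest) -> harmonize ->
# smooth -> apply each QC protocol -> balance + quality comparison -> VBM.

#' Pipeline configuration
#'
#' @param synth a [synth_config()] describing the simulated cohort (or
#'   `NULL` when `cohort`/`dataset` are supplied directly to
#'   [run_protocol_comparison()]).
#' @param protocols subset of `c("full_inclusion", "exclusion", "matching")`.
#' @param exclusion_threshold_pct exclusion cutoff on the image quality
#'   rating (percent).
#' @param match a [match_spec()] for the matching protocol.
#' @param match_covariates propensity covariates.
#' @param vbm_covariates nuisance covariates for the VBM design.
#' @param fwhm_mm smoothing kernel FWHM.
#' @param n_perm permutations for the maxT FWE correction.
#' @param alpha voxel-level FWE threshold.
#' @param extent_k cluster extent threshold.
#' @param peak_sep_mm distinct-peak separation.
#' @param harmonization `"auto"` (harmonize when the cohort has >1 site),
#'   `"on"`, or `"off"`; `eb` toggles empirical-Bayes shrinkage.
#' @param eb empirical-Bayes shrinkage for harmonization.
#' @param seed master seed for simulation and permutations.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            protocols = c("full_inclusion", "exclusion", "matching"),
                            exclusion_threshold_pct = 70,
                            match = match_spec(caliper_sd = 0.2,
                                               discard_unmatchable = TRUE),
                            match_covariates = c("iqr_pct", "euler", "defect_pct"),
                            vbm_covariates = c("tiv", "age", "sex"),
                            fwhm_mm = 8, n_perm = 200, alpha = 0.05,
                            extent_k = 1, peak_sep_mm = 8,
                            harmonization = c("auto", "on", "off"),
                            eb = TRUE, seed = 1L) {
  protocols <- match.arg(protocols, several.ok = TRUE)
  harmonization <- match.arg(harmonization)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full protocol comparison
#'
#' Generates (or takes) a cohort and its voxel data, harmonizes across
#' sites if applicable, smooths within the mask, then applies each
#' quality-control protocol and runs the identical VBM (per-voxel GLM with
#' permutation maxT FWE correction and cluster extraction) on each
#' protocol's subject selection. Harmonization and smoothing use all
#' subjects and precede protocol selection.
#'
#' @param config a [pipeline_config()].
#' @param cohort,dataset optionally supply a [cohort_table()] and aligned
#'   `voxel_dataset` instead of simulating.
#' @return a `comparison_report`: per protocol, sample sizes, the
#'   scan-quality [quality_comparison()] per metric, the [balance_report()]
#'   (matching only), significant-voxel count and [extract_clusters()]
#'   table; plus config echo and seed.
#' @export
run_protocol_comparison <- function(config = pipeline_config(),
                                    cohort = NULL, dataset = NULL) {
  seed <- config$seed
  truth <- NULL
  if (is.null(cohort)) {
    gen <- generate_cohort(config$synth, seed = seed)
    cohort <- gen$cohort
    vols <- generate_volumes(cohort, gen$truth, config$synth, seed = seed)
    dataset <- vols$dataset
    truth <- vols$truth
  } else if (is.null(dataset)) {
    qc_stop("qcmatch_validation_error", "dataset required with a supplied cohort")
  }
  if (!identical(dataset$subject_ids, cohort$subject_id))
    qc_stop("qcmatch_alignment_error", "dataset and cohort subject order differ")

  do_harmonize <- switch(config$harmonization,
                         on = TRUE, off = FALSE,
                         auto = length(unique(cohort$site)) > 1)
  harmonization_model <- NULL
  if (do_harmonize) {
    covm <- cbind(group = as.numeric(is_treated(cohort)), age = cohort$age,
                  sex_m = as.numeric(cohort$sex == "M"))
    covm <- covm[, apply(covm, 2, stats::sd) > 0, drop = FALSE]
    h <- combat_harmonize(dataset, cohort$site, covm, eb = config$eb)
    dataset <- h$dataset
    harmonization_model <- h$model
  }
  dataset <- smooth_volume(dataset, fwhm_mm = config$fwhm_mm)

  metrics <- c("iqr_pct", "euler", "defect_pct")
  entries <- list()
  for (pk in config$protocols) {
    pspec <- protocol_spec(pk,
                           exclusion_threshold_pct = config$exclusion_threshold_pct,
                           match_spec = config$match,
                           match_covariates = config$match_covariates)
    sel <- apply_protocol(cohort, pspec)
    tab <- sel$table
    sub <- subset_voxel_dataset(dataset, tab$subject_id)
    design <- glm_design(tab, config$vbm_covariates)
    map <- permutation_fwe(sub, design, n_perm = config$n_perm,
                           seed = seed + 1000L)
    clusters <- extract_clusters(map, alpha = config$alpha,
                                 extent_k = config$extent_k,
                                 peak_sep_mm = config$peak_sep_mm)
    bal <- if (!is.null(sel$match_result))
      balance_report(cohort, sel$match_result, config$match_covariates,
                     sel$scores) else NULL
    entries[[pk]] <- list(
      protocol = pk,
      n_treated = sum(is_treated(tab)),
      n_control = sum(!is_treated(tab)),
      quality = do.call(rbind, lapply(metrics, quality_comparison, table = tab)),
      balance = bal,
      match_result = sel$match_result,
      n_significant = sum(map$p_fwe <= config$alpha),
      significant_index = dataset$voxel_index[map$p_fwe <= config$alpha],
      tmap = map,
      clusters = clusters)
  }
  structure(list(protocols = entries, config = config, seed = seed,
                 truth = truth, mask = dataset$mask,
                 harmonization_model = harmonization_model,
                 version = as.character(utils::packageVersion("qcmatch"))),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report (seed", x$seed, "):\n")
  for (e in x$protocols)
    cat(sprintf("  %-15s n=%d/%d  significant voxels=%d  clusters=%d\n",
                e$protocol, e$n_treated, e$n_control, e$n_significant,
                if (nrow(e$clusters)) max(e$clusters$cluster) else 0L))
  invisible(x)
}

#' Compare significant-voxel sets between two protocols
#'
#' @param report a `comparison_report`.
#' @param protocol_a,protocol_b protocol names present in the report.
#' @return list with `n_a`, `n_b`, `percent_difference`
#'   (`100 * (n_b - n_a) / n_a`), `jaccard` overlap of the significant
#'   voxel sets.
#' @export
summarize_voxel_overlap <- function(report, protocol_a, protocol_b) {
  a <- report$protocols[[protocol_a]]
  b <- report$protocols[[protocol_b]]
  if (is.null(a) || is.null(b))
    qc_stop("qcmatch_validation_error", "protocol not present in report")
  sa <- a$significant_index
  sb <- b$significant_index
  un <- length(union(sa, sb))
  list(n_a = length(sa), n_b = length(sb),
       percent_difference = if (length(sa)) 100 * (length(sb) - length(sa)) / length(sa) else NA_real_,
       jaccard = if (un) length(intersect(sa, sb)) / un else 1)
}

#' Serialize a comparison report
#'
#' Writes `report.json` (sample sizes, quality comparisons, balance, cluster
#' tables, config echo, seed, version) plus per-protocol cluster and
#' quality TSVs into `dir`.
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if needed).
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  j <- list(seed = report$seed, version = report$version,
            protocols = lapply(report$protocols, function(e) {
              list(protocol = e$protocol, n_treated = e$n_treated,
                   n_control = e$n_control,
                   quality = as.data.frame(e$quality),
                   balance = if (!is.null(e$balance)) as.data.frame(e$balance),
                   n_significant = e$n_significant,
                   clusters = as.data.frame(e$clusters))
            }),
            config = config_echo(report$config))
  jsonlite::write_json(j, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  for (e in report$protocols) {
    utils::write.table(as.data.frame(e$quality),
                       file.path(dir, paste0("quality_", e$protocol, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(e$clusters),
                       file.path(dir, paste0("clusters_", e$protocol, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(e$balance))
      export_love_data(e$balance, file.path(dir, paste0("love_", e$protocol, ".tsv")))
  }
  invisible(NULL)
}

# Flatten config (dropping function-valued / class attrs) for JSON echo.
config_echo <- function(config) {
  drop_classes <- function(x) {
    if (is.list(x)) lapply(unclass(x), drop_classes) else x
  }
  drop_classes(config)
}
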