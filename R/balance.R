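# Covariate balance diagnostics: standardized mean differences before and
# after matching, and Love-plot data export.

#' Standardized mean difference
#'
#' `(mean(treated) - mean(control)) / sd_reference`. The reference SD
#' defaults to the pooled (average-of-variances) SD of the two samples;
#' [balance_report()] computes it on the pre-matching sample and reuses it
#' post-matching so both phases sit on one scale.
#'
#' @param values_treated,values_control numeric samples (nonempty).
#' @param sd_reference positive reference SD; default pooled SD of the two
#'   samples.
#' @return scalar SMD.
#' @export
smd <- function(values_treated, values_control, sd_reference = NULL) {
  if (!length(values_treated) || !length(values_control))
    qc_stop("qcmatch_validation_error", "both samples must be nonempty")
  if (is.null(sd_reference))
    sd_reference <- pooled_sd(values_treated, values_control)
  if (!is_scalar_number(sd_reference) || sd_reference <= 0)
    qc_stop("qcmatch_degenerate_error", "reference SD must be positive ",
            "(degenerate covariate)")
  (mean(values_treated) - mean(values_control)) / sd_reference
}

#' Balance report before and after matching
#'
#' Per covariate (plus a synthetic `"distance"` row for the propensity
#' logit): SMD on the full unmatched groups, SMD on the matched subjects
#' with the same pre-matching reference SD, variance ratios
#' (treated/control) as a secondary diagnostic, and balanced flags at
#' `|SMD| < threshold`.
#'
#' @param pre_table the unmatched [cohort_table()].
#' @param match_result a `match_result` (must contain at least one pair).
#' @param covariates numeric covariate columns to report.
#' @param scores `propensity_scores` aligned to `pre_table` (for the
#'   distance row); optional.
#' @param threshold balance threshold on `|SMD|`; the conventional 0.1.
#' @return a `balance_report` data frame with columns `covariate`,
#'   `smd_pre`, `smd_post`, `variance_ratio_pre`, `variance_ratio_post`,
#'   `balanced_pre`, `balanced_post`.
#' @export
balance_report <- function(pre_table, match_result, covariates,
                           scores = NULL, threshold = 0.1) {
  if (!nrow(match_result$pairs))
    qc_stop("qcmatch_validation_error", "match result has no pairs")
  tr_pre <- is_treated(pre_table)
  post <- apply_match(pre_table, match_result)
  tr_post <- is_treated(post)
  columns <- lapply(covariates, function(v) {
    if (!v %in% names(pre_table))
      qc_stop("qcmatch_schema_error", "covariate not in table: ", v)
    list(name = v, pre = pre_table[[v]], post = post[[v]])
  })
  if (!is.null(scores)) {
    idx <- match(post$subject_id, scores$subject_id)
    columns <- c(columns,
                 list(list(name = "distance", pre = scores$linear_predictor,
                           post = scores$linear_predictor[idx])))
  }
  rows <- lapply(columns, function(cl) {
    sd_ref <- pooled_sd(cl$pre[tr_pre], cl$pre[!tr_pre])
    data.frame(
      covariate = cl$name,
      smd_pre = smd(cl$pre[tr_pre], cl$pre[!tr_pre], sd_ref),
      smd_post = smd(cl$post[tr_post], cl$post[!tr_post], sd_ref),
      variance_ratio_pre = stats::var(cl$pre[tr_pre]) / stats::var(cl$pre[!tr_pre]),
      variance_ratio_post = stats::var(cl$post[tr_post]) / stats::var(cl$post[!tr_post]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$balanced_pre <- abs(out$smd_pre) < threshold
  out$balanced_post <- abs(out$smd_post) < threshold
  structure(out, threshold = threshold,
            class = c("balance_report", "data.frame"))
}

#' @export
print.balance_report <- function(x, ...) {
  cat("balance_report (|SMD| threshold", attr(x, "threshold"), "):\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Export Love-plot data
#'
#' Long-format TSV with one row per covariate and phase
#' (`unmatched`/`matched`), columns `covariate`, `phase`, `smd`, `abs_smd`.
#' The balance reference value is recorded in a `# reference_abs_smd:`
#' header line.
#'
#' @param report a [balance_report()].
#' @param path output path.
#' @export
export_love_data <- function(report, path) {
  long <- rbind(
    data.frame(covariate = report$covariate, phase = "unmatched",
               smd = report$smd_pre, stringsAsFactors = FALSE),
    data.frame(covariate = report$covariate, phase = "matched",
               smd = report$smd_post, stringsAsFactors = FALSE))
  long$abs_smd <- abs(long$smd)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# reference_abs_smd: ", attr(report, "threshold")), con)
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
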