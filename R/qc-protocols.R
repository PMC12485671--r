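# The three quality-control protocols (full inclusion, threshold exclusion,
# propensity matching) and the between-protocol scan-quality comparisons.

#' Quality-control protocol specification
#'
#' @param kind `"full_inclusion"` (keep everyone), `"exclusion"` (drop
#'   records with an image quality rating strictly below the threshold) or
#'   `"matching"` (1:1 propensity matching on the quality metrics).
#' @param exclusion_threshold_pct exclusion cutoff on `iqr_pct`; the
#'   conventional 70. Records strictly below are excluded; a record exactly
#'   at the threshold is retained.
#' @param match_spec a [match_spec()] used when `kind = "matching"`.
#' @param match_covariates covariates for the propensity model; default the
#'   three quality metrics (image quality rating, Euler number, defect
#'   size).
#' @return a `protocol_spec` list.
#' @export
protocol_spec <- function(kind = c("full_inclusion", "exclusion", "matching"),
                          exclusion_threshold_pct = 70,
                          match_spec = qcmatch::match_spec(),
                          match_covariates = c("iqr_pct", "euler", "defect_pct")) {
  kind <- match.arg(kind)
  if (!is_scalar_number(exclusion_threshold_pct) ||
      exclusion_threshold_pct <= 0 || exclusion_threshold_pct > 100)
    qc_stop("qcmatch_config_error", "exclusion threshold must lie in (0, 100]")
  structure(list(kind = kind,
                 exclusion_threshold_pct = exclusion_threshold_pct,
                 match_spec = match_spec,
                 match_covariates = match_covariates),
            class = "protocol_spec")
}

#' Apply a quality-control protocol
#'
#' Full inclusion returns the table unchanged; exclusion drops records whose
#' image quality rating is strictly below the threshold (a record exactly at
#' the threshold is retained); matching fits the propensity model on the
#' quality covariates, solves the 1:1 match and returns the matched subset.
#'
#' @param table a [cohort_table()].
#' @param spec a [protocol_spec()].
#' @param scores optional precomputed `propensity_scores` for the matching
#'   protocol (fitted from `spec$match_covariates` otherwise).
#' @return list with `table` (the selected [cohort_table()]) and
#'   `match_result` (`NULL` unless `kind = "matching"`).
#' @export
apply_protocol <- function(table, spec, scores = NULL) {
  switch(spec$kind,
    full_inclusion = list(table = table, match_result = NULL),
    exclusion = {
      keep <- table$iqr_pct >= spec$exclusion_threshold_pct
      out <- table[keep, , drop = FALSE]
      if (!all(c(treated_label(table), control_label(table)) %in% out$group))
        qc_stop("qcmatch_protocol_error",
                "exclusion at ", spec$exclusion_threshold_pct,
                "% empties a group")
      rownames(out) <- NULL
      list(table = cohort_table(as.data.frame(out),
                                treated_label = treated_label(table),
                                control_label = control_label(table),
                                name = paste0(attr(table, "name"), ":excl")),
           match_result = NULL)
    },
    matching = {
      if (is.null(scores)) {
        model <- fit_propensity(table, spec$match_covariates)
        scores <- compute_scores(model, table)
      }
      res <- if (spec$match_spec$method == "optimal")
        optimal_match(scores, table$group, spec$match_spec, table)
      else nearest_match(scores, table$group, spec$match_spec, table)
      list(table = apply_match(table, res), match_result = res,
           scores = scores)
    })
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. If both samples are constant, the statistic is
#' undefined when the means agree (an error) and reported as `+/-Inf` with
#' `p = 0` when they differ.
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @param var_equal use the pooled-variance (Student) form instead of Welch.
#' @return list with `t`, `df`, `p`.
#' @export
welch_ttest <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    qc_stop("qcmatch_validation_error", "each sample needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      qc_stop("qcmatch_degenerate_error",
              "t undefined: both samples constant with equal means")
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson's r effect size from a t statistic
#'
#' `r = sign(t) * sqrt(t^2 / (t^2 + df))`; approaches +/-1 as `|t|` grows.
#'
#' @param t t statistic.
#' @param df degrees of freedom (> 0).
#' @return scalar in (-1, 1) (or +/-1 for infinite `t`).
#' @export
pearson_r_from_t <- function(t, df) {
  if (!is_scalar_number(df) || df <= 0)
    qc_stop("qcmatch_validation_error", "df must be positive")
  if (is.infinite(t)) return(sign(t))
  sign(t) * sqrt(t^2 / (t^2 + df))
}

#' Between-group scan-quality comparison for one metric
#'
#' Per-group (min, max) ranges plus the Welch t-test and its Pearson's r
#' effect size, as reported per protocol in scan-quality overview tables.
#'
#' @param table a [cohort_table()] (post-protocol selection).
#' @param metric numeric column name, e.g. `"iqr_pct"`.
#' @param var_equal passed to [welch_ttest()].
#' @return a `quality_comparison` one-row data frame: `metric`,
#'   `treated_min/max`, `control_min/max`, `t_stat`, `df`, `pearson_r`,
#'   `p_value`.
#' @export
quality_comparison <- function(table, metric = "iqr_pct", var_equal = FALSE) {
  if (!metric %in% names(table))
    qc_stop("qcmatch_schema_error", "metric not in table: ", metric)
  x <- table[[metric]][is_treated(table)]
  y <- table[[metric]][!is_treated(table)]
  tt <- welch_ttest(x, y, var_equal = var_equal)
  structure(data.frame(metric = metric,
                       treated_min = min(x), treated_max = max(x),
                       control_min = min(y), control_max = max(y),
                       t_stat = tt$t, df = tt$df,
                       pearson_r = pearson_r_from_t(tt$t, tt$df),
                       p_value = tt$p, stringsAsFactors = FALSE),
            class = c("quality_comparison", "data.frame"))
}
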