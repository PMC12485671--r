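# Propensity-score estimation: logistic regression of treated-group
# membership on quality covariates.

#' Fit a logistic propensity model
#'
#' Maximum-likelihood logistic regression of the treated indicator (treated
#' coded 1, control 0) on numeric covariates, fitted by iteratively
#' reweighted least squares. Covariates are standardized internally for
#' numerical stability; reported coefficients are on the original scale.
#' Zero-variance covariates are dropped (with a message in the model);
#' genuinely collinear covariates raise a rank error, and complete or
#' quasi-complete separation raises a separation error suggesting caliper /
#' exact options.
#'
#' @param table a [cohort_table()].
#' @param covariates character vector of numeric covariate columns; default
#'   the three quality metrics used for matching (image quality rating,
#'   Euler number, defect size).
#' @param max_iter,tol IRLS iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param ridge optional ridge penalty (on the standardized scale) for
#'   separation rescue; 0 (pure MLE) by default.
#' @return a `propensity_model` with elements `coefficients` (named,
#'   original scale, intercept first), `covariate_names`, `standardization`
#'   (per-covariate mean/sd), `converged`, `n_iterations`, `log_likelihood`,
#'   `dropped` (zero-variance covariates).
#' @export
fit_propensity <- function(table, covariates = c("iqr_pct", "euler", "defect_pct"),
                           max_iter = 100L, tol = 1e-10, ridge = 0) {
  if (!inherits(table, "cohort_table"))
    qc_stop("qcmatch_validation_error", "table must be a cohort_table")
  missing_cov <- setdiff(covariates, names(table))
  if (length(missing_cov))
    qc_stop("qcmatch_schema_error", "covariate(s) not in table: ",
            paste(missing_cov, collapse = ", "))
  y <- as.numeric(is_treated(table))
  if (sum(y) == 0 || sum(y) == length(y))
    qc_stop("qcmatch_validation_error", "both groups must be nonempty")
  X <- as.matrix(table[, covariates, drop = FALSE])
  if (!is.numeric(X) || anyNA(X))
    qc_stop("qcmatch_validation_error", "covariates must be numeric and complete")

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  dropped <- covariates[!keep]
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  if (ncol(Xs) > 0 && qr(cbind(1, Xs))$rank < ncol(Xs) + 1L)
    qc_stop("qcmatch_rank_error", "covariates are collinear (rank-deficient design)")

  D <- cbind(`(Intercept)` = 1, Xs)
  fit <- suppressWarnings(stats::glm.fit(
    D, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = tol, maxit = max_iter)))
  beta_std <- fit$coefficients
  if (ridge > 0) {
    # one-step ridge refit on the standardized scale (separation rescue)
    beta_std <- ridge_logistic(D, y, ridge, max_iter, tol)
    fit$converged <- TRUE
  }
  eta <- drop(D %*% beta_std)
  p <- stats::plogis(eta)
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  sep <- max(abs(beta_std[-1]), 0) > 1e3 ||
    (length(beta_std) > 1 && ridge == 0 &&
     min(p[y == 1]) > max(p[y == 0]) &&
     (min(p[y == 1]) > 1 - 1e-6 || !fit$converged))
  if (sep && ridge == 0)
    qc_stop("qcmatch_separation_error",
            "complete or quasi-complete separation detected; consider a ",
            "caliper, exact matching on the separating variable, or ridge > 0")

  kept <- covariates[keep]
  slopes <- if (length(kept)) beta_std[-1] / sdv[keep] else numeric(0)
  intercept <- beta_std[1] -
    if (length(kept)) sum(beta_std[-1] * mu[keep] / sdv[keep]) else 0
  coefficients <- c(`(Intercept)` = unname(intercept),
                    stats::setNames(unname(slopes), kept))
  structure(list(coefficients = coefficients, covariate_names = kept,
                 standardization = list(mean = mu[keep], sd = sdv[keep]),
                 converged = fit$converged, n_iterations = fit$iter,
                 log_likelihood = ll, dropped = dropped,
                 treated_label = treated_label(table)),
            class = "propensity_model")
}

# Newton iterations for the ridge-penalized logistic log-likelihood.
ridge_logistic <- function(D, y, lambda, max_iter, tol) {
  beta <- rep(0, ncol(D))
  pen <- diag(c(0, rep(lambda, ncol(D) - 1L)), ncol(D))
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(D %*% beta))
    g <- crossprod(D, y - p) - pen %*% beta
    H <- crossprod(D, D * (p * (1 - p))) + pen
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  stats::setNames(beta, colnames(D))
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("propensity_model (logistic):", length(x$covariate_names),
      "covariate(s);", if (x$converged) "converged" else "NOT converged",
      "in", x$n_iterations, "iterations; logLik", format(x$log_likelihood), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Compute propensity scores from a fitted model
#'
#' The linear predictor is `eta = X beta`; the probability of treated-group
#' membership is `plogis(eta)`. Row order matches the input cohort.
#'
#' @param model a `propensity_model`.
#' @param table a [cohort_table()] containing the model's covariates.
#' @return a `propensity_scores` data frame with columns `subject_id`,
#'   `probability`, `linear_predictor`, plus a `group` attribute aligned to
#'   the rows.
#' @export
compute_scores <- function(model, table) {
  missing_cov <- setdiff(model$covariate_names, names(table))
  if (length(missing_cov))
    qc_stop("qcmatch_schema_error", "table lacks model covariate(s): ",
            paste(missing_cov, collapse = ", "))
  X <- cbind(1, as.matrix(table[, model$covariate_names, drop = FALSE]))
  eta <- drop(X %*% model$coefficients)
  structure(data.frame(subject_id = table$subject_id,
                       probability = stats::plogis(eta),
                       linear_predictor = eta,
                       stringsAsFactors = FALSE),
            group = table$group, treated_label = treated_label(table),
            class = c("propensity_scores", "data.frame"))
}

#' @export
print.propensity_scores <- function(x, ...) {
  cat("propensity_scores for", nrow(x), "subjects; probability range [",
      format(min(x$probability), digits = 4), ",",
      format(max(x$probability), digits = 4), "]\n")
  invisible(x)
}

#' Write propensity scores to TSV
#'
#' @param scores a `propensity_scores`.
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  df <- as.data.frame(scores)
  df$probability <- sprintf("%.17g", df$probability)
  df$linear_predictor <- sprintf("%.17g", df$linear_predictor)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
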