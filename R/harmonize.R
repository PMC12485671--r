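# Site harmonization: empirical-Bayes location/scale batch model on the
# subjects x voxels matrix, protecting group/age/sex (or any supplied
# design) so biological variability is preserved while additive and
# multiplicative site effects are removed.

#' Fit the location/scale site-harmonization model
#'
#' The model for subject i at feature v in site s is
#' `y_iv = alpha_v + x_i' beta_v + gamma_sv + delta_sv * eps_iv`.
#' Fitting proceeds in three steps: (1) feature-wise least squares of the
#' full design (site indicators plus protected covariates), yielding the
#' site-size-weighted grand mean, covariate effects and pooled residual
#' variance; (2) per-site location (`gamma_hat`) and scale (`delta2_hat`)
#' estimates on the standardized residuals; (3) with `eb = TRUE`, parametric
#' empirical-Bayes shrinkage — a normal prior on locations and an
#' inverse-gamma prior on squared scales, hyperparameters by method of
#' moments, with the coupled `(gamma*, delta*)` solution iterated to
#' relative tolerance 1e-6. With `eb = FALSE` the raw per-site estimates
#' are used, which exactly equalizes covariate-adjusted site means.
#'
#' Zero-variance features are passed through untouched and listed in the
#' model's `constant_features`. A single-site dataset yields a no-op model.
#'
#' @param dataset a `voxel_dataset` (or any subjects x features matrix
#'   wrapped by it).
#' @param site_labels character/factor vector, one per subject; every site
#'   needs at least 2 subjects.
#' @param covariate_matrix numeric matrix (subjects x q) of covariates to
#'   protect (no intercept column; e.g. group indicator, age, sex dummy).
#'   `NULL` for none.
#' @param eb empirical-Bayes shrinkage on/off.
#' @return a `harmonization_model`.
#' @export
fit_combat <- function(dataset, site_labels, covariate_matrix = NULL,
                       eb = TRUE) {
  Y <- dataset$data
  n <- nrow(Y)
  if (length(site_labels) != n)
    qc_stop("qcmatch_validation_error", "site_labels must have one entry per subject")
  site <- factor(site_labels)
  S <- nlevels(site)
  ns <- as.integer(table(site))
  if (S > 1 && any(ns < 2))
    qc_stop("qcmatch_site_size_error", "every site needs >= 2 subjects")
  feat_sd <- apply(Y, 2, stats::sd)
  constant_features <- which(feat_sd == 0)
  if (S == 1L) {
    return(structure(list(noop = TRUE, sites = levels(site), eb = eb,
                          parametric = TRUE, subject_ids = dataset$subject_ids,
                          constant_features = constant_features),
                     class = "harmonization_model"))
  }
  active <- setdiff(seq_len(ncol(Y)), constant_features)
  Ya <- Y[, active, drop = FALSE]

  Dsite <- stats::model.matrix(~ site - 1)
  X <- if (is.null(covariate_matrix)) NULL else as.matrix(covariate_matrix)
  D <- cbind(Dsite, X)
  if (qr(D)$rank < ncol(D))
    qc_stop("qcmatch_design_error",
            "design (site indicators + covariates) is rank deficient")
  B <- solve(crossprod(D), crossprod(D, Ya))            # (S+q) x V
  grand_mean <- drop((ns / n) %*% B[seq_len(S), , drop = FALSE])
  covar_fit <- if (is.null(X)) matrix(0, n, length(active)) else
    X %*% B[-seq_len(S), , drop = FALSE]
  var_pooled <- colMeans((Ya - D %*% B)^2)              # MLE over subjects
  if (any(var_pooled <= 0))
    qc_stop("qcmatch_design_error", "zero pooled residual variance at some feature")
  stand_mean <- matrix(grand_mean, n, length(active), byrow = TRUE) + covar_fit
  Z <- (Ya - stand_mean) / matrix(sqrt(var_pooled), n, length(active), byrow = TRUE)

  gamma_hat <- rowsum(Z, site) / ns                     # S x V
  # per-site scale with the MLE (1/n_s) denominator, the same convention as
  # the pooled variance, so the eb=off adjustment is a fixed point
  delta2_hat <- rowsum(Z^2, site) / ns - gamma_hat^2

  if (eb) {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    hyper <- vector("list", S)
    for (s in seq_len(S)) {
      g <- gamma_hat[s, ]; d2 <- delta2_hat[s, ]
      gbar <- mean(g); tau2 <- stats::var(g)
      m <- mean(d2); s2 <- stats::var(d2)
      if (tau2 <= 0 || s2 <= 0) {
        # degenerate prior (e.g. a single feature): fall back to raw estimates
        hyper[[s]] <- list(gamma_bar = gbar, tau2 = tau2, lambda = NA, theta = NA)
        next
      }
      lambda <- (2 * s2 + m^2) / s2                     # inverse-gamma shape
      theta <- (m * s2 + m^3) / s2                      # inverse-gamma scale
      hyper[[s]] <- list(gamma_bar = gbar, tau2 = tau2,
                         lambda = lambda, theta = theta)
      zs <- Z[site == levels(site)[s], , drop = FALSE]
      gs <- g; ds <- d2
      repeat {
        g_new <- (ns[s] * tau2 * g + ds * gbar) / (ns[s] * tau2 + ds)
        ss <- colSums(sweep(zs, 2, g_new)^2)
        d_new <- (theta + 0.5 * ss) / (ns[s] / 2 + lambda - 1)
        change <- max(abs(g_new - gs) / pmax(abs(gs), 1e-12),
                      abs(d_new - ds) / pmax(abs(ds), 1e-12))
        gs <- g_new; ds <- d_new
        if (change < 1e-6) break
      }
      gamma_star[s, ] <- gs
      delta2_star[s, ] <- ds
    }
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    hyper <- NULL
  }
  if (any(delta2_star <= 0))
    qc_stop("qcmatch_design_error", "nonpositive shrunk scale estimate")

  structure(list(noop = FALSE, sites = levels(site), site = site,
                 n_per_site = ns, active = active,
                 constant_features = constant_features,
                 grand_mean = grand_mean, covar_fit = covar_fit,
                 var_pooled = var_pooled,
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 gamma_star = gamma_star, delta2_star = delta2_star,
                 hyper = hyper, eb = eb, parametric = TRUE,
                 subject_ids = dataset$subject_ids),
            class = "harmonization_model")
}

#' @export
print.harmonization_model <- function(x, ...) {
  if (isTRUE(x$noop)) {
    cat("harmonization_model: single site, no-op\n")
  } else {
    cat("harmonization_model:", length(x$sites), "sites,",
        length(x$active), "active features,",
        if (x$eb) "EB shrinkage on" else "EB off", "\n")
  }
  invisible(x)
}

#' Apply a fitted harmonization model
#'
#' Standardized residuals are de-sited, `(z - gamma*_s) / delta*_s`, then
#' the covariate effects and grand mean are restored on the original scale.
#' Constant features and single-site fits pass through unchanged.
#'
#' @param model a `harmonization_model` from [fit_combat()].
#' @param dataset the `voxel_dataset` seen at fit time (same subjects, same
#'   order).
#' @return a harmonized `voxel_dataset` of identical shape.
#' @export
apply_combat <- function(model, dataset) {
  if (!identical(model$subject_ids, dataset$subject_ids))
    qc_stop("qcmatch_validation_error",
            "dataset subjects differ from those seen at fit time")
  if (isTRUE(model$noop)) return(dataset)
  Y <- dataset$data
  n <- nrow(Y)
  V <- length(model$active)
  stand_mean <- matrix(model$grand_mean, n, V, byrow = TRUE) + model$covar_fit
  sdm <- matrix(sqrt(model$var_pooled), n, V, byrow = TRUE)
  Z <- (Y[, model$active, drop = FALSE] - stand_mean) / sdm
  si <- as.integer(model$site)
  Zadj <- (Z - model$gamma_star[si, , drop = FALSE]) /
    sqrt(model$delta2_star)[si, , drop = FALSE]
  out <- Y
  out[, model$active] <- Zadj * sdm + stand_mean
  new_voxel_dataset(out, dataset$mask, dataset$subject_ids,
                    dataset$voxel_index)
}

#' One-call harmonization
#'
#' [fit_combat()] followed by [apply_combat()].
#'
#' @inheritParams fit_combat
#' @return list with `dataset` (harmonized) and `model`.
#' @export
combat_harmonize <- function(dataset, site_labels, covariate_matrix = NULL,
                             eb = TRUE) {
  model <- fit_combat(dataset, site_labels, covariate_matrix, eb = eb)
  list(dataset = apply_combat(model, dataset), model = model)
}

#' Serialize a harmonization model to JSON
#'
#' @param model a `harmonization_model`.
#' @param path output path.
#' @export
write_harmonization_model <- function(model, path) {
  x <- unclass(model)
  x$site <- as.character(x$site)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}
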