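# Independent oracles used to validate the package's own implementations.
# These deliberately take different algorithmic routes from the code under
# test.

# Newton maximization of the logistic log-likelihood using only the scalar
# log-likelihood and finite differences (numeric gradient and Hessian).
oracle_logistic_newton <- function(X, y, max_iter = 200, tol = 1e-10) {
  D <- cbind(1, as.matrix(X))
  p <- ncol(D)
  ll <- function(b) {
    eta <- drop(D %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  num_grad <- function(b, h = 1e-6) {
    vapply(seq_len(p), function(j) {
      e <- rep(0, p); e[j] <- h
      (ll(b + e) - ll(b - e)) / (2 * h)
    }, 0)
  }
  num_hess <- function(b, h = 1e-4) {
    H <- matrix(0, p, p)
    for (j in seq_len(p)) {
      e <- rep(0, p); e[j] <- h
      H[, j] <- (num_grad(b + e) - num_grad(b - e)) / (2 * h)
    }
    (H + t(H)) / 2
  }
  b <- rep(0, p)
  for (it in seq_len(max_iter)) {
    step <- solve(num_hess(b), num_grad(b))
    b <- b - drop(step)
    if (max(abs(step)) < tol) break
  }
  b
}

# Exact minimum-cost injective assignment of rows to columns by dynamic
# programming over column subsets (bitmask); independent of the Hungarian
# solver. Returns the minimum total cost.
oracle_assignment_dp <- function(cost) {
  nt <- nrow(cost); nc <- ncol(cost)
  stopifnot(nt <= nc, nc <= 20)
  nstates <- bitwShiftL(1L, nc)
  f <- rep(Inf, nstates)
  f[1] <- 0
  for (i in seq_len(nt)) {
    g <- rep(Inf, nstates)
    for (j in seq_len(nc)) {
      bit <- bitwShiftL(1L, j - 1L)
      has <- bitwAnd(seq_len(nstates) - 1L, bit) > 0L
      src <- which(has) - bit        # states without j, 1-based index shift
      cand <- f[src] + cost[i, j]
      tgt <- which(has)
      g[tgt] <- pmin(g[tgt], cand)
    }
    f <- g
  }
  min(f)
}

# Per-voxel OLS t statistics through lm(); independent of the vectorized
# normal-equations implementation.
oracle_glm_t <- function(Y, X, contrast) {
  vapply(seq_len(ncol(Y)), function(v) {
    fit <- stats::lm(Y[, v] ~ X - 1)
    b <- stats::coef(fit)
    V <- stats::vcov(fit)
    drop(contrast %*% b) / sqrt(drop(t(contrast) %*% V %*% contrast))
  }, 0)
}

# Build a propensity_scores object directly (for matching tests with
# hand-picked logits).
make_scores <- function(logits, groups, treated = "t",
                        ids = sprintf("s%02d", seq_along(logits))) {
  structure(data.frame(subject_id = ids,
                       probability = stats::plogis(logits),
                       linear_predictor = logits,
                       stringsAsFactors = FALSE),
            group = groups, treated_label = treated,
            class = c("propensity_scores", "data.frame"))
}

# Minimal hand-built cohort table.
make_toy_cohort <- function(n_t = 5, n_c = 5, seed = 1, site = "site1",
                            iqr = NULL, euler = NULL, defect = NULL) {
  set.seed(seed)
  n <- n_t + n_c
  df <- data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = rep(c("pat", "con"), c(n_t, n_c)),
    site = site,
    age = runif(n, 20, 60),
    sex = sample(c("M", "F"), n, replace = TRUE),
    tiv = runif(n, 1300, 1700),
    iqr_pct = iqr %||% runif(n, 60, 90),
    euler = euler %||% runif(n, 10, 120),
    defect_pct = defect %||% runif(n, 1, 8),
    stringsAsFactors = FALSE)
  cohort_table(df, treated_label = "pat", control_label = "con")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Construct a tstat_map by hand (for cluster-rule tests).
make_tmap <- function(dims, voxel_size, t_by_voxel, p_fwe_by_voxel,
                      df = 30, n1 = 16, n2 = 16) {
  aff <- diag(c(rep(voxel_size, 3), 1))
  mask <- array(0, dims)
  mask[as.integer(names(t_by_voxel))] <- 1
  idx <- sort(as.integer(names(t_by_voxel)))
  design <- cbind(1, rep(c(1, 0), c(n1, n2)))
  colnames(design) <- c("intercept", "group")
  structure(list(t = unname(t_by_voxel[as.character(idx)]),
                 df = df,
                 p_uncorr = rep(0.001, length(idx)),
                 voxel_index = idx,
                 mask = volume_image(mask, aff),
                 affine = aff,
                 p_fwe = unname(p_fwe_by_voxel[as.character(idx)]),
                 design = design, contrast = c(0, 1)),
            class = "tstat_map")
}
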