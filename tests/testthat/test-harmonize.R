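# Hand-built multi-site voxel datasets with known location/scale effects.
make_site_dataset <- function(n_per_site = c(100, 100), V = 50, seed = 1,
                              gamma = c(2, -2), delta = c(1, 2),
                              beta_group = 0.8, with_group = TRUE) {
  set.seed(seed)
  n <- sum(n_per_site)
  site <- rep(paste0("site", seq_along(n_per_site)), n_per_site)
  group <- rbinom(n, 1, 0.5)
  base <- matrix(rnorm(V, 10, 2), n, V, byrow = TRUE)
  Y <- base + (if (with_group) group %o% rep(beta_group, V) else 0) +
    gamma[as.integer(factor(site))] +
    matrix(rnorm(n * V), n, V) * delta[as.integer(factor(site))]
  mask <- volume_image(array(1, c(V, 1, 1)), diag(4))
  ds <- structure(list(data = Y, mask = mask, affine = diag(4),
                       subject_ids = sprintf("s%03d", seq_len(n)),
                       voxel_index = seq_len(V)),
                  class = "voxel_dataset")
  list(ds = ds, site = site, group = group)
}

test_that("single-site harmonization is an exact no-op", {
  d <- make_site_dataset(n_per_site = 40, gamma = 0, delta = 1)
  h <- combat_harmonize(d$ds, d$site, cbind(group = d$group))
  expect_lt(max(abs(h$dataset$data - d$ds$data)), 1e-10)
  expect_true(h$model$noop)
})

test_that("without shrinkage, covariate-adjusted site means are exactly equalized", {
  d <- make_site_dataset(seed = 2, gamma = c(2, -2), delta = c(1, 1),
                         with_group = FALSE)
  h <- combat_harmonize(d$ds, d$site, NULL, eb = FALSE)
  m1 <- colMeans(h$dataset$data[d$site == "site1", ])
  m2 <- colMeans(h$dataset$data[d$site == "site2", ])
  expect_lt(max(abs(m1 - m2)), 1e-8)
  grand <- colMeans(d$ds$data)
  # equalized means sit at the site-size-weighted grand mean
  expect_lt(max(abs(m1 - grand)), 0.5)
})

test_that("multiplicative site effects are removed (variance equalization)", {
  d <- make_site_dataset(seed = 3, gamma = c(1, -1), delta = c(1, 2))
  h <- combat_harmonize(d$ds, d$site, cbind(group = d$group), eb = FALSE)
  resid <- h$dataset$data - colMeans(h$dataset$data)[col(h$dataset$data)] -
    0.8 * d$group  # remove the protected group effect approximately
  v1 <- mean(apply(resid[d$site == "site1", ], 2, var))
  v2 <- mean(apply(resid[d$site == "site2", ], 2, var))
  expect_lt(abs(v1 - v2) / v1, 0.05)
})

test_that("EB estimates shrink toward the across-feature prior mean", {
  d <- make_site_dataset(seed = 4, gamma = c(1.5, -1.5), delta = c(1, 1.6))
  raw <- fit_combat(d$ds, d$site, cbind(group = d$group), eb = FALSE)
  ebm <- fit_combat(d$ds, d$site, cbind(group = d$group), eb = TRUE)
  for (s in 1:2) {
    gbar <- mean(raw$gamma_hat[s, ])
    # shrunk gammas lie between the raw estimate and the prior mean
    between <- (ebm$gamma_star[s, ] - raw$gamma_hat[s, ]) *
               (ebm$gamma_star[s, ] - gbar) <= 1e-12
    expect_gte(mean(between), 0.99)
  }
})

test_that("group effects in the protected design are preserved", {
  d <- make_site_dataset(seed = 5, gamma = c(2, -2), delta = c(1, 1.5),
                         beta_group = 0.8)
  h <- combat_harmonize(d$ds, d$site, cbind(group = d$group), eb = FALSE)
  # feature-wise group-effect estimate after harmonization
  bhat <- vapply(seq_len(ncol(h$dataset$data)), function(v)
    coef(lm(h$dataset$data[, v] ~ d$group))[2], 0)
  expect_equal(mean(bhat), 0.8, tolerance = 0.05 * 0.8 + 0.05)
})

test_that("harmonization is idempotent without shrinkage", {
  # pure location/scale model: exact fixed point
  d <- make_site_dataset(seed = 6, with_group = FALSE)
  h1 <- combat_harmonize(d$ds, d$site, NULL, eb = FALSE)
  h2 <- combat_harmonize(h1$dataset, d$site, NULL, eb = FALSE)
  rel <- norm(h2$dataset$data - h1$dataset$data, "F") /
    norm(h1$dataset$data, "F")
  expect_lt(rel, 1e-6)
  # with protected covariates the refit perturbs coefficients only at the
  # sampling-noise level
  dg <- make_site_dataset(seed = 6)
  g1 <- combat_harmonize(dg$ds, dg$site, cbind(group = dg$group), eb = FALSE)
  g2 <- combat_harmonize(g1$dataset, dg$site, cbind(group = dg$group), eb = FALSE)
  relg <- norm(g2$dataset$data - g1$dataset$data, "F") /
    norm(g1$dataset$data, "F")
  expect_lt(relg, 1e-3)
})

test_that("errors: tiny sites, rank deficiency, subject mismatch", {
  d <- make_site_dataset(n_per_site = c(1, 30), seed = 7)
  expect_error(fit_combat(d$ds, d$site, NULL),
               class = "qcmatch_site_size_error")
  d2 <- make_site_dataset(seed = 8)
  bad_cov <- cbind(site_copy = as.numeric(factor(d2$site)))
  expect_error(fit_combat(d2$ds, d2$site, bad_cov),
               class = "qcmatch_design_error")
  m <- fit_combat(d2$ds, d2$site, cbind(group = d2$group))
  ds_swapped <- d2$ds
  ds_swapped$subject_ids <- rev(ds_swapped$subject_ids)
  expect_error(apply_combat(m, ds_swapped), class = "qcmatch_validation_error")
})

test_that("agrees with the reference EB ComBat implementation", {
  skip_if_not_installed("sva")
  d <- make_site_dataset(n_per_site = c(40, 60), V = 30, seed = 9,
                         gamma = c(1, -1), delta = c(1, 1.5))
  h <- combat_harmonize(d$ds, d$site, cbind(group = d$group), eb = TRUE)
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(d$ds$data), batch = d$site,
                mod = stats::model.matrix(~ d$group))))
  # conventions differ slightly (scale denominator, EB stopping rule), so
  # agreement is to a small fraction of the data SD, not exact
  expect_lt(max(abs(h$dataset$data - ref)) / sd(d$ds$data), 0.02)
  expect_gt(cor(as.vector(h$dataset$data), as.vector(ref)), 0.9999)
})
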