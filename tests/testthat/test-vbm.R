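# Helpers building small voxel datasets directly.
flat_dataset <- function(Y, dims = NULL, voxel_size = 3) {
  V <- ncol(Y)
  dims <- dims %||% c(V, 1, 1)
  aff <- diag(c(rep(voxel_size, 3), 1))
  mask <- volume_image(array(1, dims), aff)
  structure(list(data = Y, mask = mask, affine = aff,
                 subject_ids = sprintf("s%03d", seq_len(nrow(Y))),
                 voxel_index = seq_len(prod(dims))),
            class = "voxel_dataset")
}

test_that("FWHM-to-sigma conversion and constant invariance", {
  expect_equal(fwhm_to_sigma(8), 3.3972, tolerance = 1e-4)
  expect_equal(fwhm_to_sigma(8), 8 / (2 * sqrt(2 * log(2))), tolerance = 1e-12)
  dims <- c(10, 10, 10)
  aff <- diag(c(2, 2, 2, 1))
  mask <- array(0, dims); mask[3:8, 3:8, 3:8] <- 1
  maskv <- volume_image(mask, aff)
  vol <- volume_image(array(5, dims), aff)
  sm <- smooth_volume(vol, fwhm_mm = 8, mask = maskv)
  expect_lt(max(abs(sm$grid[mask == 1] - 5)), 1e-12)
  expect_true(all(sm$grid[mask == 0] == 0))
})

test_that("impulse response has the requested FWHM", {
  dims <- c(41, 41, 41)
  aff <- diag(4)  # 1 mm voxels
  mask <- volume_image(array(1, dims), aff)
  imp <- array(0, dims); imp[21, 21, 21] <- 1
  sm <- smooth_volume(volume_image(imp, aff), fwhm_mm = 8, mask = mask)
  prof <- sm$grid[, 21, 21]
  half <- max(prof) / 2
  # linear interpolation of the half-max crossings
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  xl <- (lo - 1) + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1]) - 1
  xr <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1]) - 1
  fwhm_measured <- xr - xl
  expect_lt(abs(fwhm_measured - 8) / 8, 0.02)
})

test_that("smoothing requires axis-aligned geometry and positive FWHM", {
  aff <- diag(4); aff[1, 2] <- 0.5
  vol <- volume_image(array(1, c(4, 4, 4)), aff)
  mask <- volume_image(array(1, c(4, 4, 4)), aff)
  expect_error(smooth_volume(vol, 8, mask), class = "qcmatch_geometry_error")
  vol2 <- volume_image(array(1, c(4, 4, 4)))
  expect_error(smooth_volume(vol2, -1, volume_image(array(1, c(4, 4, 4)))),
               class = "qcmatch_config_error")
})

test_that("per-voxel GLM matches closed forms and the lm oracle", {
  set.seed(101)
  n <- 12
  grp <- rep(c(1, 0), each = n / 2)
  X <- cbind(intercept = 1, group = grp, age = rnorm(n))
  contrast <- c(0, 1, 0)
  # noiseless y = 2*group + 1: exact coefficient, infinite-t sentinel
  Y0 <- matrix(2 * grp + 1, n, 3)
  ds0 <- flat_dataset(Y0)
  map0 <- fit_glm(ds0, X, contrast)
  expect_equal(map0$beta_contrast, rep(2, 3), tolerance = 1e-10)
  expect_true(all(is.infinite(map0$t)))
  expect_equal(map0$n_zero_residual, 3)
  expect_equal(map0$p_uncorr, rep(0, 3))
  # random data: agree with the lm oracle
  Y <- matrix(rnorm(n * 20), n, 20)
  map <- fit_glm(flat_dataset(Y), X, contrast)
  expect_equal(map$t, oracle_glm_t(Y, X, contrast), tolerance = 1e-10)
  expect_equal(map$df, n - 3)
  # permuting subjects consistently leaves the t map unchanged
  pi <- sample(n)
  map_p <- fit_glm(flat_dataset(Y[pi, ]), X[pi, ], contrast)
  expect_equal(map_p$t, map$t, tolerance = 1e-10)
  # design errors
  Xr <- cbind(X, X[, 2])
  expect_error(fit_glm(flat_dataset(Y), Xr, c(0, 1, 0, 0)),
               class = "qcmatch_design_error")
  expect_error(fit_glm(flat_dataset(Y[c(1, 2, 7), ]), X[c(1, 2, 7), ], contrast),
               class = "qcmatch_df_error")
})

test_that("glm_design builds intercept+group+nuisance and drops constants", {
  co <- make_toy_cohort(5, 5, seed = 103)
  d <- glm_design(co)
  expect_equal(d$columns, c("intercept", "group", "tiv", "age", "sex_m"))
  expect_equal(sum(d$X[, "group"]), 5)
  expect_equal(d$contrast, c(0, 1, 0, 0, 0))
  co$sex <- "M"  # constant dummy dropped
  d2 <- glm_design(co)
  expect_false("sex_m" %in% d2$columns)
})

test_that("permutation FWE p-values obey estimator bounds and ordering", {
  set.seed(105)
  n <- 16
  grp <- rep(c(1, 0), each = 8)
  X <- cbind(1, grp, rnorm(n))
  Y <- matrix(rnorm(n * 30), n, 30)
  Y[, 1] <- Y[, 1] + 3 * grp  # one strong voxel
  map <- permutation_fwe(flat_dataset(Y), X, c(0, 1, 0), n_perm = 99, seed = 2)
  expect_gte(min(map$p_fwe), 1 / 100)
  expect_true(all(map$p_fwe >= map$p_uncorr - 1e-12))
  expect_length(map$maxT_null, 99)
  # determinism
  map2 <- permutation_fwe(flat_dataset(Y), X, c(0, 1, 0), n_perm = 99, seed = 2)
  expect_identical(map$p_fwe, map2$p_fwe)
  # tiny n: exhaustive enumeration with warning
  Ys <- matrix(rnorm(4 * 5), 4, 5)
  Xs <- cbind(1, c(1, 1, 0, 0))
  expect_warning(
    maps <- permutation_fwe(flat_dataset(Ys), Xs, c(0, 1), n_perm = 500, seed = 1),
    "exhaustively")
  expect_length(maps$maxT_null, 24)
})

test_that("Freedman-Lane permutation respects nuisance structure", {
  # strong nuisance effect, no group effect: FWE p should not be inflated
  set.seed(106)
  n <- 20
  grp <- rep(c(1, 0), each = 10)
  age <- rnorm(n)
  X <- cbind(1, grp, age)
  Y <- matrix(rnorm(n * 25), n, 25) + 5 * age %o% rep(1, 25)
  map <- permutation_fwe(flat_dataset(Y), X, c(0, 1, 0), n_perm = 199, seed = 3)
  expect_gt(min(map$p_fwe), 0.01)
})

test_that("Cohen's d conversion", {
  expect_equal(cohens_d_from_t(0, 10, 10), 0)
  expect_equal(cohens_d_from_t(2, 8, 8), 1)
  expect_equal(cohens_d_from_t(6, 8, 8), 3 * cohens_d_from_t(2, 8, 8))
  expect_error(cohens_d_from_t(1, 0, 5), class = "qcmatch_validation_error")
})

test_that("cluster extraction honours extent threshold and connectivity", {
  dims <- c(12, 12, 12)
  lin <- function(i, j, k) i + 1 + j * 12 + k * 144  # 0-based ijk
  blob1 <- c(lin(1, 1, 1), lin(2, 1, 1), lin(3, 1, 1), lin(1, 2, 1),
             lin(2, 2, 1), lin(3, 2, 1), lin(1, 1, 2), lin(2, 1, 2),
             lin(3, 1, 2), lin(2, 2, 2))            # size 10
  blob2 <- c(lin(8, 8, 8), lin(9, 8, 8), lin(8, 9, 8)) # size 3
  tv <- setNames(rep(6, 13), c(blob1, blob2))
  pv <- setNames(rep(0.01, 13), c(blob1, blob2))
  map <- make_tmap(dims, 3, tv, pv)
  ct <- extract_clusters(map, alpha = 0.05, extent_k = 5)
  expect_equal(length(unique(ct$cluster)), 1)
  expect_equal(unique(ct$size_voxels), 10)
  # with k = 1 both clusters appear
  ct1 <- extract_clusters(map, alpha = 0.05, extent_k = 1)
  expect_equal(length(unique(ct1$cluster)), 2)
  # diagonal neighbours merge under 26- but not 6-connectivity
  diagpair <- c(lin(5, 5, 5), lin(6, 6, 6))
  tv2 <- setNames(rep(6, 2), diagpair)
  pv2 <- setNames(rep(0.01, 2), diagpair)
  map2 <- make_tmap(dims, 3, tv2, pv2)
  expect_equal(length(unique(extract_clusters(map2, extent_k = 1)$cluster)), 1)
  expect_equal(length(unique(extract_clusters(map2, extent_k = 1,
                                              connectivity = 6)$cluster)), 2)
  # all-null map -> empty table
  map3 <- make_tmap(dims, 3, setNames(1, lin(5, 5, 5)), setNames(0.9, lin(5, 5, 5)))
  expect_equal(nrow(extract_clusters(map3)), 0)
})

test_that("the 8 mm distinct-peak rule merges close maxima", {
  dims <- c(12, 12, 12)
  lin <- function(i, j, k) i + 1 + j * 12 + k * 144
  # one cluster along x at 3 mm voxels: maxima 2 voxels (6 mm) apart
  idx6 <- c(lin(2, 2, 2), lin(3, 2, 2), lin(4, 2, 2))
  tv6 <- setNames(c(10, 8, 9), idx6)
  pv6 <- setNames(rep(0.01, 3), idx6)
  ct6 <- extract_clusters(make_tmap(dims, 3, tv6, pv6), extent_k = 1,
                          peak_sep_mm = 8)
  expect_equal(nrow(ct6), 1)
  expect_equal(ct6$peak_t, 10)
  # maxima 3 voxels (9 mm) apart: two peaks reported
  idx9 <- c(lin(2, 2, 2), lin(3, 2, 2), lin(4, 2, 2), lin(5, 2, 2))
  tv9 <- setNames(c(10, 8, 8, 9), idx9)
  pv9 <- setNames(rep(0.01, 4), idx9)
  ct9 <- extract_clusters(make_tmap(dims, 3, tv9, pv9), extent_k = 1,
                          peak_sep_mm = 8)
  expect_equal(nrow(ct9), 2)
  expect_equal(sort(ct9$peak_t), c(9, 10))
  expect_equal(sum(ct9$is_primary_peak), 1)
  # Cohen's d at the peak follows the conversion
  expect_equal(ct9$cohens_d, cohens_d_from_t(ct9$peak_t, 16, 16))
})

test_that("empirical extent threshold bounds the null exceedance rate", {
  # exactly 5% of null maxima reach size 10: k = 1 already suffices
  expect_equal(empirical_extent_threshold(c(rep(0, 95), rep(10, 5)), 0.95), 1)
  # 6% reach size 10: k must exceed every such cluster
  expect_equal(empirical_extent_threshold(c(rep(0, 94), rep(10, 6)), 0.95), 11)
  # all null maxima are 2: k = 3 excludes them all
  expect_equal(empirical_extent_threshold(rep(2, 100), 0.95), 3)
})
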