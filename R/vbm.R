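# Voxel-based morphometry: within-mask Gaussian smoothing, per-voxel
# general linear models, permutation maxT familywise-error correction
# (Freedman-Lane residual permutation under nuisance covariates) and
# cluster extraction with the 8 mm distinct-peak rule.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Convert a Gaussian FWHM to its standard deviation
#'
#' `sigma = fwhm / (2 * sqrt(2 * ln 2))`; 8 mm FWHM gives sigma 3.3972 mm.
#'
#' @param fwhm full width at half maximum (any unit).
#' @return sigma in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm * FWHM_TO_SIGMA

# Voxel sizes (mm) along the three axes; errors on sheared/oblique affines.
axis_voxel_sizes <- function(affine) {
  R <- affine[1:3, 1:3]
  sizes <- sqrt(colSums(R^2))
  if (max(abs(R - diag(sign(diag(R)) * sizes, 3))) > 1e-6 * max(sizes))
    qc_stop("qcmatch_geometry_error",
            "smoothing requires an axis-aligned affine")
  sizes
}

#' Within-mask Gaussian smoothing
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))`
#' per axis, converted from millimetres to voxels via the affine. The
#' convolution is mask-normalized: the smoothed image is divided by the
#' smoothed mask, so a constant image inside the mask is preserved exactly
#' and no intensity bleeds in from outside the mask.
#'
#' @param x a [volume_image()] or `voxel_dataset` (every subject row is
#'   smoothed).
#' @param fwhm_mm scalar or length-3 FWHM in millimetres (default the
#'   conventional 8 mm isotropic).
#' @param mask a `volume_image` (required for a `volume_image` input; a
#'   `voxel_dataset` uses its own mask).
#' @return the same type as `x`, smoothed within the mask (zero outside).
#' @export
smooth_volume <- function(x, fwhm_mm = 8, mask = NULL) {
  UseMethod("smooth_volume")
}

smooth_kernels <- function(affine, fwhm_mm) {
  fwhm_mm <- rep_len(fwhm_mm, 3)
  if (any(fwhm_mm <= 0)) qc_stop("qcmatch_config_error", "fwhm must be positive")
  sizes <- axis_voxel_sizes(affine)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / sizes
  lapply(sigma_vox, function(s) {
    r <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k / sum(k)
  })
}

smooth_grid_masked <- function(grid, maskgrid, kernels) {
  num <- grid * maskgrid
  den <- maskgrid
  for (ax in 1:3) {
    num <- convolve_axis(num, kernels[[ax]], ax)
    den <- convolve_axis(den, kernels[[ax]], ax)
  }
  out <- array(0, dim = dim(grid))
  inside <- maskgrid != 0
  out[inside] <- num[inside] / den[inside]
  out
}

#' @rdname smooth_volume
#' @export
smooth_volume.volume_image <- function(x, fwhm_mm = 8, mask = NULL) {
  if (is.null(mask)) qc_stop("qcmatch_validation_error", "mask required")
  kernels <- smooth_kernels(x$affine, fwhm_mm)
  volume_image(smooth_grid_masked(x$grid, mask$grid, kernels), x$affine,
               subject_id = x$subject_id)
}

#' @rdname smooth_volume
#' @export
smooth_volume.voxel_dataset <- function(x, fwhm_mm = 8, mask = NULL) {
  kernels <- smooth_kernels(x$affine, fwhm_mm)
  maskgrid <- x$mask$grid
  dims <- dim(maskgrid)
  # precompute the smoothed-mask denominator once
  den <- maskgrid
  for (ax in 1:3) den <- convolve_axis(den, kernels[[ax]], ax)
  den_in <- den[x$voxel_index]
  out <- x$data
  tmp <- array(0, dim = dims)
  for (i in seq_len(nrow(out))) {
    tmp[] <- 0
    tmp[x$voxel_index] <- out[i, ]
    for (ax in 1:3) tmp <- convolve_axis(tmp, kernels[[ax]], ax)
    out[i, ] <- tmp[x$voxel_index] / den_in
  }
  new_voxel_dataset(out, x$mask, x$subject_ids, x$voxel_index)
}

#' Build a GLM design for group comparison
#'
#' Columns: intercept, group indicator (treated = 1), then the requested
#' nuisance covariates (total intracranial volume, age, and sex as an M
#' dummy by default, the conventional VBM nuisance set).
#'
#' @param cohort a [cohort_table()].
#' @param covariates subset of `c("tiv", "age", "sex")` (or any numeric
#'   cohort columns; `"sex"` expands to an indicator of `"M"`).
#' @return a `glm_design`: list with `X` (n x p matrix), `contrast` (picks
#'   the group column), `columns`.
#' @export
glm_design <- function(cohort, covariates = c("tiv", "age", "sex")) {
  n <- nrow(cohort)
  X <- cbind(intercept = rep(1, n), group = as.numeric(is_treated(cohort)))
  for (v in covariates) {
    if (v == "sex") {
      X <- cbind(X, sex_m = as.numeric(cohort$sex == "M"))
    } else {
      if (!v %in% names(cohort) || !is.numeric(cohort[[v]]))
        qc_stop("qcmatch_schema_error", "covariate not numeric/in table: ", v)
      X <- cbind(X, stats::setNames(list(cohort[[v]]), v)[[1]])
      colnames(X)[ncol(X)] <- v
    }
  }
  if (anyNA(X)) qc_stop("qcmatch_validation_error", "design contains NA")
  keep <- c(TRUE, TRUE, apply(X[, -(1:2), drop = FALSE], 2, stats::sd) > 0)
  X <- X[, keep, drop = FALSE]
  if (qr(X)$rank < ncol(X))
    qc_stop("qcmatch_design_error", "design is rank deficient")
  contrast <- as.numeric(colnames(X) == "group")
  structure(list(X = X, contrast = contrast, columns = colnames(X), n = n,
                 rank = ncol(X)),
            class = "glm_design")
}

#' Per-voxel general linear model
#'
#' Ordinary least squares at every in-mask voxel;
#' `t = c beta / sqrt(sigma2 * c (X'X)^-1 c')` with
#' `sigma2 = RSS / (n - rank)` and a two-sided uncorrected p-value. Voxels
#' with (numerically) zero residual get a `+/-Inf` sentinel t and p 0;
#' their count is recorded in `n_zero_residual`.
#'
#' @param dataset a `voxel_dataset` (rows must align with the design).
#' @param design a [glm_design()] or a plain numeric matrix.
#' @param contrast contrast vector (defaults to the design's group
#'   contrast).
#' @return a `tstat_map`: list with `t`, `df`, `p_uncorr`, `beta_contrast`,
#'   `voxel_index`, `mask`, `affine`, `n_groups` (treated/control counts if
#'   known), `p_fwe` (`NULL` until [permutation_fwe()]).
#' @export
fit_glm <- function(dataset, design, contrast = NULL) {
  X <- if (inherits(design, "glm_design")) design$X else as.matrix(design)
  if (is.null(contrast))
    contrast <- if (inherits(design, "glm_design")) design$contrast else
      qc_stop("qcmatch_validation_error", "contrast required for a bare matrix")
  if (length(contrast) != ncol(X))
    qc_stop("qcmatch_validation_error", "contrast length must match design columns")
  n <- nrow(X)
  if (nrow(dataset$data) != n)
    qc_stop("qcmatch_validation_error", "dataset rows must match design rows")
  if (qr(X)$rank < ncol(X)) qc_stop("qcmatch_design_error", "design is rank deficient")
  if (n <= ncol(X)) qc_stop("qcmatch_df_error", "n must exceed design rank")
  st <- glm_tstats(dataset$data, X, contrast)
  structure(list(t = st$t, df = st$df, p_uncorr = st$p,
                 beta_contrast = st$cb, voxel_index = dataset$voxel_index,
                 mask = dataset$mask, affine = dataset$affine,
                 n_zero_residual = st$n_zero, p_fwe = NULL,
                 maxT_null = NULL, design = X, contrast = contrast),
            class = "tstat_map")
}

# Vectorized OLS t statistics for Y (n x V), design X, contrast c.
glm_tstats <- function(Y, X, contrast) {
  n <- nrow(X); p <- ncol(X)
  XtXi <- solve(crossprod(X))
  P <- XtXi %*% t(X)                 # p x n
  B <- P %*% Y                       # p x V
  R <- Y - X %*% B
  df <- n - p
  rss <- colSums(R^2)
  cxxc <- drop(t(contrast) %*% XtXi %*% contrast)
  cb <- drop(crossprod(contrast, B))
  scale_floor <- .Machine$double.eps * colSums(Y^2)
  zero <- rss <= pmax(scale_floor, .Machine$double.eps)
  se <- sqrt(pmax(rss, .Machine$double.eps) / df * cxxc)
  t <- cb / se
  t[zero] <- sign(cb[zero]) * Inf
  pv <- 2 * stats::pt(-abs(t), df)
  pv[zero] <- 0
  list(t = t, df = df, p = pv, cb = cb, n_zero = sum(zero))
}

#' @export
print.tstat_map <- function(x, ...) {
  cat("tstat_map:", length(x$t), "voxels, df", x$df, ", |t| max",
      format(max(abs(x$t)), digits = 4),
      if (!is.null(x$p_fwe)) paste0(", min FWE p ", format(min(x$p_fwe), digits = 4)),
      "\n")
  invisible(x)
}

# All permutations of 1..n (n small), one per row.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Permutation maxT familywise-error correction
#'
#' Freedman-Lane scheme: the nuisance-only model (all design columns with a
#' zero contrast weight) is fitted, its residuals are permuted and added
#' back to the nuisance fit, the full model is refitted, and the maximum
#' `|t|` over the mask is recorded per permutation. The FWE-corrected
#' p-value at voxel v is `(1 + #{maxT >= |t_v|}) / (n_perm + 1)`, so the
#' smallest attainable value is `1 / (n_perm + 1)`. If fewer distinct
#' permutations than `n_perm` exist, they are enumerated exhaustively
#' (with a warning).
#'
#' @inheritParams fit_glm
#' @param n_perm number of random permutations.
#' @param seed RNG seed.
#' @return the [fit_glm()] map with `p_fwe` and `maxT_null` filled in.
#' @export
permutation_fwe <- function(dataset, design, contrast = NULL, n_perm = 1000,
                            seed = 1L) {
  if (n_perm < 1) qc_stop("qcmatch_config_error", "n_perm must be >= 1")
  map <- fit_glm(dataset, design, contrast)
  X <- map$design
  contrast <- map$contrast
  Y <- dataset$data
  n <- nrow(Y)
  nuis <- which(contrast == 0)
  Z <- X[, nuis, drop = FALSE]
  if (ncol(Z)) {
    Pz <- Z %*% solve(crossprod(Z), t(Z))
    fitted_z <- Pz %*% Y
    resid_z <- Y - fitted_z
  } else {
    fitted_z <- matrix(0, n, ncol(Y))
    resid_z <- Y
  }
  XtXi <- solve(crossprod(X))
  P <- XtXi %*% t(X)
  cxxc <- drop(t(contrast) %*% XtXi %*% contrast)
  df <- n - ncol(X)

  exhaustive <- is.finite(factorial(n)) && factorial(n) <= n_perm
  perms <- with_local_seed(seed, {
    if (exhaustive) {
      warning("fewer distinct permutations than n_perm; enumerating all ",
              factorial(n), " exhaustively")
      all_permutations(n)
    } else {
      t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
    }
  })
  maxT <- apply(perms, 1, function(pi) {
    Ystar <- resid_z[pi, , drop = FALSE] + fitted_z
    B <- P %*% Ystar
    R <- Ystar - X %*% B
    rss <- pmax(colSums(R^2), .Machine$double.eps)
    max(abs(drop(crossprod(contrast, B))) / sqrt(rss / df * cxxc))
  })
  map$p_fwe <- vapply(abs(map$t), function(tv) (1 + sum(maxT >= tv)) /
                        (length(maxT) + 1), 0)
  map$maxT_null <- maxT
  map
}

# 0-based neighbour offsets for 6- or 26-connectivity.
connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  else if (connectivity != 26)
    qc_stop("qcmatch_config_error", "connectivity must be 6 or 26")
  g
}

# Label connected components among the given 1-based linear voxel indices.
label_components <- function(voxels, dims, connectivity = 26) {
  if (!length(voxels)) return(integer(0))
  offs <- connectivity_offsets(connectivity)
  ijk <- arrayInd(voxels, dims)
  key <- voxels
  lookup <- new.env(hash = TRUE, size = length(voxels))
  for (i in seq_along(key)) assign(as.character(key[i]), i, envir = lookup)
  labels <- integer(length(voxels))
  comp <- 0L
  for (start in seq_along(voxels)) {
    if (labels[start]) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      nb <- sweep(offs, 2, ijk[cur, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
        (nb[, 3] - 1L) * dims[1] * dims[2]
      for (l in lin) {
        j <- mget(as.character(l), envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && !labels[j]) {
          labels[j] <- comp
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Cohen's d from a two-sample t statistic
#'
#' `d = t * sqrt(1/n1 + 1/n2)`.
#'
#' @param t t statistic.
#' @param n1,n2 group sizes.
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n1, n2) {
  if (n1 < 1 || n2 < 1) qc_stop("qcmatch_validation_error", "group sizes must be >= 1")
  t * sqrt(1 / n1 + 1 / n2)
}

#' Extract suprathreshold clusters and peaks
#'
#' The suprathreshold set is every voxel with FWE-corrected p at or below
#' `alpha`. Connected components (26-connectivity by default) smaller than
#' the extent threshold `k` are dropped. Within each surviving cluster the
#' global `|t|` peak is reported, plus any further local maxima whose world
#' distance from every already-reported peak exceeds `peak_sep_mm`
#' (greedily, in descending `|t|`) — the conventional 8 mm distinct-peak
#' rule. Peak coordinates are world millimetres via the affine; Cohen's d
#' is derived from the peak t.
#'
#' @param map a `tstat_map` with `p_fwe` (from [permutation_fwe()]).
#' @param alpha voxel-level FWE threshold (default 0.05).
#' @param extent_k minimum cluster size in voxels.
#' @param peak_sep_mm minimum world distance between reported peaks.
#' @param connectivity 26 (default) or 6.
#' @param n1,n2 group sizes for Cohen's d (taken from the map's design
#'   group column if omitted).
#' @return a `cluster_table` data frame, one row per reported peak:
#'   `cluster`, `x`, `y`, `z`, `size_voxels`, `peak_t`, `cohens_d`,
#'   `p_uncorr`, `p_fwe`, `is_primary_peak`. Empty (zero rows) when nothing
#'   survives.
#' @export
extract_clusters <- function(map, alpha = 0.05, extent_k = 1,
                             peak_sep_mm = 8, connectivity = 26,
                             n1 = NULL, n2 = NULL) {
  if (is.null(map$p_fwe))
    qc_stop("qcmatch_validation_error", "map has no FWE p-values; run permutation_fwe")
  if (alpha <= 0 || alpha >= 1) qc_stop("qcmatch_config_error", "alpha in (0,1)")
  if (extent_k < 1) qc_stop("qcmatch_config_error", "extent_k >= 1")
  if (peak_sep_mm < 0) qc_stop("qcmatch_config_error", "peak_sep_mm >= 0")
  if (is.null(n1) || is.null(n2)) {
    grp <- map$design[, which(map$contrast != 0)[1]]
    n1 <- sum(grp == max(grp)); n2 <- sum(grp != max(grp))
  }
  dims <- dim(map$mask$grid)
  sel <- which(map$p_fwe <= alpha)
  empty <- data.frame(cluster = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), size_voxels = integer(0),
                      peak_t = numeric(0), cohens_d = numeric(0),
                      p_uncorr = numeric(0), p_fwe = numeric(0),
                      is_primary_peak = logical(0))
  class(empty) <- c("cluster_table", "data.frame")
  if (!length(sel)) return(empty)
  vox <- map$voxel_index[sel]
  labels <- label_components(vox, dims, connectivity)
  rows <- list()
  cl_id <- 0L
  for (comp in seq_len(max(labels))) {
    members <- which(labels == comp)
    if (length(members) < extent_k) next
    cl_id <- cl_id + 1L
    tvals <- map$t[sel[members]]
    ijk0 <- arrayInd(vox[members], dims) - 1L
    world <- voxel_to_world(map$affine, ijk0)
    # local maxima of |t| within the cluster
    is_max <- local_maxima_abs_t(vox[members], abs(tvals), dims, connectivity)
    cand <- order(-abs(tvals))
    cand <- cand[is_max[cand] | seq_along(cand) == 1]
    kept <- integer(0)
    for (i in cand) {
      if (!length(kept) ||
          all(sqrt(rowSums((world[kept, , drop = FALSE] -
                            matrix(world[i, ], length(kept), 3,
                                   byrow = TRUE))^2)) > peak_sep_mm))
        kept <- c(kept, i)
    }
    rows[[cl_id]] <- data.frame(
      cluster = cl_id, x = world[kept, 1], y = world[kept, 2],
      z = world[kept, 3], size_voxels = length(members),
      peak_t = tvals[kept],
      cohens_d = cohens_d_from_t(tvals[kept], n1, n2),
      p_uncorr = map$p_uncorr[sel[members[kept]]],
      p_fwe = map$p_fwe[sel[members[kept]]],
      is_primary_peak = seq_along(kept) == 1)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cluster_table", "data.frame")
  out
}

# TRUE where a member voxel's |t| is >= that of all its in-cluster neighbours.
local_maxima_abs_t <- function(vox, abst, dims, connectivity) {
  offs <- connectivity_offsets(connectivity)
  ijk <- arrayInd(vox, dims)
  val <- stats::setNames(abst, as.character(vox))
  vapply(seq_along(vox), function(i) {
    nb <- sweep(offs, 2, ijk[i, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- as.character(nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
                          (nb[ok, 3] - 1L) * dims[1] * dims[2])
    nbv <- val[lin]
    all(is.na(nbv) | nbv <= abst[i])
  }, TRUE)
}

#' Empirical extent threshold from a permutation null
#'
#' The smallest integer `k` such that the proportion of permutations whose
#' maximal null cluster reaches size `k` is at most `1 - q`; clusters at
#' least that large arise in no more than a `1 - q` fraction of the null.
#' Used to derive the extent threshold empirically instead of supplying it.
#'
#' @param null_sizes integer vector of maximal null cluster sizes, one per
#'   permutation (zeros allowed).
#' @param q coverage level (default 0.95).
#' @return integer threshold (>= 1).
#' @export
empirical_extent_threshold <- function(null_sizes, q = 0.95) {
  k <- 1L
  while (mean(null_sizes >= k) > 1 - q) k <- k + 1L
  k
}

#' Write a t map or FWE p map as NIfTI
#'
#' @param map a `tstat_map`.
#' @param path output `.nii(.gz)` path.
#' @param what `"t"` or `"p_fwe"`.
#' @export
write_stat_volume <- function(map, path, what = c("t", "p_fwe")) {
  what <- match.arg(what)
  vals <- map[[what]]
  if (is.null(vals)) qc_stop("qcmatch_validation_error", what, " not computed")
  grid <- array(0, dim = dim(map$mask$grid))
  grid[map$voxel_index] <- vals
  write_volume(volume_image(grid, map$affine), path)
}
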