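# Synthetic motion-confounded cohort generator. Patients move more in the
# scanner; motion degrades automated quality metrics and depresses apparent
# gray-matter volume, most strongly along tissue boundaries. Every module
# downstream is testable against this generator's known ground truth.

#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the confound structure of motion-contaminated
#' structural MRI group studies: a latent per-subject motion level is
#' lognormal with a group shift on the log scale (patients move more);
#' quality metrics are linear in motion plus Gaussian noise, clipped to
#' their valid ranges; per-voxel gray-matter values carry a smooth baseline,
#' an optional true group effect in spherical blobs, a motion artifact
#' (separate slopes at tissue-boundary and interior voxels, both reducing
#' gray matter as motion rises), additive/multiplicative site effects and
#' i.i.d. voxel noise.
#'
#' @param n_treated,n_control group sizes.
#' @param n_sites number of scan sites (round-robin assignment).
#' @param motion_log_shift treated-minus-control shift of log-motion, in SD
#'   units of the log scale.
#' @param motion_log_sd within-group SD of log-motion.
#' @param motion_log_mu control-group mean of log-motion.
#' @param qc_map per-metric linear maps `c(a, b, sd)`: the metric is
#'   `a - b * motion` (quality grades, higher is better) or `a + b * motion`
#'   (euler/defect, higher is worse) plus `N(0, sd)` noise, clipped to the
#'   metric's valid range. Defaults are calibrated so the image quality
#'   rating of a shifted cohort spans roughly the low-50s to high-80s
#'   percent range typical of large multi-site clinical releases.
#' @param grid_dims 3D grid shape for generated volumes.
#' @param voxel_size_mm isotropic voxel size (the affine is diagonal with
#'   the grid centre at the world origin).
#' @param mask_radius_vox radius (voxels) of the spherical analysis mask;
#'   default `min(grid_dims)/2 - 1`.
#' @param boundary_width_vox width of the boundary shell (artifact-prone rim
#'   of the mask).
#' @param effect_blobs list of `list(center=, radius=, amplitude=)` true
#'   group-effect spheres (`center` 0-based voxel indices). Amplitude is in
#'   gray-matter units, added for treated subjects.
#' @param artifact_slope_boundary,artifact_slope_interior gray-matter change
#'   per unit motion at boundary-shell / all in-mask voxels (subtracted).
#' @param baseline_mean,baseline_sd,baseline_smooth_vox smooth baseline
#'   field: Gaussian noise of SD `baseline_sd` smoothed with a
#'   `baseline_smooth_vox`-voxel sigma, plus `baseline_mean`.
#' @param voxel_noise_sd i.i.d. per-voxel subject noise SD.
#' @param site_additive_sd SD of per-site additive offsets.
#' @param site_multiplicative_range range of per-site multiplicative noise
#'   scale factors (uniform).
#' @param age_mean,age_sd,age_min age generator (normal, truncated below).
#' @param p_male probability of sex "M" (otherwise "F").
#' @param tiv_mean,tiv_sd,tiv_sex_gap total intracranial volume in ml;
#'   males get `tiv_sex_gap` more on average.
#' @param treated_label,control_label group labels.
#' @param seed default seed used when an operation is not given one.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_treated = 100, n_control = 100, n_sites = 1,
                         motion_log_shift = 0.5, motion_log_sd = 0.3,
                         motion_log_mu = 0,
                         qc_map = list(
                           res_grade   = c(a = 88, b = 4,  sd = 2),
                           noise_grade = c(a = 86, b = 8,  sd = 3),
                           bias_grade  = c(a = 90, b = 3,  sd = 2),
                           iqr_pct     = c(a = 85, b = 8,  sd = 3),
                           euler       = c(a = 30, b = 40, sd = 15),
                           defect_pct  = c(a = 2,  b = 3,  sd = 1)),
                         grid_dims = c(12, 12, 12), voxel_size_mm = 3,
                         mask_radius_vox = NULL, boundary_width_vox = 1.5,
                         effect_blobs = list(list(center = c(6, 6, 6),
                                                  radius = 2,
                                                  amplitude = 1.5)),
                         artifact_slope_boundary = 1.0,
                         artifact_slope_interior = 0.2,
                         baseline_mean = 10, baseline_sd = 2,
                         baseline_smooth_vox = 2,
                         voxel_noise_sd = 1,
                         site_additive_sd = 0.5,
                         site_multiplicative_range = c(0.8, 1.25),
                         age_mean = 30, age_sd = 8, age_min = 18,
                         p_male = 0.5,
                         tiv_mean = 1450, tiv_sd = 120, tiv_sex_gap = 100,
                         treated_label = "patient",
                         control_label = "control",
                         seed = 1L) {
  cfg <- as.list(environment())
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_treated < 1 || cfg$n_control < 1 || cfg$n_sites < 1)
    qc_stop("qcmatch_config_error", "counts must be >= 1")
  if (cfg$motion_log_sd < 0 || cfg$voxel_noise_sd < 0 ||
      cfg$site_additive_sd < 0 || cfg$baseline_sd < 0)
    qc_stop("qcmatch_config_error", "standard deviations must be >= 0")
  if (any(vapply(cfg$qc_map, function(m) m[["sd"]] < 0, TRUE)))
    qc_stop("qcmatch_config_error", "qc_map noise sd must be >= 0")
  if (length(cfg$grid_dims) != 3L || any(cfg$grid_dims < 1))
    qc_stop("qcmatch_config_error", "grid_dims must be three positive integers")
  r <- cfg$mask_radius_vox %||% (min(cfg$grid_dims) / 2 - 1)
  for (b in cfg$effect_blobs) {
    if (any(b$center < 0) || any(b$center > cfg$grid_dims - 1))
      qc_stop("qcmatch_config_error", "effect blob centre outside grid")
    if (b$radius > min(cfg$grid_dims))
      qc_stop("qcmatch_config_error", "effect blob larger than grid")
  }
  if (r <= 0) qc_stop("qcmatch_config_error", "grid too small for a mask")
  invisible(cfg)
}

#' Sample latent per-subject motion
#'
#' Motion is lognormal: `exp(N(mu_g, motion_log_sd^2))` with
#' `mu_treated = motion_log_mu + motion_log_shift` and
#' `mu_control = motion_log_mu`. Returned in cohort order (treated block
#' then control block) with a `"group"` attribute.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return nonnegative numeric vector of length `n_treated + n_control`.
#' @export
sample_motion <- function(config, seed = config$seed) {
  validate_synth_config(config)
  grp <- rep(c(config$treated_label, config$control_label),
             c(config$n_treated, config$n_control))
  mu <- ifelse(grp == config$treated_label,
               config$motion_log_mu + config$motion_log_shift,
               config$motion_log_mu)
  m <- with_local_seed(seed,
    exp(stats::rnorm(length(mu), mean = mu, sd = config$motion_log_sd)))
  attr(m, "group") <- grp
  m
}

#' Map motion to quality metrics
#'
#' Quality grades (resolution/noise/bias/image quality rating) fall linearly
#' in motion; the Euler number and defect size rise linearly. Gaussian noise
#' is added and percent metrics are clipped to `[0, 100]` (a mild
#' nonlinearity at the extremes).
#'
#' @param motion nonnegative motion vector.
#' @param config a [synth_config()].
#' @param seed RNG seed for the metric noise.
#' @return data frame with the six quality-metric columns.
#' @export
motion_to_qc <- function(motion, config, seed = config$seed) {
  if (any(motion < 0)) qc_stop("qcmatch_config_error", "motion must be >= 0")
  qm <- config$qc_map
  n <- length(motion)
  with_local_seed(seed, {
    lin <- function(m, sign) qm[[m]][["a"]] + sign * qm[[m]][["b"]] * motion +
      stats::rnorm(n, 0, qm[[m]][["sd"]])
    data.frame(
      res_grade   = pmin(pmax(lin("res_grade", -1), 0), 100),
      noise_grade = pmin(pmax(lin("noise_grade", -1), 0), 100),
      bias_grade  = pmin(pmax(lin("bias_grade", -1), 0), 100),
      iqr_pct     = pmin(pmax(lin("iqr_pct", -1), 0), 100),
      euler       = lin("euler", +1),
      defect_pct  = pmin(pmax(lin("defect_pct", +1), 0), 100))
  })
}

#' Generate a synthetic cohort table
#'
#' Groups, round-robin site assignment, demographics and quality metrics
#' driven by latent motion via [sample_motion()] and [motion_to_qc()].
#'
#' @inheritParams sample_motion
#' @return list with `cohort` (a [cohort_table()]) and `truth` (a
#'   `ground_truth` list carrying the latent motion and site effects).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_synth_config(config)
  motion <- sample_motion(config, seed = seed)
  grp <- attr(motion, "group")
  n <- length(motion)
  demo <- with_local_seed(seed + 1L, {
    age <- pmax(stats::rnorm(n, config$age_mean, config$age_sd), config$age_min)
    sex <- ifelse(stats::rbinom(n, 1, config$p_male) == 1, "M", "F")
    tiv <- stats::rnorm(n, config$tiv_mean, config$tiv_sd) +
      ifelse(sex == "M", config$tiv_sex_gap, 0)
    list(age = age, sex = sex, tiv = pmax(tiv, 800))
  })
  qc <- motion_to_qc(motion, config, seed = seed + 2L)
  site_fx <- with_local_seed(seed + 3L, list(
    gamma = stats::rnorm(config$n_sites, 0, config$site_additive_sd),
    delta = stats::runif(config$n_sites, config$site_multiplicative_range[1],
                         config$site_multiplicative_range[2])))
  if (config$n_sites == 1L) {
    site_fx$gamma <- 0
    site_fx$delta <- 1
  }
  site <- paste0("site", rep_len(seq_len(config$n_sites), n))
  df <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)), group = grp, site = site,
    age = demo$age, sex = demo$sex, tiv = demo$tiv, qc,
    stringsAsFactors = FALSE)
  cohort <- cohort_table(df, treated_label = config$treated_label,
                         control_label = config$control_label,
                         name = "synthetic")
  truth <- structure(list(motion = as.numeric(motion),
                          site_gamma = site_fx$gamma,
                          site_delta = site_fx$delta,
                          true_amplitude = vapply(config$effect_blobs,
                                                  `[[`, 0, "amplitude")),
                     class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

# Spherical mask / boundary-shell / effect-blob geometry for a config.
synth_geometry <- function(config) {
  d <- config$grid_dims
  r <- config$mask_radius_vox %||% (min(d) / 2 - 1)
  ctr <- (d - 1) / 2
  idx <- arrayInd(seq_len(prod(d)), d) - 1L
  dist <- sqrt(colSums((t(idx) - ctr)^2))
  mask <- array(as.numeric(dist <= r), dim = d)
  boundary <- array(as.numeric(dist <= r & dist > r - config$boundary_width_vox),
                    dim = d)
  effect <- array(0, dim = d)
  for (b in config$effect_blobs) {
    if (b$amplitude == 0) next
    db <- sqrt(colSums((t(idx) - b$center)^2))
    effect[db <= b$radius & mask > 0] <- 1
  }
  aff <- diag(c(rep(config$voxel_size_mm, 3), 1))
  aff[1:3, 4] <- -ctr * config$voxel_size_mm
  list(mask = volume_image(mask, aff), boundary = boundary, effect = effect,
       affine = aff)
}

#' Generate synthetic gray-matter volumes
#'
#' Each in-mask voxel value is
#' `baseline + amplitude * blob * treated - slope_boundary * motion * shell -
#' slope_interior * motion + site_gamma + site_delta * noise`,
#' i.e. a smooth anatomical baseline, an optional true group effect, a
#' motion artifact concentrated on the boundary shell plus a diffuse
#' interior component, and additive/multiplicative site effects on the
#' noise, mirroring the location/scale batch model that harmonization
#' removes.
#'
#' @param cohort a [cohort_table()] from [generate_cohort()].
#' @param truth the matching `ground_truth`.
#' @inheritParams sample_motion
#' @return list with `dataset` (a `voxel_dataset`) and `truth` augmented
#'   with `effect_mask` and `boundary_mask` volumes.
#' @export
generate_volumes <- function(cohort, truth, config, seed = config$seed) {
  validate_synth_config(config)
  geo <- synth_geometry(config)
  vox <- which(geo$mask$grid != 0)
  V <- length(vox)
  n <- nrow(cohort)
  stopifnot(length(truth$motion) == n)
  treated <- as.numeric(is_treated(cohort))
  site_num <- as.integer(factor(cohort$site,
                                levels = paste0("site", seq_len(config$n_sites))))
  with_local_seed(seed + 10L, {
    base_field <- gaussian_smooth_array(
      array(stats::rnorm(prod(config$grid_dims), 0, config$baseline_sd),
            dim = config$grid_dims),
      rep(config$baseline_smooth_vox, 3)) + config$baseline_mean
    noise <- matrix(stats::rnorm(n * V, 0, config$voxel_noise_sd), n, V)
  })
  data <- matrix(rep(base_field[vox], each = n), n, V)
  # true effect: per-voxel blob amplitude, added for treated subjects
  amp_field <- blob_amplitude_field(config, geo)
  data <- data + treated %o% amp_field[vox]
  data <- data - truth$motion %o% (config$artifact_slope_boundary * geo$boundary[vox])
  data <- data - config$artifact_slope_interior * truth$motion %o% rep(1, V)
  data <- data + truth$site_gamma[site_num] %o% rep(1, V)
  data <- data + noise * truth$site_delta[site_num]
  rownames(data) <- cohort$subject_id
  dataset <- new_voxel_dataset(data, geo$mask, cohort$subject_id, vox)
  truth$effect_mask <- volume_image(geo$effect, geo$affine)
  truth$boundary_mask <- volume_image(geo$boundary, geo$affine)
  list(dataset = dataset, truth = truth)
}

# Per-voxel amplitude of the true group effect (sum over blobs).
blob_amplitude_field <- function(config, geo) {
  d <- config$grid_dims
  idx <- arrayInd(seq_len(prod(d)), d) - 1L
  out <- array(0, dim = d)
  for (b in config$effect_blobs) {
    db <- sqrt(colSums((t(idx) - b$center)^2))
    sel <- db <= b$radius & geo$mask$grid > 0
    out[sel] <- out[sel] + b$amplitude
  }
  out
}

# Plain (unmasked, zero-padded) separable Gaussian smoothing of an array,
# sigma given in voxels per axis. Used for the synthetic baseline field.
gaussian_smooth_array <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, ax)
  }
  arr
}

# Zero-padded 1D convolution along one axis via banded-matrix multiply.
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) / 2L
  n <- d[axis]
  K <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- K %*% matrix(a, da[1], da[2] * da[3])
  dim(a) <- da
  aperm(a, order(perm))
}
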