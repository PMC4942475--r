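#' Specification for synthetic mediation datasets
#'
#' Defines the study conditions emulated by the generator: two age groups
#' (63 young, 112 old), global switch costs with group means 0.22 / 0.30 s
#' and SDs 0.083 / 0.15 s, spatially smooth volumetric maps in which
#' designated regions carry planted path coefficients and all other voxels
#' are null, and an ellipsoidal gray-matter envelope exercising the 0.5
#' probability threshold.
#'
#' A signal region is a list with `center` (voxel coordinates, 1-based,
#' possibly fractional), `radius` (voxels), `shape` (`"sphere"`: Euclidean
#' ball; `"cube"`: Chebyshev ball) and path coefficients `a`, `b`, `d`, `e`,
#' `f` plus the direct effect `c_prime`. The default region is a 2x2x2 cube
#' with a = -0.5, b = 0.4, d = 0.2, e = 0.3, f = 0.1 and c_prime = 0.13, so
#' the serial indirect effect a*b*e = -0.06 and the implied total effect
#' c = c_prime + a*f + d*e + a*b*e = 0.08 matches the behavioral group
#' difference.
#'
#' @param n_young,n_old group sizes.
#' @param cost_mean_young,cost_mean_old,cost_sd_young,cost_sd_old switch-cost
#'   moments in seconds (residual SD around the structural part of P).
#' @param grid_shape 3 integers.
#' @param voxel_size isotropic voxel size in mm.
#' @param signal_regions list of region lists (see Details); `list()` for a
#'   null dataset with no planted effects.
#' @param baseline_S,baseline_F map baselines (arbitrary units; a positive
#'   activation baseline makes the one-sample activation screen pass inside
#'   the gray-matter envelope).
#' @param noise_sd_S,noise_sd_F voxel noise SD before smoothing.
#' @param smooth_fwhm Gaussian smoothing FWHM in mm applied to the noise
#'   fields (8 mm isotropic by default); the planted signal is added
#'   un-smoothed so in-region voxels carry the planted coefficients exactly.
#' @param subject_sd_S,subject_sd_F SD of per-subject region-level scatter
#'   added uniformly to all voxels of a signal region: individual differences
#'   in regional gray-matter volume and activation beyond what group,
#'   covariates and voxel noise explain. This between-subject variation in S
#'   and F (given A) is what identifies the b, e and f paths in real data;
#'   without it, mediator variation would come only from residual voxel
#'   noise.
#' @param nwbv_mean_young mean nWBV of the young group; the old group's mean
#'   is `nwbv_old_shift` (fraction) lower.
#' @param nwbv_sd,nwbv_old_shift nWBV spread and relative old-group deficit.
#' @param covariate_effects named list with numeric length-2 vectors
#'   (`c(sex, nwbv)`) of covariate coefficients for `S`, `F` and `P`.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_young = 63, n_old = 112,
                           cost_mean_young = 0.22, cost_mean_old = 0.30,
                           cost_sd_young = 0.083, cost_sd_old = 0.15,
                           grid_shape = c(16, 16, 16), voxel_size = 2,
                           signal_regions = default_signal_region(grid_shape),
                           baseline_S = 0.5, baseline_F = 0.5,
                           noise_sd_S = 0.5, noise_sd_F = 0.5,
                           subject_sd_S = 0.15, subject_sd_F = 0.2,
                           smooth_fwhm = 8,
                           nwbv_mean_young = 0.78, nwbv_sd = 0.03,
                           nwbv_old_shift = 0.05,
                           covariate_effects = list(S = c(0, 0), F = c(0, 0),
                                                    P = c(0, 0))) {
  stopifnot(n_young >= 2, n_old >= 2, cost_sd_young >= 0, cost_sd_old >= 0,
            subject_sd_S >= 0, subject_sd_F >= 0,
            length(grid_shape) == 3, voxel_size > 0, smooth_fwhm >= 0,
            noise_sd_S >= 0, noise_sd_F >= 0)
  for (rg in signal_regions) {
    if (any(rg$center - rg$radius < 1) ||
        any(rg$center + rg$radius > grid_shape)) {
      stop("signal region extends outside the grid")
    }
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_signal_region <- function(grid_shape = c(16, 16, 16)) {
  ctr <- (grid_shape + 1) / 2 # e.g. 8.5: a 2-wide cube at radius 0.5
  list(list(center = ctr, radius = 0.5, shape = "cube",
            a = -0.5, b = 0.4, d = 0.2, e = 0.3, f = 0.1, c_prime = 0.13))
}

region_voxels <- function(region, grid) {
  ijk <- voxel_ijk(seq_len(prod(grid)), grid) + 1 # 1-based
  dd <- sweep(ijk, 2, region$center)
  inside <- if (identical(region$shape, "cube")) {
    apply(abs(dd) <= region$radius + 1e-9, 1, all)
  } else {
    sqrt(rowSums(dd^2)) <= region$radius + 1e-9
  }
  which(inside)
}

#' Generate a subject table under the study conditions
#'
#' Group labels per the spec's counts; sex Bernoulli(1/2); nWBV Gaussian with
#' the old group's mean shifted down; switch cost P Gaussian per group with
#' the spec's means/SDs, truncated at zero. Fully determined by the seed.
#' When brain maps are later generated with planted path coefficients,
#' [generate_brain_maps()] regenerates P from the structural model so the
#' planted pathways are exactly consistent.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return subject table (see [subject_table()]).
#' @export
generate_subjects <- function(spec, seed = 1) {
  with_seed(seed, {
    n <- spec$n_young + spec$n_old
    group <- rep(c(0, 1), c(spec$n_young, spec$n_old))
    sex <- stats::rbinom(n, 1, 0.5)
    nwbv_mean <- ifelse(group == 1,
                        spec$nwbv_mean_young * (1 - spec$nwbv_old_shift),
                        spec$nwbv_mean_young)
    nwbv <- pmin(1, pmax(1e-3, stats::rnorm(n, nwbv_mean, spec$nwbv_sd)))
    mu <- ifelse(group == 1, spec$cost_mean_old, spec$cost_mean_young)
    sdv <- ifelse(group == 1, spec$cost_sd_old, spec$cost_sd_young)
    P <- rtruncnorm_pos(n, mu, sdv)
    subject_table(group = group, switch_cost = P, sex = sex, nwbv = nwbv)
  })
}

# Normal draws truncated at zero (rejection sampling; the study's means are
# 2+ SDs above zero so acceptance is near 1).
rtruncnorm_pos <- function(n, mu, sdv) {
  x <- stats::rnorm(n, mu, sdv)
  while (any(neg <- x <= 0)) {
    x[neg] <- stats::rnorm(sum(neg), mu[neg], sdv[neg])
  }
  x
}

#' Generate trial-level records implying a given global switch cost
#'
#' Single-task block RTs centered at `base_rt`, switch-block RTs at
#' `base_rt + cost`, correctness Bernoulli(`accuracy`);
#' [compute_global_switch_cost()] recovers `cost` in expectation (exactly
#' when `rt_sd = 0` and `accuracy = 1`).
#'
#' @param cost global switch cost in seconds.
#' @param base_rt single-task mean RT in seconds.
#' @param n_per_condition trials per block condition.
#' @param rt_sd trial RT standard deviation.
#' @param accuracy probability a trial is correct.
#' @param seed integer seed.
#' @return data.frame of trial records (`block_type`, `rt`, `correct`,
#'   `responded`).
#' @export
generate_trials <- function(cost, base_rt = 0.5, n_per_condition = 40,
                            rt_sd = 0.1, accuracy = 0.95, seed = 1) {
  stopifnot(accuracy > 0, accuracy <= 1, n_per_condition >= 1)
  with_seed(seed, {
    n <- n_per_condition
    rt <- c(pmax(0.05, stats::rnorm(n, base_rt, rt_sd)),
            pmax(0.05, stats::rnorm(n, base_rt + cost, rt_sd)))
    data.frame(block_type = rep(c("single", "switch"), each = n),
               rt = rt,
               correct = stats::runif(2 * n) <= accuracy,
               responded = TRUE)
  })
}

# Separable 3D Gaussian smoothing; kernel rows renormalized so constant maps
# stay constant. A no-op at fwhm = 0.
smooth_volume <- function(arr, fwhm_mm, voxel_size) {
  if (fwhm_mm <= 0) return(arr)
  sigma <- fwhm_mm / voxel_size / (2 * sqrt(2 * log(2)))
  kmat <- function(d) {
    K <- outer(seq_len(d), seq_len(d),
               function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
    K[abs(row(K) - col(K)) > ceiling(4 * sigma)] <- 0
    K / rowSums(K)
  }
  d <- dim(arr)
  x <- kmat(d[1]) %*% matrix(arr, d[1], d[2] * d[3])
  x <- array(x, d)
  x <- aperm(array(kmat(d[2]) %*% matrix(aperm(x, c(2, 1, 3)), d[2], d[1] * d[3]),
                   d[c(2, 1, 3)]), c(2, 1, 3))
  x <- aperm(array(kmat(d[3]) %*% matrix(aperm(x, c(3, 1, 2)), d[3], d[1] * d[2]),
                   d[c(3, 1, 2)]), c(2, 3, 1))
  x
}

#' Generate brain map sets with planted mediation structure
#'
#' For each subject, spatially smooth Gaussian noise fields are drawn for the
#' structural (S) and functional (F) maps; inside each signal region the
#' planted model is added per voxel: `S = baseline_S + a*A + cov + noise`,
#' `F = baseline_F + b*S + d*A + cov + noise`. The switch cost is regenerated
#' from the structural model, `P = e*Fbar + f*Sbar + c_prime*A + cov +
#' noise`, with `Fbar`, `Sbar` the subject means over the primary (first)
#' signal region, so that the planted pathway is exactly consistent with the
#' maps; region-free specs keep the marginal group draw. The gray-matter
#' probability map is an ellipsoidal envelope (0.9 inside, 0.1 outside).
#'
#' @param subjects from [generate_subjects()] (or compatible).
#' @param spec a [synthetic_spec()].
#' @param seed integer seed (determines the map noise and regenerated P).
#' @return list with `maps` (a [brain_map_set()]), `subjects` (with
#'   regenerated P when signal regions exist), and `truth` (planted
#'   coefficients with region voxel indices and implied effects).
#' @export
generate_brain_maps <- function(subjects, spec, seed = 1) {
  grid <- as.integer(spec$grid_shape)
  V <- prod(grid)
  n <- nrow(subjects)
  A <- subjects$group
  zs <- function(x) {
    if (anyNA(x) || stats::sd(x) == 0) return(rep(0, length(x)))
    (x - mean(x)) / stats::sd(x)
  }
  sexz <- zs(subjects$sex); nwbvz <- zs(subjects$nwbv)
  cov_S <- spec$covariate_effects$S[1] * sexz + spec$covariate_effects$S[2] * nwbvz
  cov_F <- spec$covariate_effects$F[1] * sexz + spec$covariate_effects$F[2] * nwbvz
  cov_P <- spec$covariate_effects$P[1] * sexz + spec$covariate_effects$P[2] * nwbvz

  with_seed(seed, {
    S <- matrix(0, n, V); Fm <- matrix(0, n, V)
    for (s in seq_len(n)) {
      nS <- smooth_volume(array(stats::rnorm(V, 0, spec$noise_sd_S), grid),
                          spec$smooth_fwhm, spec$voxel_size)
      nF <- smooth_volume(array(stats::rnorm(V, 0, spec$noise_sd_F), grid),
                          spec$smooth_fwhm, spec$voxel_size)
      S[s, ] <- spec$baseline_S + cov_S[s] + as.numeric(nS)
      Fm[s, ] <- spec$baseline_F + cov_F[s] + as.numeric(nF)
    }
    truth <- list(regions = list())
    for (rg in spec$signal_regions) {
      vox <- region_voxels(rg, grid)
      eta_S <- stats::rnorm(n, 0, spec$subject_sd_S)
      eta_F <- stats::rnorm(n, 0, spec$subject_sd_F)
      S[, vox] <- S[, vox] + rg$a * A + eta_S
      Fm[, vox] <- Fm[, vox] + rg$b * (S[, vox] - spec$baseline_S) +
        rg$d * A + eta_F
      truth$regions <- c(truth$regions, list(c(rg, list(
        voxels = vox,
        ind_S = rg$a * rg$f, ind_F = rg$d * rg$e, ind_SF = rg$a * rg$b * rg$e,
        total = rg$c_prime + rg$a * rg$f + rg$d * rg$e + rg$a * rg$b * rg$e))))
    }
    if (length(spec$signal_regions) > 0) {
      rg <- spec$signal_regions[[1]]
      vox <- truth$regions[[1]]$voxels
      Sbar <- rowMeans(S[, vox, drop = FALSE])
      Fbar <- rowMeans(Fm[, vox, drop = FALSE])
      sd_resid <- ifelse(A == 1, spec$cost_sd_old, spec$cost_sd_young)
      base_P <- spec$cost_mean_young -
        (rg$e * spec$baseline_F + rg$f * spec$baseline_S)
      subjects$switch_cost <- base_P + rg$e * Fbar + rg$f * Sbar +
        rg$c_prime * A + cov_P + stats::rnorm(n, 0, sd_resid)
    }
    # centered ellipsoid gray-matter envelope
    ijk <- voxel_ijk(seq_len(V), grid) + 1
    cen <- (grid + 1) / 2
    r2 <- rowSums(sweep(sweep(ijk, 2, cen), 2, 0.45 * grid, "/")^2)
    gm_prob <- ifelse(r2 <= 1, 0.9, 0.1)
    list(maps = brain_map_set(S = S, F = Fm, grid = grid,
                              affine = default_affine(grid, spec$voxel_size),
                              gm_prob = gm_prob),
         subjects = subjects, truth = truth)
  })
}

#' One-call synthetic dataset
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return list with `maps`, `subjects`, `truth` (see
#'   [generate_brain_maps()]).
#' @export
generate_dataset <- function(spec = synthetic_spec(), seed = 1) {
  subj <- generate_subjects(spec, seed = seed)
  generate_brain_maps(subj, spec, seed = seed + 1)
}

#' Write a synthetic dataset to disk
#'
#' NIfTI maps, the tab-separated subject table, and a ground-truth sidecar
#' (plain text, one row per region with planted coefficients) for later
#' evaluation.
#'
#' @param dataset from [generate_dataset()].
#' @param prefix output path prefix.
#' @export
write_dataset <- function(dataset, prefix) {
  write_brain_maps(dataset$maps, prefix)
  write_subject_table(dataset$subjects, paste0(prefix, "_subjects.tsv"))
  truth <- do.call(rbind, lapply(dataset$truth$regions, function(rg) {
    data.frame(center = paste(rg$center, collapse = ","),
               radius = rg$radius, shape = rg$shape, n_voxels = length(rg$voxels),
               a = rg$a, b = rg$b, d = rg$d, e = rg$e, f = rg$f,
               c_prime = rg$c_prime, ind_S = rg$ind_S, ind_F = rg$ind_F,
               ind_SF = rg$ind_SF, total = rg$total)
  }))
  if (is.null(truth)) truth <- data.frame()
  utils::write.table(truth, paste0(prefix, "_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
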