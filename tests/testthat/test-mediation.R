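test_that("group activation t maps match hand and oracle computations", {
  # hand pooled-t: young F {0,2}, old F {1,3} at one voxel
  grid <- c(2, 2, 1)
  S <- matrix(rnorm(16), 4, 4)
  Fm <- matrix(c(0, 2, 1, 3), 4, 4) # same values at every voxel
  maps <- brain_map_set(S, Fm, grid)
  st <- subject_table(group = c(0, 0, 1, 1), switch_cost = rnorm(4, 0.3))
  act <- group_activation_tests(maps, st)
  expect_equal(act$t_old_gt_young[1], 1 / sqrt(2 * (1 / 2 + 1 / 2)))
  expect_equal(act$t_young[1], mean(c(0, 2)) / sqrt(var(c(0, 2)) / 2))
  # sign flip negates all three maps
  maps2 <- brain_map_set(S, -Fm, grid)
  act2 <- group_activation_tests(maps2, st)
  expect_equal(act2$t_young, -act$t_young)
  expect_equal(act2$t_old, -act$t_old)
  expect_equal(act2$t_old_gt_young, -act$t_old_gt_young)
})

test_that("zero within-group variance yields non-finite t, excluded from mask", {
  grid <- c(2, 1, 1)
  Fm <- cbind(c(1, 1, 1, 2, 3), rnorm(5))
  maps <- brain_map_set(matrix(rnorm(10), 5), Fm, grid)
  st <- subject_table(group = c(0, 0, 0, 1, 1), switch_cost = rnorm(5, 0.3))
  act <- group_activation_tests(maps, st)
  expect_false(is.finite(act$t_young[1]))
  mask <- suppressWarnings(
    build_analysis_mask(maps, st, alpha = 1, gm_threshold = 0))
  # voxel 1 young t is non-finite; old group {2,3} keeps it in at alpha = 1
  expect_true(mask[1])
})

test_that("analysis mask obeys gray-matter dominance and critical t", {
  ds <- quick_dataset(seed = 2)
  # gm_prob below threshold everywhere -> empty mask with warning
  maps_lowgm <- brain_map_set(ds$maps$S, ds$maps$F, ds$maps$grid,
                              ds$maps$affine,
                              gm_prob = rep(0.4, prod(ds$maps$grid)))
  expect_warning(m0 <- build_analysis_mask(maps_lowgm, ds$subjects), "empty")
  expect_false(any(m0))
  # alpha = 1 degenerates to the gray-matter threshold
  m1 <- build_analysis_mask(ds$maps, ds$subjects, alpha = 1)
  expect_equal(m1, ds$maps$gm_prob > 0.5 & is.finite(ds$maps$gm_prob))
  # two-voxel toy: strong effect passes, weak does not
  grid <- c(2, 1, 1)
  n <- 20
  set.seed(5)
  Fm <- cbind(rnorm(n, 3, 1), rnorm(n, 0, 1) * 0.1)
  maps <- brain_map_set(matrix(rnorm(2 * n), n), Fm, grid)
  st <- subject_table(group = rep(c(0, 1), each = 10),
                      switch_cost = rnorm(n, 0.3, 0.05))
  mask <- build_analysis_mask(maps, st)
  act <- group_activation_tests(maps, st)
  crit <- qt(0.975, 9)
  expect_equal(mask,
               (abs(act$t_young) > crit | abs(act$t_old) > crit) & TRUE)
})

test_that("vectorized voxel-wise fit equals a per-voxel lm oracle", {
  ds <- quick_dataset(n_young = 6, n_old = 8, grid = c(4, 4, 4), seed = 9)
  mask <- rep(TRUE, 64)
  fit <- fit_voxelwise_mediation(ds$maps, ds$subjects, mask)
  orc <- oracle_mediation_fit(ds$maps, ds$subjects, mask)
  for (k in c("a", "b", "d", "e", "f", "c_prime")) {
    expect_equal(unname(fit[[k]]), unname(orc[[k]]), tolerance = 1e-10,
                 label = paste("coefficient", k))
  }
  expect_equal(fit$c, orc$c, tolerance = 1e-12)
})

test_that("noise-free planted coefficients are recovered to machine precision", {
  # A noise-free voxel: S carries structural variation orthogonal to the
  # design (so Eq 2 is exactly interpolable without making Eq 3 collinear),
  # and F, P are exact linear functions of their regressors.
  set.seed(17)
  n <- 30
  A <- rep(c(0, 1), c(12, 18))
  sex <- rbinom(n, 1, 0.5)
  nwbv <- runif(n, 0.7, 0.85)
  zsc <- function(x) (x - mean(x)) / sd(x)
  eta <- residuals(lm(rnorm(n) ~ A + zsc(sex) + zsc(nwbv)))
  S <- 0.5 - 0.5 * A + eta
  # F needs exact residual variation of its own (orthogonal to the Eq 3
  # design), otherwise F lies in span{1, S, A} and Eq 4 is unidentified
  nu <- residuals(lm(rnorm(n) ~ A + zsc(sex) + zsc(nwbv) + S))
  Fv <- 0.5 + 0.4 * (S - 0.5) + 0.2 * A + nu
  P <- 0.3 * Fv + 0.1 * S + 0.13 * A + 0.05
  maps <- brain_map_set(cbind(S, S), cbind(Fv, Fv), grid = c(2, 1, 1))
  st <- subject_table(group = A, switch_cost = P, sex = sex, nwbv = nwbv)
  fit <- fit_voxelwise_mediation(maps, st, rep(TRUE, 2))
  expect_equal(fit$a, rep(-0.5, 2), tolerance = 1e-12)
  expect_equal(fit$b, rep(0.4, 2), tolerance = 1e-12)
  expect_equal(fit$d, rep(0.2, 2), tolerance = 1e-12)
  expect_equal(fit$e, rep(0.3, 2), tolerance = 1e-12)
  expect_equal(fit$f, rep(0.1, 2), tolerance = 1e-12)
  expect_equal(fit$c_prime, rep(0.13, 2), tolerance = 1e-12)
})

test_that("estimates converge to planted truth as noise shrinks", {
  region <- default_signal_region(c(6, 6, 6))
  # Noise scales must vanish at different rates so every path stays
  # identified while its error goes to zero: each equation's residual must
  # shrink faster than the exogenous variation of its regressors
  # (S scatter ~ sqrt(sd), F residual ~ sd, cost residual ~ sd^1.5).
  err_at <- function(sd) {
    spec <- synthetic_spec(n_young = 40, n_old = 60, grid_shape = c(6, 6, 6),
                           signal_regions = region,
                           noise_sd_S = sd, noise_sd_F = sd,
                           cost_sd_young = sd^1.5, cost_sd_old = sd^1.5,
                           subject_sd_S = 0.3 * sqrt(sd),
                           subject_sd_F = sd)
    ds <- generate_dataset(spec, seed = 21)
    vox <- ds$truth$regions[[1]]$voxels
    mask <- logical(216); mask[vox] <- TRUE
    fit <- fit_voxelwise_mediation(ds$maps, ds$subjects, mask)
    max(abs(fit$a + 0.5), abs(fit$b - 0.4), abs(fit$e - 0.3))
  }
  errs <- vapply(c(0.5, 0.02, 1e-4), err_at, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
  expect_lt(errs[3], 0.02)
})

test_that("constant structural map at a voxel fails naming the voxel", {
  ds <- quick_dataset(n_young = 5, n_old = 5, grid = c(2, 2, 1), seed = 3,
                      regions = list())
  ds$maps$S[, 2] <- 1
  expect_error(
    fit_voxelwise_mediation(ds$maps, ds$subjects, rep(TRUE, 4)),
    "collinear.*2|voxel.*2")
})

test_that("non-finite map values inside the mask fail naming the voxel", {
  ds <- quick_dataset(n_young = 5, n_old = 5, grid = c(2, 2, 1), seed = 3,
                      regions = list())
  ds$maps$F[2, 3] <- NA
  expect_error(
    fit_voxelwise_mediation(ds$maps, ds$subjects, rep(TRUE, 4)),
    "non-finite.*3")
})

test_that("indirect effects are coefficient products with exact decomposition", {
  # hand products
  fake <- structure(list(a = -0.5, b = 0.4, d = 0.2, e = 0.3, f = 0.1,
                         c_prime = 0.13, c = 0.08, mask = TRUE,
                         grid = c(1, 1, 1), affine = diag(4)),
                    class = "path_coefs")
  eff <- compute_indirect_effects(fake)
  expect_equal(eff$ind_SF, -0.06)
  expect_equal(eff$ind_S, -0.05)
  expect_equal(eff$ind_F, 0.06)
  # a = 0 kills the S-involving pathways
  fake$a <- 0
  eff0 <- compute_indirect_effects(fake)
  expect_equal(eff0$ind_S, 0)
  expect_equal(eff0$ind_SF, 0)
  # decomposition identity on random fitted data
  for (seed in 1:3) {
    ds <- quick_dataset(grid = c(5, 5, 5), seed = seed)
    fit <- fit_voxelwise_mediation(ds$maps, ds$subjects, rep(TRUE, 125))
    eff <- compute_indirect_effects(fit)
    resid <- eff$total - eff$direct - eff$ind_S - eff$ind_F - eff$ind_SF
    expect_lt(max(abs(resid)), 1e-10 * abs(eff$total))
  }
})

test_that("permuting subject order leaves all outputs unchanged", {
  ds <- quick_dataset(grid = c(5, 5, 5), seed = 13)
  mask <- build_analysis_mask(ds$maps, ds$subjects)
  fit <- fit_voxelwise_mediation(ds$maps, ds$subjects, mask)
  set.seed(1)
  ord <- sample(nrow(ds$subjects))
  maps2 <- brain_map_set(ds$maps$S[ord, ], ds$maps$F[ord, ], ds$maps$grid,
                         ds$maps$affine, ds$maps$gm_prob)
  fit2 <- fit_voxelwise_mediation(maps2, ds$subjects[ord, ], mask)
  for (k in c("a", "b", "d", "e", "f", "c_prime", "c")) {
    expect_equal(fit2[[k]], fit[[k]], tolerance = 1e-12)
  }
})

test_that("percent indirect is signed and guards a zero total", {
  eff <- structure(list(ind_S = -0.004, ind_F = 0.08, ind_SF = -0.004096,
                        direct = 0.1, total = 0.08),
                   class = "effect_maps")
  pct <- percent_indirect(eff)
  expect_equal(pct$ind_S, -5)
  expect_equal(pct$ind_F, 100)
  expect_equal(pct$ind_SF, -5.12)
  eff$total <- 0
  expect_error(percent_indirect(eff), "total effect is zero")
})
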