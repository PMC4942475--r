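#' Per-group and between-group activation t maps
#'
#' At every voxel: one-sample t of the activation contrast F against zero
#' within the young and old groups, and the pooled-variance two-sample t of
#' old minus young. Voxels with zero within-group variance yield non-finite
#' t values (`NaN`/`Inf`), which [build_analysis_mask()] excludes.
#'
#' @param maps a [brain_map_set()].
#' @param subjects subject table aligned with `maps` (same subject order).
#' @return list of class `group_activation` with vectors `t_young`, `t_old`,
#'   `t_old_gt_young` (length `prod(grid)`) and the degrees of freedom
#'   `df_young`, `df_old`, `df_between`.
#' @export
group_activation_tests <- function(maps, subjects) {
  stopifnot(n_subjects(maps) == nrow(subjects))
  g <- subjects$group
  if (sum(g == 0) < 2L || sum(g == 1) < 2L) {
    stop("both groups need at least 2 subjects")
  }
  one_sample <- function(Fm) {
    n <- nrow(Fm)
    mu <- colMeans(Fm)
    s2 <- colSums(sweep(Fm, 2, mu)^2) / (n - 1)
    mu / sqrt(s2 / n)
  }
  Fy <- maps$F[g == 0, , drop = FALSE]
  Fo <- maps$F[g == 1, , drop = FALSE]
  ny <- nrow(Fy); no <- nrow(Fo)
  my <- colMeans(Fy); mo <- colMeans(Fo)
  s2y <- colSums(sweep(Fy, 2, my)^2) / (ny - 1)
  s2o <- colSums(sweep(Fo, 2, mo)^2) / (no - 1)
  s2p <- ((ny - 1) * s2y + (no - 1) * s2o) / (ny + no - 2)
  structure(list(
    t_young = one_sample(Fy),
    t_old = one_sample(Fo),
    t_old_gt_young = (mo - my) / sqrt(s2p * (1 / ny + 1 / no)),
    df_young = ny - 1L, df_old = no - 1L, df_between = ny + no - 2L
  ), class = "group_activation")
}

#' Build the analysis mask
#'
#' A voxel enters the analysis if the activation contrast shows an effect in
#' at least one group — `|t|` exceeds the two-tailed critical value at
#' `alpha` for that group's own degrees of freedom, from uncorrected
#' one-sample t tests — and the gray-matter probability exceeds
#' `gm_threshold`. Voxels with non-finite t in both groups are excluded.
#'
#' @param maps a [brain_map_set()].
#' @param subjects aligned subject table.
#' @param alpha two-tailed uncorrected significance level for the activation
#'   screen (default 0.05).
#' @param gm_threshold gray-matter probability cutoff (default 0.5).
#' @return logical vector of length `prod(grid)`.
#' @export
build_analysis_mask <- function(maps, subjects, alpha = 0.05,
                                gm_threshold = 0.5) {
  act <- group_activation_tests(maps, subjects)
  crit_y <- stats::qt(1 - alpha / 2, act$df_young)
  crit_o <- stats::qt(1 - alpha / 2, act$df_old)
  pass_y <- is.finite(act$t_young) & abs(act$t_young) > crit_y
  pass_o <- is.finite(act$t_old) & abs(act$t_old) > crit_o
  mask <- (pass_y | pass_o) & maps$gm_prob > gm_threshold
  if (!any(mask)) {
    warning("analysis mask is empty: no voxel passes the activation screen ",
            "and gray-matter threshold")
  }
  mask
}

# Residualize columns of Y on Z (with Z including the intercept).
# Zplus = (Z'Z)^{-1} Z' is precomputed by the caller.
residualize <- function(Y, Z, Zplus) Y - Z %*% (Zplus %*% Y)

# Core vectorized path fit on residualized data (Frisch-Waugh-Lovell).
# At: residualized group indicator (n); St, Ft: residualized maps
# (n x V, in-mask voxels only); Pt: residualized switch cost (n).
# Returns the six path coefficients (a, b, d, e, f, c_prime as V-vectors;
# c scalar) plus the per-equation residual sums of squares.
fit_paths_core <- function(At, St, Ft, Pt, check = TRUE) {
  Saa <- sum(At^2)
  if (Saa <= 0) stop("group indicator is collinear with the covariates")
  Ptt <- sum(Pt^2)
  Sap <- sum(At * Pt)

  # Eq 1: P ~ A (total effect, scalar)
  c_total <- Sap / Saa

  # Eq 2: S ~ A, per voxel
  Sas <- drop(crossprod(At, St))           # A'S per voxel
  Sss <- .colSums(St * St, nrow(St), ncol(St))
  a <- Sas / Saa

  # Eq 3: F ~ S + A, per voxel (2x2 normal equations)
  Saf <- drop(crossprod(At, Ft))
  Sff <- .colSums(Ft * Ft, nrow(Ft), ncol(Ft))
  Ssf <- .colSums(St * Ft, nrow(St), ncol(St))
  det3 <- Sss * Saa - Sas^2
  if (check && any(bad <- det3 <= .Machine$double.eps * pmax(Sss * Saa, 1))) {
    stop("structural map is collinear with the design (constant S?) at ",
         "voxel(s) ", paste(utils::head(which(bad), 5), collapse = ", "))
  }
  b <- (Ssf * Saa - Saf * Sas) / det3
  d <- (Saf * Sss - Ssf * Sas) / det3

  # Eq 4: P ~ F + S + A, per voxel (3x3 symmetric solve via Cramer)
  Sfp <- drop(crossprod(Ft, Pt))
  Ssp <- drop(crossprod(St, Pt))
  # Gram matrix per voxel: [Sff Ssf Saf; Ssf Sss Sas; Saf Sas Saa]
  M11 <- Sss * Saa - Sas^2
  M12 <- Ssf * Saa - Saf * Sas
  M13 <- Ssf * Sas - Saf * Sss
  M22 <- Sff * Saa - Saf^2
  M23 <- Sff * Sas - Ssf * Saf
  M33 <- Sff * Sss - Ssf^2
  det4 <- Sff * M11 - Ssf * M12 + Saf * M13
  if (check && any(bad <- det4 <= .Machine$double.eps * pmax(Sff * M11, 1))) {
    stop("rank-deficient voxel design (F, S, A collinear) at voxel(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  e       <- ( M11 * Sfp - M12 * Ssp + M13 * Sap) / det4
  f_coef  <- (-M12 * Sfp + M22 * Ssp - M23 * Sap) / det4
  c_prime <- ( M13 * Sfp - M23 * Ssp + M33 * Sap) / det4

  list(a = a, b = b, d = d, e = e, f = f_coef, c_prime = c_prime,
       c = c_total,
       rss1 = Ptt - c_total * Sap,
       rss2 = Sss - a * Sas,
       rss3 = Sff - b * Ssf - d * Saf,
       rss4 = Ptt - e * Sfp - f_coef * Ssp - c_prime * Sap)
}

#' Fit the serial mediation path model at every in-mask voxel
#'
#' At each voxel inside the analysis mask, ordinary least squares fits of the
#' four path equations with age group A, gray-matter volume S, activation F
#' and switch cost P (sex and nWBV as covariates in every equation):
#' \deqn{P = c A + \epsilon_1}
#' \deqn{S = a A + \epsilon_2}
#' \deqn{F = b S + d A + \epsilon_3}
#' \deqn{P = e F + f S + c' A + \epsilon_4}
#' Fitting uses the Frisch-Waugh-Lovell residualization on the shared
#' covariate block, which reproduces the full-design OLS coefficients exactly
#' and vectorizes over voxels.
#'
#' @param maps a [brain_map_set()].
#' @param subjects aligned subject table.
#' @param mask logical analysis mask (vector or 3D array); see
#'   [build_analysis_mask()].
#' @param with_covariates include sex and nWBV (z-scored) in every equation.
#' @return object of class `path_coefs`: per-voxel coefficient vectors `a`,
#'   `b`, `d`, `e`, `f`, `c_prime` (length = in-mask voxel count), scalar
#'   total effect `c`, intercept/covariate coefficients per equation,
#'   residual variances, per-equation df, the mask and grid.
#' @export
fit_voxelwise_mediation <- function(maps, subjects, mask,
                                    with_covariates = TRUE) {
  stopifnot(n_subjects(maps) == nrow(subjects))
  m <- mask_vector(mask, maps$grid)
  if (!any(m)) stop("analysis mask is empty")
  n <- nrow(subjects)
  S <- maps$S[, m, drop = FALSE]
  F <- maps$F[, m, drop = FALSE]
  if (anyNA(S) || anyNA(F) || any(!is.finite(S)) || any(!is.finite(F))) {
    bad <- which(colSums(!is.finite(S)) + colSums(!is.finite(F)) > 0)
    stop("non-finite map values inside the mask at voxel(s) ",
         paste(utils::head(which(m)[bad], 5), collapse = ", "))
  }
  X <- design_matrix(subjects, with_covariates)   # validates rank
  Z <- X[, colnames(X) != "group", drop = FALSE]  # intercept + covariates
  A <- subjects$group
  P <- subjects$switch_cost
  Zplus <- solve(crossprod(Z), t(Z))
  At <- drop(residualize(cbind(A), Z, Zplus))
  Pt <- drop(residualize(cbind(P), Z, Zplus))
  St <- residualize(S, Z, Zplus)
  Ft <- residualize(F, Z, Zplus)

  fit <- fit_paths_core(At, St, Ft, Pt)

  p_cov <- ncol(Z)                       # intercept (+ sex + nwbv)
  df <- c(eq1 = n - p_cov - 1L, eq2 = n - p_cov - 1L,
          eq3 = n - p_cov - 2L, eq4 = n - p_cov - 3L)
  # Covariate/intercept coefficients by back-substitution:
  # gamma = (Z'Z)^{-1} Z'(y - X_main beta)
  gam1 <- Zplus %*% (P - A * fit$c)
  gam2 <- Zplus %*% (S - tcrossprod(A, fit$a))
  gam3 <- Zplus %*% (F - St_scale(S, fit$b) - tcrossprod(A, fit$d))
  gam4 <- Zplus %*% (P - St_scale(F, fit$e) - St_scale(S, fit$f) -
                       tcrossprod(A, fit$c_prime))
  rownames(gam1) <- rownames(gam2) <- rownames(gam3) <- rownames(gam4) <-
    colnames(Z)

  structure(list(
    a = fit$a, b = fit$b, d = fit$d, e = fit$e, f = fit$f,
    c_prime = fit$c_prime, c = fit$c,
    covariate_coefs = list(eq1 = gam1, eq2 = gam2, eq3 = gam3, eq4 = gam4),
    residual_variance = list(eq1 = fit$rss1 / df["eq1"],
                             eq2 = fit$rss2 / df["eq2"],
                             eq3 = fit$rss3 / df["eq3"],
                             eq4 = fit$rss4 / df["eq4"]),
    df = df, n = n, mask = m, grid = maps$grid, affine = maps$affine,
    with_covariates = with_covariates
  ), class = "path_coefs")
}

# Columns of Y scaled by per-column coefficients (Y[, v] * beta[v]).
St_scale <- function(Y, beta) Y * rep(beta, each = nrow(Y))

#' @export
print.path_coefs <- function(x, ...) {
  cat("path_coefs:", sum(x$mask), "in-mask voxels,", x$n, "subjects; ",
      "total effect c =", signif(x$c, 4), "\n")
  invisible(x)
}

#' Product-of-coefficients indirect effects
#'
#' From fitted path coefficients: the indirect effect through structure
#' (`a*f`), through function (`d*e`), through structure and function in
#' series (`a*b*e`), the direct effect (`c'`) and the scalar total effect
#' (`c`). For OLS fits with identical covariate sets in every equation the
#' decomposition `c = c' + a*f + d*e + a*b*e` holds exactly at every voxel.
#'
#' @param coef a `path_coefs` object from [fit_voxelwise_mediation()].
#' @return object of class `effect_maps` with per-voxel vectors `ind_S`,
#'   `ind_F`, `ind_SF`, `direct`, scalar `total`, plus mask/grid/affine.
#' @export
compute_indirect_effects <- function(coef) {
  structure(list(
    ind_S = coef$a * coef$f,
    ind_F = coef$d * coef$e,
    ind_SF = coef$a * coef$b * coef$e,
    direct = coef$c_prime,
    total = coef$c,
    mask = coef$mask, grid = coef$grid, affine = coef$affine
  ), class = "effect_maps")
}

#' Indirect effects as a signed percentage of the total effect
#'
#' `100 * indirect / total` per pathway and voxel. The sign is kept: a
#' negative value marks inconsistent mediation (suppression), where the
#' indirect effect opposes the total effect.
#'
#' @param effects an `effect_maps` object.
#' @return list with vectors `ind_S`, `ind_F`, `ind_SF` of signed percentages
#'   (in-mask voxels).
#' @export
percent_indirect <- function(effects) {
  if (!is.finite(effects$total) || effects$total == 0) {
    stop("total effect is zero; %IND undefined")
  }
  lapply(effects[c("ind_S", "ind_F", "ind_SF")],
         function(x) 100 * x / effects$total)
}

pathway_names <- c("ind_S", "ind_F", "ind_SF")
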