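#' Max-statistic permutation test with TFCE for the indirect-effect maps
#'
#' Family-wise-error-corrected inference on the three voxel-wise indirect
#' effects (a*f, d*e, a*b*e) by the 'single threshold' (max-statistic)
#' permutation test. For each permutation the group labels are randomly
#' shuffled, the full mediation model is refit at every in-mask voxel, and
#' the maximum TFCE-enhanced statistic over the mask is recorded per tail;
#' the corrected p value at a voxel is `(count of null maxima >= observed
#' + 1) / (m + 1)` on the voxel's tail, counting ties as exceedances.
#'
#' By default (`statistic = "zperm"`) each indirect-effect estimate is
#' z-standardized per voxel with the mean and SD of its permutation
#' distribution before enhancement, so that products of coefficients with
#' voxel-varying scale become comparable across voxels. The moments include
#' the observed statistic alongside the `m` permutations — a symmetric
#' function of the whole relabeling set, which keeps the enhanced statistics
#' exchangeable under the null and the test level-accurate;
#' `statistic = "raw"` enhances the raw products. Two-tailed control:
#' the positive part of the statistic and of its negation are enhanced
#' separately, with one null max distribution per tail and `alpha` split
#' evenly — a voxel is significant when its per-tail corrected p is at most
#' `alpha / 2`.
#'
#' @param maps a [brain_map_set()].
#' @param subjects aligned subject table.
#' @param mask logical analysis mask.
#' @param params [tfce_params()].
#' @param m number of permutations (the study default is 2000). Ignored when
#'   `exhaustive = TRUE`.
#' @param alpha two-tailed family-wise error level (used only to warn when
#'   `m` is too small to ever reach it).
#' @param seed master seed; permutation `r` uses a deterministic function of
#'   `(seed, r)`, so results do not depend on evaluation order.
#' @param statistic `"zperm"` (permutation-standardized z, default) or
#'   `"raw"` (raw coefficient products).
#' @param exhaustive enumerate all distinct group-label assignments instead
#'   of sampling (feasible only for small samples); corrected p is then the
#'   exact proportion of relabelings whose max statistic reaches the
#'   observed one (the identity relabeling is part of the enumeration).
#' @param pathways which indirect pathways to test (default all three).
#' @param with_covariates include sex and nWBV in every equation.
#' @return object of class `permutation_null`: `m`, `seed`, `statistic`, and
#'   per pathway (`ind_S`, `ind_F`, `ind_SF`) the observed enhanced map,
#'   per-voxel `p_corrected` (per-tail FWE-corrected), the voxel `tail`,
#'   z map, and the two null max distributions.
#' @export
permutation_test <- function(maps, subjects, mask, params = tfce_params(),
                             m = 2000, alpha = 0.05, seed = 1,
                             statistic = c("zperm", "raw"),
                             exhaustive = FALSE, pathways = pathway_names,
                             with_covariates = TRUE) {
  statistic <- match.arg(statistic)
  pathways <- match.arg(pathways, pathway_names, several.ok = TRUE)
  grid <- maps$grid
  msk <- mask_vector(mask, grid)
  if (!any(msk)) stop("analysis mask is empty")
  n <- nrow(subjects)
  stopifnot(n_subjects(maps) == n)

  # Precompute residualized data once; only the group labels change across
  # permutations, so each refit is a handful of matrix products.
  X <- design_matrix(subjects, with_covariates)
  Z <- X[, colnames(X) != "group", drop = FALSE]
  Zplus <- solve(crossprod(Z), t(Z))
  St <- residualize(maps$S[, msk, drop = FALSE], Z, Zplus)
  Ft <- residualize(maps$F[, msk, drop = FALSE], Z, Zplus)
  Pt <- drop(residualize(cbind(subjects$switch_cost), Z, Zplus))
  A <- subjects$group

  ind_of <- function(Avec) {
    At <- Avec - Z %*% (Zplus %*% Avec)
    fit <- fit_paths_core(drop(At), St, Ft, Pt, check = FALSE)
    cbind(ind_S = fit$a * fit$f, ind_F = fit$d * fit$e,
          ind_SF = fit$a * fit$b * fit$e)[, pathways, drop = FALSE]
  }
  np <- length(pathways)
  obs <- ind_of(A)

  if (exhaustive) {
    n_old <- sum(A == 1)
    n_comb <- choose(n, n_old)
    if (n_comb > 50000) {
      stop("exhaustive enumeration infeasible: ", n_comb, " relabelings")
    }
    combs <- utils::combn(n, n_old)
    m_eff <- ncol(combs)
    perm_A <- function(r) {
      av <- numeric(n); av[combs[, r]] <- 1; av
    }
  } else {
    m_eff <- as.integer(m)
    stopifnot(m_eff >= 1)
    if (1 / (m_eff + 1) > alpha / 2) {
      warning("m = ", m_eff, " is too small for any voxel to reach the ",
              "per-tail level alpha/2 = ", alpha / 2,
              " (p-value floor is ", signif(1 / (m_eff + 1), 3), ")")
    }
    perm_A <- function(r) {
      ord <- with_seed(perm_seed(seed, r), sample.int(n))
      A[ord]
    }
  }

  Vm <- sum(msk)
  # Pass 1: standardization moments per voxel and pathway. The moments must
  # be a symmetric function of the full set of relabelings {observed,
  # permutations}, otherwise the permuted values are shrunk by their own
  # leave-in contribution while the observed is not, the m + 1 enhanced
  # statistics stop being exchangeable, and the max-statistic test becomes
  # anti-conservative. Under exhaustive enumeration the identity relabeling
  # is already in the set; under random sampling the observed is added.
  s1 <- matrix(0, Vm, np); s2 <- matrix(0, Vm, np)
  for (r in seq_len(m_eff)) {
    ip <- ind_of(perm_A(r))
    s1 <- s1 + ip
    s2 <- s2 + ip^2
  }
  if (!exhaustive) {
    s1 <- s1 + obs
    s2 <- s2 + obs^2
  }
  n_mom <- if (exhaustive) m_eff else m_eff + 1
  mu <- s1 / n_mom
  sdv <- sqrt(pmax(0, (s2 - n_mom * mu^2) / max(n_mom - 1, 1)))

  standardize <- function(ind) {
    if (statistic == "raw") return(ind)
    z <- (ind - mu) / sdv
    z[!is.finite(z)] <- 0
    z[sdv < 1e-12 * pmax(abs(mu), 1)] <- 0
    z
  }
  z_obs <- standardize(obs)

  full_map <- function(vals) {
    x <- numeric(prod(grid)); x[msk] <- vals; x
  }
  enhance <- function(zcol) {
    list(pos = tfce_transform(full_map(pmax(zcol, 0)), msk, params, grid)[msk],
         neg = tfce_transform(full_map(pmax(-zcol, 0)), msk, params, grid)[msk])
  }
  obs_enh <- apply(z_obs, 2, enhance, simplify = FALSE)

  # Pass 2: null max distributions (regenerating the same permutations).
  max_pos <- matrix(0, m_eff, np, dimnames = list(NULL, pathways))
  max_neg <- max_pos
  for (r in seq_len(m_eff)) {
    zp <- standardize(ind_of(perm_A(r)))
    for (k in seq_len(np)) {
      en <- enhance(zp[, k])
      max_pos[r, k] <- max(0, en$pos)
      max_neg[r, k] <- max(0, en$neg)
    }
  }

  denom <- if (exhaustive) m_eff else m_eff + 1
  add <- if (exhaustive) 0 else 1
  # Ties count as exceedances; the comparison carries a small relative
  # tolerance so that mathematically tied enhanced statistics (e.g. a
  # relabeling whose maps mirror the observed ones) are counted as ties
  # regardless of floating-point evaluation order.
  tie_ge <- function(null_max, obs_val) {
    sum(null_max >= obs_val - 1e-9 * max(obs_val, 1))
  }
  path_res <- lapply(seq_len(np), function(k) {
    tail <- sign(z_obs[, k])
    tpos <- obs_enh[[k]]$pos
    tneg <- obs_enh[[k]]$neg
    p <- numeric(Vm)
    for (v in seq_len(Vm)) {
      p[v] <- if (tail[v] > 0) {
        (tie_ge(max_pos[, k], tpos[v]) + add) / denom
      } else if (tail[v] < 0) {
        (tie_ge(max_neg[, k], tneg[v]) + add) / denom
      } else 1
    }
    list(p_corrected = p, tail = tail, z = z_obs[, k],
         tfce_pos = tpos, tfce_neg = tneg,
         max_null_pos = max_pos[, k], max_null_neg = max_neg[, k])
  })
  names(path_res) <- pathways

  structure(list(m = m_eff, seed = seed, statistic = statistic,
                 exhaustive = exhaustive, alpha = alpha, params = params,
                 pathways = path_res, mask = msk, grid = grid,
                 affine = maps$affine),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("permutation_null:", x$m,
      if (x$exhaustive) "exhaustive relabelings," else "permutations,",
      "statistic =", x$statistic, "\n")
  for (k in names(x$pathways)) {
    cat("  ", k, ": min corrected p =",
        signif(min(x$pathways[[k]]$p_corrected), 3), "\n")
  }
  invisible(x)
}

#' Threshold corrected p maps and apply the %IND magnitude filter
#'
#' A voxel is significant when its per-tail FWE-corrected p is at most
#' `alpha / 2` (two-tailed control at level `alpha`) and the magnitude of its
#' indirect effect is at least `pct_threshold` percent of the total effect.
#'
#' @param perm a `permutation_null` from [permutation_test()].
#' @param effects the matching `effect_maps` from
#'   [compute_indirect_effects()].
#' @param alpha two-tailed family-wise error level (default 0.05).
#' @param pct_threshold minimum `|%IND|` in percent (default 5; set 0 to
#'   disable the effect-size screen).
#' @return object of class `significance_result`: per pathway a logical
#'   significance vector over in-mask voxels, the effect `direction`
#'   (sign), plus alpha, threshold, mask, grid, affine.
#' @export
threshold_results <- function(perm, effects, alpha = 0.05,
                              pct_threshold = 5) {
  stopifnot(identical(perm$mask, effects$mask))
  pct <- if (pct_threshold > 0) percent_indirect(effects) else NULL
  pw_names <- names(perm$pathways)
  pathways <- lapply(pw_names, function(k) {
    p <- perm$pathways[[k]]$p_corrected
    sig <- p <= alpha / 2
    if (!is.null(pct)) sig <- sig & abs(pct[[k]]) >= pct_threshold
    list(sig = sig, direction = sign(effects[[k]]))
  })
  names(pathways) <- pw_names
  structure(list(pathways = pathways, alpha = alpha,
                 pct_threshold = pct_threshold, mask = perm$mask,
                 grid = perm$grid, affine = perm$affine),
            class = "significance_result")
}

#' Significant-voxel mask for one pathway as a full-grid logical vector
#'
#' @param sig a `significance_result`.
#' @param pathway one of `"ind_S"`, `"ind_F"`, `"ind_SF"`.
#' @return logical vector of length `prod(grid)`.
#' @export
significance_mask <- function(sig, pathway = names(sig$pathways)) {
  pathway <- match.arg(pathway, names(sig$pathways))
  out <- logical(prod(sig$grid))
  out[sig$mask] <- sig$pathways[[pathway]]$sig
  out
}

#' Exclusive masking: remove voxels already claimed by a reference result
#'
#' Set difference of two significance masks on the same grid: the target map
#' minus its intersection with the reference map. Used to report a simpler
#' pathway only where the serial pathway is not already significant.
#'
#' @param target,reference logical vectors/arrays on the same grid.
#' @return logical vector, `target & !reference`.
#' @export
exclusive_mask <- function(target, reference) {
  stopifnot(length(target) == length(reference))
  as.logical(target) & !as.logical(reference)
}

#' Write permutation-inference outputs
#'
#' Corrected p maps and z maps per pathway as NIfTI-1 (full-grid volumes,
#' 1 / zero outside the mask respectively), significance masks as uint8
#' NIfTI-1, and the null max-statistic distributions as tab-separated text
#' for audit.
#'
#' @param perm a `permutation_null`.
#' @param sig optional `significance_result` (writes masks when given).
#' @param prefix output path prefix.
#' @export
write_inference <- function(perm, sig = NULL, prefix) {
  g <- perm$grid
  for (k in names(perm$pathways)) {
    pw <- perm$pathways[[k]]
    pmap <- rep(1, prod(g)); pmap[perm$mask] <- pw$p_corrected
    zmap <- numeric(prod(g)); zmap[perm$mask] <- pw$z
    write_volume(pmap, g, perm$affine, paste0(prefix, "_", k, "_pcorr.nii"))
    write_volume(zmap, g, perm$affine, paste0(prefix, "_", k, "_z.nii"))
    if (!is.null(sig)) {
      write_volume(significance_mask(sig, k), g, perm$affine,
                   paste0(prefix, "_", k, "_sig.nii"))
    }
  }
  nulls <- do.call(cbind, lapply(names(perm$pathways), function(k) {
    cbind(perm$pathways[[k]]$max_null_pos, perm$pathways[[k]]$max_null_neg)
  }))
  colnames(nulls) <- as.vector(outer(c("max_pos_", "max_neg_"),
                                     names(perm$pathways),
                                     function(a, b) paste0(a, b)))
  utils::write.table(data.frame(perm = seq_len(perm$m), nulls),
                     paste0(prefix, "_null_max.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
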