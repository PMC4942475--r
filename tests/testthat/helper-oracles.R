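# Independent brute-force oracles, deliberately naive: per-voxel lm() fits,
# R-level flood-fill connected components, and threshold-loop TFCE. These
# never share code with the package internals they check.

# Per-voxel mediation fit via lm(); returns coefficient vectors like
# fit_voxelwise_mediation but computed one voxel at a time.
oracle_mediation_fit <- function(maps, subjects, mask,
                                 with_covariates = TRUE) {
  vox <- which(as.logical(mask))
  zsc <- function(x) (x - mean(x)) / sd(x)
  df0 <- data.frame(A = subjects$group, P = subjects$switch_cost)
  covs <- ""
  if (with_covariates) {
    df0$sexz <- zsc(subjects$sex)
    df0$nwbvz <- zsc(subjects$nwbv)
    covs <- " + sexz + nwbvz"
  }
  c_total <- coef(lm(as.formula(paste("P ~ A", covs)), df0))[["A"]]
  out <- sapply(vox, function(v) {
    d <- df0
    d$S <- maps$S[, v]
    d$F <- maps$F[, v]
    m2 <- lm(as.formula(paste("S ~ A", covs)), d)
    m3 <- lm(as.formula(paste("F ~ S + A", covs)), d)
    m4 <- lm(as.formula(paste("P ~ F + S + A", covs)), d)
    c(a = coef(m2)[["A"]], b = coef(m3)[["S"]], d = coef(m3)[["A"]],
      e = coef(m4)[["F"]], f = coef(m4)[["S"]], c_prime = coef(m4)[["A"]])
  })
  list(a = out["a", ], b = out["b", ], d = out["d", ], e = out["e", ],
       f = out["f", ], c_prime = out["c_prime", ], c = c_total)
}

# Flood-fill components of a logical 3D array, pure R.
oracle_components <- function(mask3d, connectivity = 26) {
  d <- dim(mask3d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  manh <- rowSums(abs(offs))
  offs <- offs[manh > 0 & manh <= c("6" = 1, "18" = 2,
                                    "26" = 3)[as.character(connectivity)], ,
               drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  for (v in which(mask3d)) {
    if (lab[v] > 0L) next
    nxt <- nxt + 1L
    queue <- v
    lab[v] <- nxt
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      uijk <- arrayInd(u, d)
      for (r in seq_len(nrow(offs))) {
        w <- uijk + offs[r, ]
        if (any(w < 1) || any(w > d)) next
        wl <- w[1] + d[1] * ((w[2] - 1) + d[2] * (w[3] - 1))
        if (mask3d[wl] && lab[wl] == 0L) {
          lab[wl] <- nxt
          queue <- c(queue, wl)
        }
      }
    }
  }
  lab
}

# Components via igraph on the voxel adjacency graph: a second independent
# route, fast enough for the exhaustive-enumeration oracle.
oracle_components_igraph <- function(mask3d, connectivity = 26) {
  d <- dim(mask3d)
  V <- prod(d)
  idx <- which(mask3d)
  if (length(idx) == 0) return(array(0L, d))
  ijk <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  manh <- rowSums(abs(offs))
  offs <- offs[manh > 0 & manh <= c("6" = 1, "18" = 2,
                                    "26" = 3)[as.character(connectivity)], ,
               drop = FALSE]
  edges <- NULL
  pos <- integer(V)
  pos[idx] <- seq_along(idx)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + d[1] * ((nb[ok, 2] - 1) + d[2] * (nb[ok, 3] - 1))
    hit <- mask3d[lin]
    edges <- rbind(edges, cbind(pos[idx[ok]][hit], pos[lin[hit]]))
  }
  lab <- array(0L, d)
  if (is.null(edges) || nrow(edges) == 0) {
    lab[idx] <- seq_along(idx)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(unique(t(apply(edges, 1, sort))),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Naive TFCE: explicit loop over thresholds h = dh, 2dh, ... <= max,
# components from a pluggable labeling routine.
oracle_tfce <- function(x3d, mask3d = NULL, E = 0.5, H = 2, dh = NULL,
                        n_steps = 100, connectivity = 26,
                        components = oracle_components) {
  d <- dim(x3d)
  if (is.null(mask3d)) mask3d <- array(TRUE, d)
  x <- ifelse(mask3d & x3d > 0, x3d, 0)
  mx <- max(x)
  out <- array(0, d)
  if (mx <= 0) return(out)
  from_max <- is.null(dh)
  if (from_max) dh <- mx / n_steps
  k <- 1
  repeat {
    # thresholds as multiples (h = mx * k / n_steps when derived from the
    # map maximum), matching the package's stepping exactly
    h <- if (from_max) {
      if (k == n_steps) mx else mx * k / n_steps # top step pinned to the max
    } else dh * k
    if (if (from_max) k > n_steps else h > mx) break
    lab <- components(array(x >= h, d), connectivity)
    sizes <- tabulate(lab)
    act <- lab > 0
    out[act] <- out[act] + sizes[lab[act]]^E * h^H * dh
    k <- k + 1
  }
  out
}

# Small synthetic dataset for fast tests.
quick_dataset <- function(n_young = 10, n_old = 14, grid = c(6, 6, 6),
                          seed = 1, regions = NULL, ...) {
  spec <- if (is.null(regions)) {
    synthetic_spec(n_young = n_young, n_old = n_old, grid_shape = grid, ...)
  } else {
    synthetic_spec(n_young = n_young, n_old = n_old, grid_shape = grid,
                   signal_regions = regions, ...)
  }
  generate_dataset(spec, seed = seed)
}
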