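# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-permutation seed derived from (master seed, index r);
# results are independent of evaluation order. Kept below 2^31.
perm_seed <- function(seed, r) {
  (as.numeric(seed) * 48271 + as.numeric(r) * 16807) %% 2147483647
}

# Reshape a voxel vector to a 3D array on the grid.
as_volume <- function(x, grid) {
  stopifnot(length(x) == prod(grid))
  array(x, dim = grid)
}

# Coerce a mask given as 3D array or vector to a logical vector of length V.
mask_vector <- function(mask, grid) {
  m <- as.logical(mask)
  stopifnot(length(m) == prod(grid))
  m & !is.na(m)
}

# 0-based voxel indices (one row per voxel) for linear indices on the grid.
voxel_ijk <- function(lin_idx, grid) {
  i0 <- lin_idx - 1L
  cbind(i = i0 %% grid[1],
        j = (i0 %/% grid[1]) %% grid[2],
        k = i0 %/% (grid[1] * grid[2]))
}

# Map 0-based voxel indices to mm coordinates via the 4x4 affine.
ijk_to_mm <- function(ijk, affine) {
  ijk <- rbind(ijk) # ensure matrix
  mm <- cbind(ijk, 1) %*% t(affine)
  mm[, 1:3, drop = FALSE]
}

# Default RAS affine for an isotropic grid centered at the origin.
default_affine <- function(grid, voxel_size = 2) {
  aff <- diag(c(rep(voxel_size, 3), 1))
  aff[1:3, 4] <- -voxel_size * (grid - 1) / 2
  aff
}
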