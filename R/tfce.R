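#' TFCE parameters
#'
#' Settings for threshold-free cluster enhancement. The defaults (E = 0.5,
#' H = 2, step = map maximum / 100, 26-connectivity) are the method's
#' standard settings for volumetric data.
#'
#' @param E extent exponent (>= 0).
#' @param H height exponent (>= 0).
#' @param dh integration step. `NULL` (default) uses `max(map) / n_steps`
#'   per map; a positive number is used as an absolute step.
#' @param n_steps number of integration steps when `dh` is `NULL`.
#' @param connectivity 6, 18 or 26 neighbors.
#' @return list of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, n_steps = 100,
                        connectivity = 26) {
  stopifnot(E >= 0, H >= 0, is.null(dh) || dh > 0, n_steps >= 1,
            connectivity %in% c(6, 18, 26))
  structure(list(E = E, H = H, dh = dh, n_steps = n_steps,
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' Integrates, over height thresholds `h = dh, 2dh, ...` up to the map
#' maximum, each voxel's cluster extent`^E` times `h^H` times `dh`, where
#' the cluster is the connected component containing the voxel in the
#' supra-threshold set at height `h`. This gives cluster-like sensitivity
#' without choosing a cluster-forming threshold. The input is treated as
#' one-signed: only positive values are enhanced; run the negated map for
#' the negative tail.
#'
#' @param stat_map numeric 3D array or vector of length `prod(grid)`.
#' @param mask logical mask (3D array or vector); enhancement is restricted
#'   to, and zero outside, the mask.
#' @param params a [tfce_params()] object.
#' @param grid volume dimensions; taken from `dim(stat_map)` when absent.
#' @return numeric vector of enhanced values, length `prod(grid)`.
#' @export
tfce_transform <- function(stat_map, mask = NULL, params = tfce_params(),
                           grid = dim(stat_map)) {
  if (is.null(grid) || length(grid) != 3L) {
    stop("supply a 3D array or an explicit `grid`")
  }
  x <- as.numeric(stat_map)
  if (is.null(mask)) mask <- rep(TRUE, prod(grid))
  m <- mask_vector(mask, grid)
  if (is.null(params$dh)) {
    # step derived from the map maximum: exactly n_steps thresholds
    .tfce_cpp(x, as.integer(grid), m, params$E, params$H, -1,
              as.integer(params$n_steps), params$connectivity)
  } else {
    .tfce_cpp(x, as.integer(grid), m, params$E, params$H, params$dh, 0L,
              params$connectivity)
  }
}

#' Label connected components of a 3D mask
#'
#' @param mask logical 3D array or vector.
#' @param grid volume dimensions; taken from `dim(mask)` when absent.
#' @param connectivity 6, 18 or 26.
#' @return integer vector of component labels (0 = background) with
#'   attribute `n_components`.
#' @export
label_components <- function(mask, grid = dim(mask), connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26), length(grid) == 3L)
  .label_components_cpp(mask_vector(mask, grid), as.integer(grid),
                        as.integer(connectivity))
}
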