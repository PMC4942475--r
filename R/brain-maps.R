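#' Per-subject structural and functional brain map set
#'
#' Container for the voxel-wise inputs of the mediation model: per-subject
#' gray-matter volume maps (structure, S) and task-activation contrast maps
#' (function, F) on a shared grid with a common voxel-to-mm affine, plus a
#' gray-matter probability map used for masking. Maps are stored
#' subjects-by-voxels so that mass-univariate fits are plain matrix algebra.
#'
#' @param S,F numeric matrices, subjects x voxels (`prod(grid)` columns), or
#'   4D arrays with subject as the 4th dimension.
#' @param grid integer vector of length 3, the volume dimensions.
#' @param affine 4x4 voxel-to-mm transform (0-based voxel indices).
#' @param gm_prob gray-matter probability per voxel in `[0, 1]`, as a vector
#'   of length `prod(grid)` or a 3D array.
#' @return An object of class `brain_map_set`.
#' @export
brain_map_set <- function(S, F, grid, affine = default_affine(grid),
                          gm_prob = rep(1, prod(grid))) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(dim(affine) == c(4, 4)))
  to_mat <- function(x) {
    if (length(dim(x)) == 4L) {
      stopifnot(all(dim(x)[1:3] == grid))
      t(matrix(x, prod(grid), dim(x)[4]))
    } else as.matrix(x)
  }
  S <- unname(to_mat(S)); F <- unname(to_mat(F))
  stopifnot(ncol(S) == prod(grid), all(dim(S) == dim(F)))
  gm_prob <- as.numeric(gm_prob)
  stopifnot(length(gm_prob) == prod(grid))
  structure(list(S = S, F = F, grid = grid, affine = affine,
                 gm_prob = gm_prob),
            class = "brain_map_set")
}

#' @export
print.brain_map_set <- function(x, ...) {
  cat("brain_map_set:", nrow(x$S), "subjects on a",
      paste(x$grid, collapse = " x "), "grid\n")
  invisible(x)
}

n_subjects <- function(maps) nrow(maps$S)

#' Read and write brain map sets as NIfTI-1
#'
#' Subject maps travel as 4D NIfTI (subject-stacked); the gray-matter
#' probability map as 3D NIfTI. `write_brain_maps` writes `<prefix>_S.nii`,
#' `<prefix>_F.nii` and `<prefix>_gmprob.nii`; `read_brain_maps` reads them
#' back.
#'
#' @param maps a [brain_map_set()].
#' @param prefix file path prefix.
#' @return `read_brain_maps` returns a `brain_map_set`; `write_brain_maps`
#'   returns the prefix invisibly.
#' @name brain_maps_io
#' @export
write_brain_maps <- function(maps, prefix) {
  g <- maps$grid
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    img <- RNifti::`sform<-`(img, structure(maps$affine, code = 2L))
    RNifti::writeNifti(img, path)
  }
  wr(array(t(maps$S), dim = c(g, nrow(maps$S))), paste0(prefix, "_S.nii"))
  wr(array(t(maps$F), dim = c(g, nrow(maps$F))), paste0(prefix, "_F.nii"))
  wr(as_volume(maps$gm_prob, g), paste0(prefix, "_gmprob.nii"))
  invisible(prefix)
}

#' @rdname brain_maps_io
#' @export
read_brain_maps <- function(prefix) {
  S <- RNifti::readNifti(paste0(prefix, "_S.nii"))
  F <- RNifti::readNifti(paste0(prefix, "_F.nii"))
  gm <- RNifti::readNifti(paste0(prefix, "_gmprob.nii"))
  grid <- dim(S)[1:3]
  affine <- RNifti::xform(S)
  attributes(affine) <- list(dim = c(4L, 4L))
  brain_map_set(S = array(S, dim(S)), F = array(F, dim(F)), grid = grid,
                affine = affine, gm_prob = as.numeric(gm))
}

#' Write a voxel map (statistic, p-value, or mask) as 3D NIfTI-1
#'
#' @param x numeric or logical vector of length `prod(grid)`, or 3D array.
#' @param grid volume dimensions.
#' @param affine 4x4 voxel-to-mm transform.
#' @param path output file.
#' @param datatype NIfTI datatype; masks are written as `"uint8"`.
#' @export
write_volume <- function(x, grid, affine, path,
                         datatype = if (is.logical(x)) "uint8" else "double") {
  arr <- as_volume(as.numeric(x), grid)
  img <- RNifti::asNifti(arr, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
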