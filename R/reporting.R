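#' Cluster table from a significance map
#'
#' Connected components of the significant voxels, with peak coordinates in
#' mm, cluster extent k, the per-group and between-group activation t values
#' at each peak, and the signed %IND at the peak. Within a cluster, local
#' maxima of `|stat_map|` are reported (primary peak first); a local maximum
#' is a voxel strictly greater than all its in-cluster neighbors, ties broken
#' by lowest linear index. Sub-peaks closer than `peak_sep_mm` to an already
#' accepted peak are dropped. Rows are sorted by cluster size descending,
#' ties by peak `|stat|` descending; sub-peak rows carry `NA` extent.
#'
#' @param sig a `significance_result` from [threshold_results()].
#' @param pathway which indirect pathway to tabulate.
#' @param stat_map per-voxel statistic used for peak ranking, as a full-grid
#'   vector/array (e.g. the TFCE or z map); defaults to the pathway z map
#'   when `perm` is given.
#' @param activation a `group_activation` from [group_activation_tests()].
#' @param effects the `effect_maps` (for %IND at the peak).
#' @param perm optional `permutation_null` supplying the default `stat_map`.
#' @param connectivity component connectivity (default 26).
#' @param peak_sep_mm minimum separation between reported peaks of one
#'   cluster, in mm (default 8).
#' @param max_peaks maximum peaks reported per cluster (default 3).
#' @return data.frame of class `cluster_table` with columns `pathway`,
#'   `cluster`, `x`, `y`, `z`, `k`, `t_young`, `t_old`, `t_old_gt_young`,
#'   `pct_ind`.
#' @export
extract_clusters <- function(sig, pathway = pathway_names, stat_map = NULL,
                             activation = NULL, effects = NULL, perm = NULL,
                             connectivity = 26, peak_sep_mm = 8,
                             max_peaks = 3) {
  pathway <- match.arg(pathway)
  grid <- sig$grid
  smask <- significance_mask(sig, pathway)
  empty <- data.frame(pathway = character(), cluster = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      k = integer(), t_young = numeric(), t_old = numeric(),
                      t_old_gt_young = numeric(), pct_ind = numeric())
  class(empty) <- c("cluster_table", "data.frame")
  if (!any(smask)) return(empty)

  if (is.null(stat_map)) {
    if (is.null(perm)) stop("supply stat_map or perm")
    stat_map <- numeric(prod(grid))
    stat_map[perm$mask] <- perm$pathways[[pathway]]$z
  }
  stat <- abs(as.numeric(stat_map))
  pct_full <- rep(NA_real_, prod(grid))
  if (!is.null(effects)) {
    pct_full[sig$mask] <- percent_indirect(effects)[[pathway]]
  }

  labels <- label_components(smask, grid, connectivity)
  n_comp <- attr(labels, "n_components")
  nb <- neighbor_index_offsets(grid, connectivity)

  rows <- list()
  for (cl in seq_len(n_comp)) {
    vox <- which(labels == cl)
    k <- length(vox)
    peaks <- local_maxima(vox, stat, labels, cl, grid, nb)
    # order candidate peaks by value desc, then lowest linear index
    peaks <- peaks[order(-stat[peaks], peaks)]
    mm_all <- ijk_to_mm(voxel_ijk(peaks, grid), sig$affine)
    keep <- integer()
    for (i in seq_along(peaks)) {
      if (length(keep) >= max_peaks) break
      if (length(keep) == 0L) { keep <- i; next }
      dists <- sqrt(colSums((t(mm_all[keep, , drop = FALSE]) - mm_all[i, ])^2))
      if (all(dists >= peak_sep_mm)) keep <- c(keep, i)
    }
    peaks <- peaks[keep]
    mm <- mm_all[keep, , drop = FALSE]
    rows[[cl]] <- data.frame(
      pathway = pathway, cluster = cl,
      x = mm[, 1], y = mm[, 2], z = mm[, 3],
      k = c(k, rep(NA_integer_, length(peaks) - 1L)),
      t_young = if (is.null(activation)) NA_real_ else activation$t_young[peaks],
      t_old = if (is.null(activation)) NA_real_ else activation$t_old[peaks],
      t_old_gt_young = if (is.null(activation)) NA_real_ else
        activation$t_old_gt_young[peaks],
      pct_ind = pct_full[peaks],
      peak_stat = stat[peaks], size = k
    )
  }
  tab <- do.call(rbind, rows)
  # sort clusters by size desc, ties by primary-peak |stat| desc
  firsts <- tab[!is.na(tab$k), c("cluster", "size", "peak_stat")]
  ord <- firsts$cluster[order(-firsts$size, -firsts$peak_stat)]
  tab <- do.call(rbind, lapply(ord, function(cl) tab[tab$cluster == cl, ]))
  tab$cluster <- rep(seq_along(ord), times = table(factor(tab$cluster,
                                                          levels = ord)))
  tab$size <- tab$peak_stat <- NULL
  rownames(tab) <- NULL
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

# Precompute linear-index neighbor offsets plus the ijk deltas needed for
# boundary checks.
neighbor_index_offsets <- function(grid, connectivity) {
  d <- expand.grid(i = -1:1, j = -1:1, k = -1:1)
  manh <- abs(d$i) + abs(d$j) + abs(d$k)
  keep <- manh > 0 & manh <= switch(as.character(connectivity),
                                    "6" = 1, "18" = 2, "26" = 3)
  d <- d[keep, ]
  list(delta = as.matrix(d),
       lin = d$i + grid[1] * (d$j + grid[2] * d$k))
}

# Voxels in `vox` strictly greater than all in-cluster neighbors.
local_maxima <- function(vox, stat, labels, cl, grid, nb) {
  ijk <- voxel_ijk(vox, grid)
  is_peak <- vapply(seq_along(vox), function(t) {
    v <- vox[t]
    for (r in seq_len(nrow(nb$delta))) {
      ni <- ijk[t, ] + nb$delta[r, ]
      if (any(ni < 0) || any(ni >= grid)) next
      w <- v + nb$lin[r]
      if (labels[w] == cl && stat[w] >= stat[v]) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- vox[is_peak]
  if (length(out) == 0L) out <- vox[which.max(stat[vox])]
  out
}

#' Write / read cluster tables
#'
#' Tab-separated text in the peak-table column order (`pathway`, `cluster`,
#' `x`, `y`, `z`, `k`, `t_young`, `t_old`, `t_old_gt_young`, `pct_ind`).
#' Sub-peak rows of a cluster carry `-` in the extent column, as in
#' conventional peak tables; the reader maps `-` back to `NA`.
#'
#' @param rows a `cluster_table`.
#' @param path destination file.
#' @name cluster_table_io
#' @export
write_cluster_table <- function(rows, path) {
  out <- as.data.frame(rows)
  out$k <- ifelse(is.na(out$k), "-", as.character(out$k))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cluster_table_io
#' @export
read_cluster_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = list(k = "character"))
  x$k <- suppressWarnings(as.integer(ifelse(x$k == "-", NA, x$k)))
  for (col in c("x", "y", "z", "t_young", "t_old", "t_old_gt_young",
                "pct_ind")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  class(x) <- c("cluster_table", "data.frame")
  x
}

#' Cluster-index map as integer labels on the full grid
#'
#' @param sig a `significance_result`.
#' @param pathway which pathway.
#' @param connectivity component connectivity.
#' @return integer vector of cluster labels (0 outside clusters).
#' @export
cluster_index_map <- function(sig, pathway = pathway_names,
                              connectivity = 26) {
  pathway <- match.arg(pathway)
  label_components(significance_mask(sig, pathway), sig$grid, connectivity)
}
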