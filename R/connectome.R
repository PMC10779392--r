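#' Canonical edge index table
#'
#' Edges are ordered by the strict upper triangle of the region-by-region
#' matrix, row-major: (1,2), (1,3), ..., (1,R), (2,3), ... This ordering
#' is the single vectorisation convention used by every edge-level
#' statistic in the package.
#'
#' @param n_regions number of regions R.
#' @return Integer matrix with columns `i`, `j` (i < j), one row per edge,
#'   R(R-1)/2 rows.
#' @export
edge_index_table <- function(n_regions) {
  if (n_regions < 2L) stop("need at least 2 regions", call. = FALSE)
  idx <- t(utils::combn(n_regions, 2L))
  colnames(idx) <- c("i", "j")
  idx
}

#' Region time-series container
#'
#' @param matrix frames x regions numeric matrix.
#' @param region_ids region labels, in region-table order.
#' @param subject subject id.
#' @param group group label (`"control"` or `"cko"`).
#' @param tr repetition time, seconds.
#' @return Object of class `region_timeseries`.
#' @export
region_timeseries <- function(matrix, region_ids, subject = "s1",
                              group = "control", tr = 1.8) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != length(region_ids))
    stop("region count (", ncol(matrix), ") does not match region_ids (",
         length(region_ids), ")", call. = FALSE)
  colnames(matrix) <- as.character(region_ids)
  structure(list(matrix = matrix, region_ids = as.character(region_ids),
                 subject = subject, group = group, tr = tr),
            class = "region_timeseries")
}

#' Extract region-averaged time series from a BOLD image
#'
#' For each atlas region, the unweighted mean of the in-region voxel
#' series per frame. Every region in the table must be present in the
#' label grid.
#'
#' @param bold a [bold_image].
#' @param labels a [volume_image] whose `data` holds non-negative integer
#'   atlas labels (0 = background) on the same spatial grid.
#' @param region_table region lookup table (see [read_region_table()]).
#' @param subject,group metadata attached to the result.
#' @return A [region_timeseries].
#' @export
extract_region_timeseries <- function(bold, labels, region_table,
                                      subject = "s1", group = "control") {
  db <- dim(bold$data)
  dl <- dim(labels$data)
  if (!all(db[1:3] == dl))
    stop("BOLD spatial grid (", paste(db[1:3], collapse = "x"),
         ") does not match label grid (", paste(dl, collapse = "x"), ")",
         call. = FALSE)
  lab <- as.integer(labels$data)
  n_frames <- db[4L]
  vox_by_time <- matrix(bold$data, nrow = prod(db[1:3]), ncol = n_frames)
  ids <- region_table$label
  counts <- tabulate(lab, nbins = max(ids))
  missing <- ids[counts[ids] == 0L]
  if (length(missing))
    stop("region(s) with zero voxels in the label grid: ",
         paste(missing, collapse = ", "), call. = FALSE)
  keep <- lab > 0L
  sums <- rowsum(vox_by_time[keep, , drop = FALSE], group = lab[keep])
  sums <- sums[as.character(ids), , drop = FALSE]
  series <- t(sums / counts[ids])
  region_timeseries(series, region_ids = ids, subject = subject,
                    group = group, tr = bold$tr)
}

#' Compute a subject's functional connectome
#'
#' The connectome is the matrix of Pearson correlations between the BOLD
#' series of all region pairs. Requires at least 3 frames and no
#' constant-in-time region series.
#'
#' @param rts a [region_timeseries].
#' @return Object of class `connectome` with elements `matrix`
#'   (symmetric, unit diagonal), `region_ids`, `subject`, `group`.
#' @export
compute_connectome <- function(rts) {
  m <- rts$matrix
  if (nrow(m) < 3L)
    stop("need at least 3 frames to correlate, found ", nrow(m),
         call. = FALSE)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant time series for region(s): ",
         paste(rts$region_ids[sds == 0], collapse = ", "), call. = FALSE)
  cc <- stats::cor(m)
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  dimnames(cc) <- list(rts$region_ids, rts$region_ids)
  structure(list(matrix = cc, region_ids = rts$region_ids,
                 subject = rts$subject, group = rts$group),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> subject ", x$subject, " (", x$group, "), ",
      length(x$region_ids), " regions, ",
      length(x$region_ids) * (length(x$region_ids) - 1) / 2, " edges\n",
      sep = "")
  invisible(x)
}

edge_hemisphere_class <- function(idx, hemispheres) {
  hi <- hemispheres[idx[, "i"]]
  hj <- hemispheres[idx[, "j"]]
  ifelse(hi != hj, "inter-hemisphere",
         ifelse(hi == "left", "intra-left", "intra-right"))
}

#' Vectorise a connectome into its canonical edge vector
#'
#' @param conn a `connectome` (or a bare symmetric matrix).
#' @param region_table optional region table supplying hemispheres; when
#'   given, each edge is classed as intra-left, intra-right or
#'   inter-hemisphere.
#' @return A data.frame with columns `edge`, `i`, `j`, `region_i`,
#'   `region_j`, `value`, and `class` when hemispheres are known.
#' @export
vectorize_edges <- function(conn, region_table = NULL) {
  m <- if (inherits(conn, "connectome")) conn$matrix else as.matrix(conn)
  ids <- if (inherits(conn, "connectome")) conn$region_ids
         else as.character(seq_len(nrow(m)))
  idx <- edge_index_table(nrow(m))
  out <- data.frame(edge = seq_len(nrow(idx)),
                    i = idx[, "i"], j = idx[, "j"],
                    region_i = ids[idx[, "i"]],
                    region_j = ids[idx[, "j"]],
                    value = m[idx], stringsAsFactors = FALSE)
  if (!is.null(region_table)) {
    hemi <- region_table$hemisphere[match(ids, region_table$label)]
    out$class <- edge_hemisphere_class(idx, hemi)
  }
  out
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_edges()]; the diagonal is set to 1.
#'
#' @param values edge values in canonical order.
#' @param n_regions number of regions.
#' @return A symmetric matrix with unit diagonal.
#' @export
devectorize_edges <- function(values, n_regions) {
  idx <- edge_index_table(n_regions)
  if (length(values) != nrow(idx))
    stop("expected ", nrow(idx), " edge values, found ", length(values),
         call. = FALSE)
  m <- diag(n_regions)
  m[idx] <- values
  m[idx[, c(2L, 1L)]] <- values
  m
}

#' Edge-wise similarity of two connectomes
#'
#' Pearson correlation across the canonical edge vectors of two
#' connectomes on the same region ordering, with the t-transform p-value
#' at df = E - 2 where E is the edge count.
#'
#' @param c1,c2 `connectome` objects (or symmetric matrices).
#' @return List with `r`, `r_squared`, `p`, `n_edges`.
#' @export
connectome_similarity <- function(c1, c2) {
  v1 <- vectorize_edges(c1)$value
  v2 <- vectorize_edges(c2)$value
  if (length(v1) != length(v2))
    stop("connectomes have different region counts", call. = FALSE)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero-variance edge vector", call. = FALSE)
  ct <- stats::cor.test(v1, v2)
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n_edges = length(v1))
}
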