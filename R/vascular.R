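#' Segment vessels by intensity threshold
#'
#' A voxel is lumen when its intensity strictly exceeds the threshold
#' (boundary voxels at exactly the threshold are excluded). The study
#' thresholds are 7000, 7500 and 8000 intensity units.
#'
#' @param angio a [volume_image] angiogram.
#' @param threshold intensity threshold.
#' @return List with `mask` (logical array) and `volume_mm3`
#'   (voxel count times voxel volume).
#' @export
segment_vessels <- function(angio, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite",
                                  call. = FALSE)
  mask <- angio$data > threshold
  list(mask = mask, volume_mm3 = sum(mask) * prod(angio$voxel_dims))
}

#' Maximum intensity projection along one axis
#'
#' @param angio a [volume_image].
#' @param axis `"X"`, `"Y"` or `"Z"` (or 1:3).
#' @return 2D matrix of per-pixel maxima over the projected axis.
#' @export
mip <- function(angio, axis) {
  if (is.character(axis)) axis <- match(toupper(axis), c("X", "Y", "Z"))
  if (!axis %in% 1:3) stop("axis must be X, Y or Z", call. = FALSE)
  apply(angio$data, setdiff(1:3, axis), max)
}

#' Suprathreshold area of a maximum intensity projection
#'
#' Counts MIP pixels strictly above the threshold times the in-plane
#' pixel area (product of the two off-axis voxel dimensions).
#'
#' @inheritParams mip
#' @param threshold intensity threshold.
#' @return Area in mm2.
#' @export
mip_vessel_area <- function(angio, axis, threshold) {
  if (is.character(axis)) axis <- match(toupper(axis), c("X", "Y", "Z"))
  proj <- mip(angio, axis)
  pixel_area <- prod(angio$voxel_dims[setdiff(1:3, axis)])
  sum(proj > threshold) * pixel_area
}

#' Per-subject vascular measures over the threshold grid
#'
#' @param angio a [volume_image].
#' @param thresholds intensity thresholds (default 7000, 7500, 8000).
#' @return data.frame with, per threshold, the 3D lumen volume and the
#'   MIP suprathreshold area for each projection axis.
#' @export
vascular_measures <- function(angio, thresholds = c(7000, 7500, 8000)) {
  rows <- lapply(thresholds, function(th) {
    data.frame(threshold = th,
               volume_mm3 = segment_vessels(angio, th)$volume_mm3,
               mip_area_x_mm2 = mip_vessel_area(angio, 1L, th),
               mip_area_y_mm2 = mip_vessel_area(angio, 2L, th),
               mip_area_z_mm2 = mip_vessel_area(angio, 3L, th))
  })
  do.call(rbind, rows)
}

#' Correlation of vessel measures with brain volume
#'
#' For each (projection axis, threshold) combination, an ordinary
#' least-squares fit of the per-subject vessel measure on brain volume,
#' reporting r, R-squared, slope and the correlation p-value, plus the
#' mean and SD of R-squared across the combinations (the 3 axes x 3
#' thresholds grid gives 9). Constant vessel measures are reported as
#' undefined with a warning and excluded from the summary.
#'
#' @param measures list of per-subject data.frames from
#'   [vascular_measures()] (same threshold grid).
#' @param brain_volumes numeric vector of per-subject brain volumes, in
#'   the same subject order.
#' @return List with `by_combination` (data.frame axis, threshold, r,
#'   r_squared, slope, p) and `summary` (mean and SD of R-squared).
#' @export
vessel_brain_correlation <- function(measures, brain_volumes) {
  n <- length(measures)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (length(brain_volumes) != n)
    stop("brain_volumes length does not match subjects", call. = FALSE)
  thresholds <- measures[[1L]]$threshold
  axes <- c(x = "mip_area_x_mm2", y = "mip_area_y_mm2",
            z = "mip_area_z_mm2")
  rows <- list()
  for (ax in names(axes)) {
    for (k in seq_along(thresholds)) {
      y <- vapply(measures, function(m) m[[axes[[ax]]]][k], numeric(1))
      if (stats::sd(y) == 0) {
        warning("constant vessel measure for axis ", toupper(ax),
                ", threshold ", thresholds[k],
                "; combination excluded", call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          axis = toupper(ax), threshold = thresholds[k], r = NA_real_,
          r_squared = NA_real_, slope = NA_real_, p = NA_real_)
        next
      }
      pc <- pearson_with_p(brain_volumes, y)
      slope <- pc$estimate * stats::sd(y) / stats::sd(brain_volumes)
      rows[[length(rows) + 1L]] <- data.frame(
        axis = toupper(ax), threshold = thresholds[k], r = pc$estimate,
        r_squared = pc$estimate^2, slope = slope, p = pc$p)
    }
  }
  by_comb <- do.call(rbind, rows)
  ok <- !is.na(by_comb$r_squared)
  list(by_combination = by_comb,
       summary = list(mean_r_squared = mean(by_comb$r_squared[ok]),
                      sd_r_squared = stats::sd(by_comb$r_squared[ok]),
                      n_combinations = sum(ok)))
}
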