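#' Per-region volumes from a labelled atlas image
#'
#' Each region's volume is its voxel count times the voxel volume.
#' Ventricle-flagged regions are totalled separately and excluded from
#' the brain-tissue total. Regions present in the table but absent from
#' the grid get volume 0 with a warning.
#'
#' @param labels a [volume_image] of non-negative integer labels.
#' @param region_table region lookup table.
#' @param subject subject id attached to the rows.
#' @return List of class `volumetry`: `table` (data.frame subject,
#'   region, region_name, voxel_count, volume_mm3, ventricle),
#'   `brain_volume_mm3` (non-ventricle labelled total),
#'   `ventricle_volume_mm3`. Voxel counts conserve exactly: their sum
#'   equals the labelled voxel count of the grid.
#' @export
region_volumes <- function(labels, region_table, subject = "s1") {
  vox_vol <- prod(labels$voxel_dims)
  lab <- as.integer(labels$data)
  ids <- region_table$label
  counts <- tabulate(lab[lab > 0L], nbins = max(ids))[ids]
  counts[is.na(counts)] <- 0L
  if (any(counts == 0L))
    warning("region(s) absent from label grid, volume 0: ",
            paste(ids[counts == 0L], collapse = ", "), call. = FALSE)
  tab <- data.frame(subject = subject, region = ids,
                    region_name = region_table$region,
                    voxel_count = counts,
                    volume_mm3 = counts * vox_vol,
                    ventricle = region_table$ventricle,
                    stringsAsFactors = FALSE)
  list(table = tab,
       brain_volume_mm3 = sum(tab$volume_mm3[!tab$ventricle]),
       ventricle_volume_mm3 = sum(tab$volume_mm3[tab$ventricle]))
}

#' Normalise regional volumes
#'
#' `"total_brain"` divides each region volume by the subject's
#' non-ventricle brain volume (unitless fraction); `"body_weight"`
#' divides by body weight (mm3/g).
#'
#' @param vol a `volumetry` result from [region_volumes()].
#' @param mode `"total_brain"` or `"body_weight"`.
#' @param body_weight subject body weight in grams (required for
#'   `"body_weight"`).
#' @return The `volumetry` list with a `normalized` column added to
#'   `table` and the normalisation recorded.
#' @export
normalize_volumes <- function(vol, mode = c("total_brain", "body_weight"),
                              body_weight = NULL) {
  mode <- match.arg(mode)
  denom <- if (mode == "total_brain") {
    if (vol$brain_volume_mm3 <= 0)
      stop("non-positive brain volume for subject ",
           vol$table$subject[1L], call. = FALSE)
    vol$brain_volume_mm3
  } else {
    if (is.null(body_weight) || !is.finite(body_weight) ||
        body_weight <= 0)
      stop("missing or non-positive body weight for subject ",
           vol$table$subject[1L], call. = FALSE)
    body_weight
  }
  vol$table$normalized <- vol$table$volume_mm3 / denom
  vol$normalization <- mode
  vol
}

#' Signed percent difference between two group means
#'
#' `100 * (mean_alt - mean_ref) / mean_ref`, the convention used for
#' "cKO relative to control" summaries (e.g. group mean brain volumes
#' 475.7 and 381.4 mm3 give -19.8).
#'
#' @param mean_ref reference (control) mean; must be nonzero.
#' @param mean_alt alternative (cKO) mean.
#' @param digits decimals in the returned value (default 1, the reporting
#'   precision).
#' @return Signed percent, rounded to `digits`.
#' @export
percent_mean_difference <- function(mean_ref, mean_alt, digits = 1L) {
  if (!is.finite(mean_ref) || mean_ref == 0)
    stop("reference mean must be nonzero", call. = FALSE)
  round(100 * (mean_alt - mean_ref) / mean_ref, digits)
}

#' Per-region group comparison of volumes
#'
#' For every region (and the brain/ventricle totals), group means, the
#' percent difference of cKO relative to control, and a two-sample
#' t-test ([two_sample_ttest()]). No multiple-testing correction by
#' default; `adjust = "BH"` applies Benjamini-Hochberg across regions.
#'
#' @param volumetries list of `volumetry` results, one per subject.
#' @param meta subject metadata (see [read_subject_meta()]); grouping
#'   uses `group_column`.
#' @param use_normalized compare the `normalized` column instead of raw
#'   mm3 (requires [normalize_volumes()] first).
#' @param variance `"pooled"` (default) or `"welch"`.
#' @param adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @param group_column metadata column holding the two-level grouping
#'   (default `"group"`; use `"sex"` for sex-stratified comparisons).
#' @return data.frame with one row per region plus `total_brain` and
#'   `total_ventricle` rows: means, `percent_difference`, `t`, `df`, `p`
#'   (and `p_adj` when adjusted).
#' @export
group_volume_comparison <- function(volumetries, meta,
                                    use_normalized = FALSE,
                                    variance = c("pooled", "welch"),
                                    adjust = "none",
                                    group_column = "group") {
  variance <- match.arg(variance)
  subjects <- vapply(volumetries, function(v) v$table$subject[1L],
                     character(1))
  grp <- meta[[group_column]][match(subjects, meta$subject)]
  levels <- unique(meta[[group_column]])
  if (length(levels) != 2L)
    stop("grouping column must have exactly 2 levels", call. = FALSE)
  ref <- if ("control" %in% levels) "control" else levels[1L]
  alt <- setdiff(levels, ref)
  if (sum(grp == ref) < 2L || sum(grp == alt) < 2L)
    stop("each group needs at least 2 subjects", call. = FALSE)
  col <- if (use_normalized) "normalized" else "volume_mm3"
  if (use_normalized &&
      is.null(volumetries[[1L]]$table$normalized))
    stop("run normalize_volumes() before use_normalized = TRUE",
         call. = FALSE)
  # totals are always compared raw (a total-brain fraction is identically 1)
  values <- vapply(volumetries, function(v)
    c(v$table[[col]], v$brain_volume_mm3, v$ventricle_volume_mm3),
    numeric(nrow(volumetries[[1L]]$table) + 2L))
  rn <- c(as.character(volumetries[[1L]]$table$region),
          "total_brain", "total_ventricle")
  rows <- lapply(seq_len(nrow(values)), function(r) {
    a <- values[r, grp == ref]
    b <- values[r, grp == alt]
    tt <- if (stats::sd(a) == 0 && stats::sd(b) == 0 &&
              mean(a) == mean(b))
      list(statistic = 0, df = length(a) + length(b) - 2, p = 1)
    else two_sample_ttest(a, b, variance)
    data.frame(region = rn[r],
               mean_ref = mean(a), mean_alt = mean(b),
               percent_difference =
                 if (mean(a) != 0)
                   percent_mean_difference(mean(a), mean(b))
                 else NA_real_,
               t = tt$statistic, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_ref"] <- paste0("mean_", ref)
  names(out)[names(out) == "mean_alt"] <- paste0("mean_", alt)
  if (adjust != "none") {
    out$p_adj <- stats::p.adjust(out$p, method = adjust)
    message("p-values adjusted with method '", adjust, "'")
  }
  out
}
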