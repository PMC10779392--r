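#' Read and validate an atlas region lookup table
#'
#' The region table maps integer atlas labels to region names, hemispheres
#' and macro-regions at a given atlas scale. Required columns:
#' `label`, `region`, `hemisphere` (left/right), `macro_region`, `scale`
#' (coarse/medium). An optional logical column `ventricle` flags CSF
#' compartments excluded from brain-tissue totals.
#'
#' @param path CSV file path.
#' @return A data.frame with one row per region, ordered by label.
#' @export
read_region_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_region_table(tab)
}

#' @rdname read_region_table
#' @param tab a data.frame to validate in place of a file.
#' @export
validate_region_table <- function(tab) {
  required <- c("label", "region", "hemisphere", "macro_region", "scale")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("region table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L)
    stop("region table is empty", call. = FALSE)
  if (anyDuplicated(tab$label))
    stop("duplicated label id(s) in region table: row ",
         anyDuplicated(tab$label), call. = FALSE)
  bad_hemi <- which(!tab$hemisphere %in% c("left", "right"))
  if (length(bad_hemi))
    stop("unknown hemisphere token in region table row ", bad_hemi[1L],
         ": '", tab$hemisphere[bad_hemi[1L]], "'", call. = FALSE)
  bad_scale <- which(!tab$scale %in% c("coarse", "medium"))
  if (length(bad_scale))
    stop("unknown scale token in region table row ", bad_scale[1L],
         ": '", tab$scale[bad_scale[1L]], "'", call. = FALSE)
  if (is.null(tab$ventricle)) tab$ventricle <- FALSE
  tab$ventricle <- as.logical(tab$ventricle)
  tab[order(tab$label), , drop = FALSE]
}

#' Read and validate a subject metadata table
#'
#' Required columns: `subject` (unique id), `group` (control/cko), `sex`
#' (M/F), `body_weight` (grams, positive). An optional logical `excluded`
#' column flags subjects dropped before any pairing (e.g. unverifiable
#' genotype).
#'
#' @param path CSV file path.
#' @return A validated data.frame.
#' @export
read_subject_meta <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_subject_meta(tab)
}

#' @rdname read_subject_meta
#' @param tab a data.frame to validate in place of a file.
#' @export
validate_subject_meta <- function(tab) {
  required <- c("subject", "group", "sex", "body_weight")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("subject table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L)
    stop("subject table is empty", call. = FALSE)
  if (anyDuplicated(tab$subject))
    stop("duplicated subject id in row ", anyDuplicated(tab$subject),
         call. = FALSE)
  bad_grp <- which(!tab$group %in% c("control", "cko"))
  if (length(bad_grp))
    stop("unknown group token in subject table row ", bad_grp[1L],
         ": '", tab$group[bad_grp[1L]], "'", call. = FALSE)
  bad_sex <- which(!tab$sex %in% c("M", "F"))
  if (length(bad_sex))
    stop("unknown sex token in subject table row ", bad_sex[1L],
         call. = FALSE)
  if (any(!is.finite(tab$body_weight)) || any(tab$body_weight <= 0))
    stop("body_weight must be positive for every subject", call. = FALSE)
  if (is.null(tab$excluded)) tab$excluded <- FALSE
  tab
}

#' Write a data.frame as CSV with header
#'
#' @param rows a data.frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a square matrix as CSV with region-id headers
#'
#' Matrices (connectomes, difference matrices) are persisted as delimited
#' text with row and column headers for auditability; round-trips are
#' lossless to full double precision (17 significant digits).
#'
#' @param m numeric matrix; `dimnames` are used as headers if present.
#' @param path destination path.
#' @return `path` (write) or the matrix with dimnames (read).
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- seq_len(ncol(m))
  df <- data.frame(id = rownames(m),
                   format(m, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}
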