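#' Construct a 3D scalar volume
#'
#' A `volume_image` is the package's container for any 3D scalar grid
#' (anatomical image, angiogram, brain mask): a numeric array plus voxel
#' dimensions in millimetres. Axis convention is x = left-right,
#' y = anterior-posterior, z = dorsal-ventral, and inputs are assumed
#' pre-aligned to the atlas grid (registration is out of scope).
#'
#' @param data 3D numeric array.
#' @param voxel_dims length-3 positive numeric, mm per axis. Default
#'   0.275 mm isotropic, the functional acquisition resolution.
#' @return An object of class `volume_image` with elements `data` and
#'   `voxel_dims`.
#' @export
volume_image <- function(data, voxel_dims = c(0.275, 0.275, 0.275)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume_image requires a 3D array, found ", length(dim(data)),
         " dimensions", call. = FALSE)
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) ||
      any(voxel_dims <= 0))
    stop("voxel_dims must be 3 positive numbers (mm)", call. = FALSE)
  structure(list(data = data, voxel_dims = voxel_dims),
            class = "volume_image")
}

#' Construct a 4D BOLD image
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxel_dims length-3 positive numeric, mm.
#' @param tr repetition time in seconds (default 1.8 s).
#' @return An object of class `bold_image` with elements `data`,
#'   `voxel_dims`, `tr` and `n_frames`.
#' @export
bold_image <- function(data, voxel_dims = c(0.275, 0.275, 0.275), tr = 1.8) {
  data <- as.array(data)
  if (length(dim(data)) != 4L)
    stop("bold_image requires a 4D array (x,y,z,t), found ",
         length(dim(data)), " dimensions", call. = FALSE)
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0))
    stop("voxel_dims must be 3 positive numbers (mm)", call. = FALSE)
  if (!is.finite(tr) || tr <= 0)
    stop("tr must be a positive number of seconds", call. = FALSE)
  structure(list(data = data, voxel_dims = voxel_dims, tr = tr,
                 n_frames = dim(data)[4L]),
            class = "bold_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_dims, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.bold_image <- function(x, ...) {
  d <- dim(x$data)
  cat("<bold_image> ", paste(d[1:3], collapse = " x "), " voxels x ",
      d[4], " frames, TR ", x$tr, " s\n", sep = "")
  invisible(x)
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return A [volume_image].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, found ", length(d),
         " dimensions in ", path, call. = FALSE)
  vd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vd)) || any(vd <= 0))
    stop("non-positive voxel dimensions in ", path, call. = FALSE)
  volume_image(array(as.numeric(img), dim = d), voxel_dims = vd)
}

#' Read a 4D BOLD series from a NIfTI file
#'
#' TR is taken from the time-axis spacing in the header unless overridden;
#' when both are available and disagree the explicit value wins with a
#' warning.
#'
#' @param path path to a 4D NIfTI file.
#' @param tr optional repetition time (s) overriding the header.
#' @return A [bold_image].
#' @export
read_bold <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D BOLD image, found ", length(d),
         " dimensions in ", path, call. = FALSE)
  pd <- RNifti::pixdim(img)
  vd <- pd[1:3]
  if (any(!is.finite(vd)) || any(vd <= 0))
    stop("non-positive voxel dimensions in ", path, call. = FALSE)
  header_tr <- if (length(pd) >= 4L && is.finite(pd[4L]) && pd[4L] > 0)
    pd[4L] else NA_real_
  if (is.null(tr)) {
    if (is.na(header_tr))
      stop("no usable TR in header of ", path,
           "; supply tr explicitly", call. = FALSE)
    tr <- header_tr
  } else if (!is.na(header_tr) && abs(tr - header_tr) > 1e-6) {
    warning("TR mismatch (header ", signif(header_tr, 4), " s, config ",
            signif(tr, 4), " s); using the configured value", call. = FALSE)
  }
  bold_image(array(as.numeric(img), dim = d), voxel_dims = vd, tr = tr)
}

#' Write a volume or BOLD image to NIfTI
#'
#' @param x a [volume_image] or [bold_image].
#' @param path destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "bold_image")) {
    img <- RNifti::asNifti(x$data)
    RNifti::pixdim(img) <- c(x$voxel_dims, x$tr)
  } else if (inherits(x, "volume_image")) {
    img <- RNifti::asNifti(x$data)
    RNifti::pixdim(img) <- x$voxel_dims
  } else {
    stop("x must be a volume_image or bold_image", call. = FALSE)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}
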