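#' Apply a binary brain mask to a BOLD image
#'
#' Voxels outside the mask are zeroed and excluded from all downstream
#' statistics (global signal, smoothing normalisation). The mask is
#' attached to the returned image so later stages can honour it.
#'
#' @param bold a [bold_image].
#' @param mask a binary [volume_image] on the same spatial grid.
#' @return The masked [bold_image] with a `mask` element.
#' @export
apply_brain_mask <- function(bold, mask) {
  db <- dim(bold$data)[1:3]
  dm <- dim(mask$data)
  if (!all(db == dm))
    stop("mask grid (", paste(dm, collapse = "x"),
         ") does not match BOLD spatial grid (",
         paste(db, collapse = "x"), ")", call. = FALSE)
  mk <- mask$data != 0
  if (!any(mk)) stop("empty brain mask", call. = FALSE)
  out <- bold
  out$data <- bold$data * as.numeric(rep(mk, times = bold$n_frames))
  dim(out$data) <- dim(bold$data)
  out$mask <- mk
  out
}

# Zero-phase Butterworth band-pass of one demeaned series: reflective
# padding at both ends, forward-backward second-order-section-free
# filtering via signal::filter. Effective order is twice the design order.
filtfilt_reflect <- function(flt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  head_ref <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  tail_ref <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(head_ref, x, tail_ref)
  y <- signal::filter(flt, xp)
  y <- rev(signal::filter(flt, rev(y)))
  y[seq(pad + 1L, pad + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Removes the mean, then applies a Butterworth band-pass of the given
#' design order forward and backward (zero phase, effective order
#' 2 x `order`) with reflective padding. Output length equals input
#' length. The study passband is 0.008-0.2 Hz at TR 1.8 s.
#'
#' @param x numeric vector or frames x series matrix.
#' @param tr sampling interval, seconds.
#' @param passband length-2 numeric, Hz.
#' @param order Butterworth design order (default 2).
#' @return Filtered data of the same shape.
#' @export
bandpass_filter <- function(x, tr, passband = c(0.008, 0.2), order = 2L) {
  nyquist <- 1 / (2 * tr)
  if (passband[1L] <= 0 || passband[1L] >= passband[2L] ||
      passband[2L] >= nyquist)
    stop("passband must satisfy 0 < low < high < Nyquist (",
         signif(nyquist, 4), " Hz at TR ", tr, " s)", call. = FALSE)
  was_vector <- is.null(dim(x))
  m <- as.matrix(x)
  if (any(!is.finite(m))) stop("non-finite values in series", call. = FALSE)
  n <- nrow(m)
  if (n <= 3L * order)
    stop("series length ", n, " too short for order ", order,
         call. = FALSE)
  flt <- signal::butter(order, passband / nyquist, type = "pass")
  pad <- 3L * order
  out <- apply(m, 2L, function(col) {
    filtfilt_reflect(flt, col - mean(col), pad)
  })
  if (was_vector) as.numeric(out) else out
}

#' Global-signal regression
#'
#' Each series is replaced by its residual after least-squares regression
#' on an intercept and the global mean series (optionally also a linear
#' trend). Residuals are exactly orthogonal to the global signal.
#'
#' @param m frames x series numeric matrix (voxel or region series).
#' @param detrend also include a linear-trend regressor (default `FALSE`).
#' @return Residual matrix of the same shape.
#' @export
global_signal_regress <- function(m, detrend = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 time points", call. = FALSE)
  g <- rowMeans(m)
  if (stats::sd(g) == 0) stop("degenerate global signal", call. = FALSE)
  X <- cbind(1, g)
  if (detrend) X <- cbind(X, seq_len(nrow(m)))
  qr_x <- qr(X)
  m - X %*% qr.coef(qr_x, m)
}

# 1D Gaussian kernel sampled at voxel centres, truncated at 4 sigma.
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable 3D convolution with zero padding, one axis at a time.
convolve_3d <- function(a, kernels) {
  d <- dim(a)
  for (axis in 1:3) {
    k <- kernels[[axis]]
    if (length(k) == 1L) next
    half <- (length(k) - 1L) / 2L
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    mat <- matrix(ap, nrow = dp[1L])
    n <- dp[1L]
    padded <- rbind(matrix(0, half, ncol(mat)), mat,
                    matrix(0, half, ncol(mat)))
    out <- matrix(0, n, ncol(mat))
    for (t in seq_along(k))
      out <- out + k[t] * padded[seq(t, t + n - 1L), , drop = FALSE]
    a <- aperm(array(out, dp), order(perm))
  }
  a
}

#' Spatial Gaussian smoothing of a BOLD image
#'
#' Per-frame separable 3D Gaussian convolution with
#' sigma_axis = FWHM / (2 sqrt(2 ln 2)) / voxel_dim_axis. Inside a mask the
#' kernel is renormalised (divided by the smoothed mask) so that no
#' intensity bleeds in from zeroed background and the in-mask mean is
#' preserved; `fwhm = 0` is the identity.
#'
#' @param bold a [bold_image]; a `mask` element (from
#'   [apply_brain_mask()]) is honoured if present.
#' @param fwhm full width at half maximum, mm (default 0.3).
#' @return The smoothed [bold_image].
#' @export
gaussian_smooth <- function(bold, fwhm = 0.3) {
  if (fwhm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (fwhm == 0) return(bold)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  kernels <- lapply(1:3, function(axis)
    gaussian_kernel_1d(sigma_mm / bold$voxel_dims[axis]))
  d <- dim(bold$data)
  mask <- if (!is.null(bold$mask)) bold$mask else array(TRUE, d[1:3])
  mask_sm <- convolve_3d(array(as.numeric(mask), d[1:3]), kernels)
  mask_sm[!mask] <- 1  # outside the mask stays zero; avoid 0/0
  mask_sm[mask & mask_sm <= 0] <- 1
  out <- bold
  for (t in seq_len(d[4L])) {
    frame <- bold$data[, , , t] * mask
    sm <- convolve_3d(frame, kernels) / mask_sm
    sm[!mask] <- 0
    out$data[, , , t] <- sm
  }
  out
}

#' Full per-subject BOLD preprocessing (voxel mode)
#'
#' Fixed stage order: mask, band-pass filter, global-signal regression,
#' Gaussian smoothing. Region-series inputs (matrices) should instead use
#' [bandpass_filter()] and [global_signal_regress()] directly, which is
#' what [run_pipeline()] does in region mode.
#'
#' @param bold a [bold_image].
#' @param mask binary [volume_image].
#' @param config a [run_config()].
#' @return Preprocessed [bold_image].
#' @export
preprocess_bold <- function(bold, mask, config = run_config()) {
  masked <- apply_brain_mask(bold, mask)
  d <- dim(masked$data)
  in_mask <- which(masked$mask)
  vox <- matrix(masked$data, nrow = prod(d[1:3]), ncol = d[4L])
  series <- t(vox[in_mask, , drop = FALSE])
  series <- bandpass_filter(series, tr = bold$tr,
                            passband = config$passband,
                            order = config$filter_order)
  series <- global_signal_regress(series,
                                  detrend = config$detrend_global)
  vox[in_mask, ] <- t(series)
  masked$data <- array(vox, d)
  gaussian_smooth(masked, fwhm = config$fwhm)
}
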