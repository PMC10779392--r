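#' Pipeline run configuration
#'
#' Collects the fixed analysis constants with their study defaults:
#' band-pass 0.008-0.2 Hz, Butterworth order 2 applied forward-backward,
#' spatial smoothing FWHM 0.3 mm, discriminative-edge threshold
#' R-squared > 0.2, angiogram intensity thresholds 7000/7500/8000,
#' pooled-variance two-sample t, TR 1.8 s. Any field can be overridden;
#' omitted fields keep the defaults.
#'
#' @param passband length-2 numeric, band-pass edges in Hz.
#' @param filter_order Butterworth design order (applied forward-backward).
#' @param fwhm spatial smoothing full width at half maximum, mm.
#' @param edge_r2_threshold per-edge R-squared threshold for the
#'   discriminative network, in (0, 1).
#' @param vascular_thresholds intensity thresholds for angiogram
#'   segmentation (arbitrary scanner units).
#' @param ttest_variance `"pooled"` or `"welch"`.
#' @param tr repetition time in seconds.
#' @param detrend_global logical; also remove a linear trend during
#'   global-signal regression (default `FALSE`).
#' @param seed integer seed for every stochastic step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(passband = c(0.008, 0.2),
                       filter_order = 2L,
                       fwhm = 0.3,
                       edge_r2_threshold = 0.2,
                       vascular_thresholds = c(7000, 7500, 8000),
                       ttest_variance = c("pooled", "welch"),
                       tr = 1.8,
                       detrend_global = FALSE,
                       seed = 1L) {
  ttest_variance <- match.arg(ttest_variance)
  cfg <- list(passband = as.numeric(passband),
              filter_order = as.integer(filter_order),
              fwhm = as.numeric(fwhm),
              edge_r2_threshold = as.numeric(edge_r2_threshold),
              vascular_thresholds = sort(as.numeric(vascular_thresholds)),
              ttest_variance = ttest_variance,
              tr = as.numeric(tr),
              detrend_global = isTRUE(detrend_global),
              seed = as.integer(seed))
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg a config list to validate.
#' @export
validate_run_config <- function(cfg) {
  nyquist <- 1 / (2 * cfg$tr)
  if (length(cfg$passband) != 2L || cfg$passband[1L] <= 0 ||
      cfg$passband[1L] >= cfg$passband[2L])
    stop("passband must satisfy 0 < low < high", call. = FALSE)
  if (cfg$passband[2L] >= nyquist)
    stop("passband high edge ", cfg$passband[2L],
         " Hz is at or above the Nyquist frequency ", signif(nyquist, 4),
         " Hz for TR ", cfg$tr, " s", call. = FALSE)
  if (cfg$filter_order < 1L) stop("filter_order must be >= 1", call. = FALSE)
  if (cfg$fwhm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (cfg$edge_r2_threshold <= 0 || cfg$edge_r2_threshold >= 1)
    stop("edge_r2_threshold must lie in (0, 1)", call. = FALSE)
  if (cfg$tr <= 0) stop("tr must be positive", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults of [run_config()];
#' everything else keeps its default.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n",
      "  passband: ", x$passband[1], "-", x$passband[2], " Hz (order ",
      x$filter_order, ", zero-phase)\n",
      "  fwhm: ", x$fwhm, " mm | edge R2 > ", x$edge_r2_threshold,
      " | t-test: ", x$ttest_variance, "\n",
      "  vascular thresholds: ",
      paste(x$vascular_thresholds, collapse = ", "),
      " | TR ", x$tr, " s | seed ", x$seed, "\n", sep = "")
  invisible(x)
}
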