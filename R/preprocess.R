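#' Preprocessing settings
#'
#' Collects the time-series cleaning parameters: band-pass edges, filter
#' order, spatial smoothing kernel width, voxel size, and the framewise
#' displacement cutoff used for motion scrubbing.
#'
#' @param band_hz `c(low, high)` band-pass edges in Hz. The study
#'   protocols used 0.01-0.1 Hz (an alternative 0.0025-0.05 Hz band can be
#'   supplied here).
#' @param order Butterworth filter order (applied forward and backward, so
#'   the effective attenuation is doubled and the phase is zero).
#' @param fwhm_mm Gaussian smoothing kernel full width at half maximum in
#'   mm (0 disables smoothing).
#' @param voxel_mm Isotropic voxel edge length in mm.
#' @param fd_threshold_mm Framewise-displacement cutoff above which frames
#'   are censored.
#' @param max_censor_frac Maximum tolerated fraction of censored frames
#'   before a run is flagged as excluded.
#' @return An object of class `filter_settings`.
#' @export
filter_settings <- function(band_hz = c(0.01, 0.1), order = 4L,
                            fwhm_mm = 1.5, voxel_mm = 1.25,
                            fd_threshold_mm = 0.5,
                            max_censor_frac = 0.5) {
  band_hz <- as.numeric(band_hz)
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[2] <= band_hz[1])
    stop("band_hz must be an increasing pair of positive frequencies")
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fd_threshold_mm <= 0) stop("fd_threshold_mm must be > 0")
  structure(list(band_hz = band_hz, order = as.integer(order),
                 fwhm_mm = fwhm_mm, voxel_mm = voxel_mm,
                 fd_threshold_mm = fd_threshold_mm,
                 max_censor_frac = max_censor_frac),
            class = "filter_settings")
}

# Cache of zero-phase Butterworth filter matrices keyed by
# (n, order, band, tr). filtfilt is linear in its input, so applying the
# filter to the identity matrix once gives an n x n operator that
# reproduces per-column filtfilt exactly while filtering all voxels in a
# single BLAS call.
.filter_cache <- new.env(parent = emptyenv())

bandpass_operator <- function(n, order, band_hz, tr_seconds) {
  key <- paste(n, order, band_hz[1], band_hz[2], tr_seconds, sep = "|")
  F <- .filter_cache[[key]]
  if (is.null(F)) {
    nyq <- 1 / (2 * tr_seconds)
    if (band_hz[2] >= nyq)
      stop(sprintf("band edge %.4g Hz not below Nyquist %.4g Hz",
                   band_hz[2], nyq))
    bf <- signal::butter(order, band_hz / nyq, type = "pass")
    F <- apply(diag(n), 2, function(col) signal::filtfilt(bf, col))
    .filter_cache[[key]] <- F
  }
  F
}

#' Zero-phase band-pass filter a run
#'
#' Censored frames are dropped first (scrubbed runs are filtered on the
#' concatenation of their kept frames), columns are demeaned, and a
#' zero-phase forward-backward Butterworth band-pass is applied to every
#' voxel and to the nuisance traces, so that later regressions compare
#' like with like. The returned run contains only the kept frames and an
#' all-`TRUE` censor vector.
#'
#' @param run A `run_ts`.
#' @param settings A [filter_settings()].
#' @return The filtered `run_ts`.
#' @export
bandpass <- function(run, settings) {
  stopifnot(inherits(run, "run_ts"), inherits(settings, "filter_settings"))
  keep <- run$censor
  n <- sum(keep)
  if (n < 64)
    stop("fewer than 64 kept frames: band-pass filter unstable on shorter series")
  F <- bandpass_operator(n, settings$order, settings$band_hz, run$tr_seconds)

  d <- run$data[keep, , drop = FALSE]
  d <- sweep(d, 2, colMeans(d))
  d <- F %*% d
  # the filter's DC gain is zero but finite-length edge transients leave a
  # small residual mean; remove it so downstream correlations see exactly
  # zero-mean series
  run$data <- sweep(d, 2, colMeans(d))

  nuis <- run$nuisance[keep, , drop = FALSE]
  for (col in c("wm", "csf"))
    nuis[[col]] <- drop(F %*% (nuis[[col]] - mean(nuis[[col]])))
  run$nuisance <- nuis
  if (!is.null(run$latents)) run$latents <- run$latents[keep, , drop = FALSE]
  run$spike_frames <- integer(0)
  run$censor <- rep(TRUE, n)
  run
}

#' Regress nuisance signals out of every voxel
#'
#' Ordinary least squares of each voxel's time series on an intercept plus
#' the given regressors, returning the residuals. Collinear regressor
#' columns are dropped with a warning. Residuals are orthogonal to every
#' retained regressor column.
#'
#' @param run A `run_ts`.
#' @param regressors Frame x k numeric matrix over the run's kept frames,
#'   or `NULL` to use the run's own white-matter and ventricle traces. An
#'   empty (0-column) matrix removes only the column mean.
#' @return The residualized `run_ts`.
#' @export
nuisance_regress <- function(run, regressors = NULL) {
  stopifnot(inherits(run, "run_ts"))
  keep <- run$censor
  n <- sum(keep)
  if (is.null(regressors))
    regressors <- as.matrix(run$nuisance[keep, c("wm", "csf")])
  regressors <- as.matrix(regressors)
  if (nrow(regressors) == length(keep) && !all(keep))
    regressors <- regressors[keep, , drop = FALSE]
  if (nrow(regressors) != n && ncol(regressors) > 0)
    stop("regressors must have one row per kept frame")
  if (ncol(regressors) > 0 && any(!is.finite(regressors)))
    stop("regressors must be finite")
  if (ncol(regressors) >= n)
    stop("more regressors than kept frames")

  X <- cbind(intercept = 1, regressors)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning("rank-deficient nuisance design; dropping collinear column(s): ",
            paste(dropped, collapse = ", "))
  }
  d <- run$data[keep, , drop = FALSE]
  res <- qr.resid(qx, d)
  out <- run$data
  out[keep, ] <- res
  run$data <- out
  run
}

#' Censor high-motion frames
#'
#' Sets `censor[t] = FALSE` wherever the framewise displacement exceeds
#' the threshold. Censored frames are excluded from all downstream
#' filtering, regression, and correlation (never interpolated). Scrubbing
#' is idempotent: the censor vector is recomputed from the FD trace each
#' time. Runs losing more than `max_censor_frac` of their frames are
#' flagged as excluded (attribute `excluded`) with a warning.
#'
#' @param run A `run_ts`.
#' @param settings A [filter_settings()].
#' @return The `run_ts` with its censor vector updated.
#' @export
scrub <- function(run, settings) {
  stopifnot(inherits(run, "run_ts"), inherits(settings, "filter_settings"))
  fd <- run$nuisance$fd
  if (is.null(fd)) stop("run has no framewise-displacement trace")
  run$censor <- fd <= settings$fd_threshold_mm
  frac <- mean(!run$censor)
  if (frac > settings$max_censor_frac) {
    attr(run, "excluded") <- TRUE
    warning(sprintf("%s %s: %.0f%% of frames censored (> %.0f%%); run flagged for exclusion",
                    run$subject_id, run$run_id, 100 * frac,
                    100 * settings$max_censor_frac))
  } else {
    attr(run, "excluded") <- FALSE
  }
  vip_log(sprintf("%s %s: censored %d/%d frames", run$subject_id, run$run_id,
                  sum(!run$censor), length(run$censor)))
  run
}

#' Mask-normalized Gaussian smoothing of a volume map
#'
#' Smooths a per-voxel map with a separable Gaussian kernel of the given
#' FWHM (sigma = FWHM / (2 sqrt(2 ln 2)), voxelized by the voxel size).
#' The kernel is renormalized over in-mask neighbors — the smoothed map is
#' the ratio of the smoothed masked values to the smoothed mask indicator
#' — so constants are preserved and values near mask edges are unbiased.
#' `fwhm_mm = 0` returns the input unchanged.
#'
#' @param values Numeric vector over the geometry's in-mask voxels (NAs
#'   are treated as missing and excluded from the kernel normalization).
#' @param geometry A `vip_geometry`.
#' @param settings A [filter_settings()].
#' @return Smoothed values in the same voxel order; NA where the input
#'   was NA.
#' @export
smooth_volume <- function(values, geometry, settings) {
  stopifnot(inherits(geometry, "vip_geometry"),
            length(values) == geometry$n_voxels)
  if (settings$fwhm_mm == 0) return(values)
  sigma <- settings$fwhm_mm / (2 * sqrt(2 * log(2))) / settings$voxel_mm
  radius <- max(1L, as.integer(ceiling(3 * sigma)))
  kern <- dnorm(seq(-radius, radius), sd = sigma)
  kern <- kern / sum(kern)

  dims <- geometry$dims
  idx <- which(geometry$mask)
  vol <- array(0, dims)
  wt <- array(0, dims)
  ok <- !is.na(values)
  vol[idx[ok]] <- values[ok]
  wt[idx[ok]] <- 1

  vol <- separable_smooth(vol, kern, radius)
  wt <- separable_smooth(wt, kern, radius)

  out <- rep(NA_real_, length(values))
  num <- vol[idx]
  den <- wt[idx]
  nz <- ok & den > 0
  out[nz] <- num[nz] / den[nz]
  out
}

# shift-and-add separable convolution along the three array dimensions
separable_smooth <- function(a, kern, radius) {
  d <- dim(a)
  for (axis in 1:3) {
    out <- array(0, d)
    n <- d[axis]
    for (off in seq(-radius, radius)) {
      w <- kern[off + radius + 1L]
      src <- seq_len(n) - off
      valid <- src >= 1 & src <= n
      dst_idx <- which(valid)
      src_idx <- src[valid]
      if (axis == 1) {
        out[dst_idx, , ] <- out[dst_idx, , ] + w * a[src_idx, , ]
      } else if (axis == 2) {
        out[, dst_idx, ] <- out[, dst_idx, ] + w * a[, src_idx, ]
      } else {
        out[, , dst_idx] <- out[, , dst_idx] + w * a[, , src_idx]
      }
    }
    a <- out
  }
  a
}

#' Run the full preprocessing chain on one run
#'
#' Fixed stage order: scrub, then band-pass on the kept frames, then
#' nuisance regression against the (identically filtered) white-matter and
#' ventricle traces. Spatial smoothing is applied later to connectivity
#' maps by default (`smooth_stage = "map"` in [run_pipeline()]); with
#' `smooth_stage = "timeseries"` each frame is smoothed here instead.
#'
#' @param run A `run_ts`.
#' @param settings A [filter_settings()].
#' @param geometry Required when `smooth_stage = "timeseries"`.
#' @param smooth_stage `"map"` (default; no smoothing here) or
#'   `"timeseries"`.
#' @return The preprocessed `run_ts`, or `NULL` when the run is excluded
#'   by the scrubbing rule.
#' @export
preprocess_run <- function(run, settings = filter_settings(),
                           geometry = NULL,
                           smooth_stage = c("map", "timeseries")) {
  smooth_stage <- match.arg(smooth_stage)
  run <- scrub(run, settings)
  if (isTRUE(attr(run, "excluded"))) {
    vip_log(sprintf("%s %s excluded by scrubbing", run$subject_id, run$run_id))
    return(NULL)
  }
  run <- bandpass(run, settings)
  run <- nuisance_regress(run)
  if (smooth_stage == "timeseries") {
    if (is.null(geometry)) stop("geometry required for time-series smoothing")
    run$data <- t(apply(run$data, 1, smooth_volume, geometry = geometry,
                        settings = settings))
  }
  run
}
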