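#' Band-limited unit-variance Gaussian signals
#'
#' White Gaussian noise is passed through a zero-phase DFT band mask that
#' keeps only Fourier components inside `band`, then rescaled to unit
#' sample variance. All power therefore lies inside the band and the mean
#' is exactly zero (the DC bin is removed).
#'
#' @param n_frames Series length.
#' @param k Number of independent signals.
#' @param tr_seconds Sampling interval (seconds).
#' @param band `c(low, high)` in Hz, inside (0, Nyquist).
#' @return `n_frames x k` matrix.
#' @export
band_limited_signals <- function(n_frames, k, tr_seconds, band) {
  freqs <- seq(0, n_frames - 1) / (n_frames * tr_seconds)
  freqs <- pmin(freqs, 1 / tr_seconds - freqs) # fold to [0, Nyquist]
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep))
    stop("latent band contains no DFT bin at this length and TR")
  w <- matrix(rnorm(n_frames * k), n_frames, k)
  W <- mvfft(w)
  W[!keep, ] <- 0
  s <- Re(mvfft(W, inverse = TRUE)) / n_frames
  scale(s, center = FALSE, scale = apply(s, 2, sd))[, , drop = FALSE]
}

#' Simulate one resting-state run of the phantom
#'
#' Generates the masked voxel x frame signal for one run under the planted
#' design: each voxel is a non-negative combination of the run's three
#' latent seed signals, plus a shared global fluctuation, white-matter and
#' ventricle nuisance signals with fixed voxel couplings, shared motion
#' spikes, and white Gaussian noise. The run carries its nuisance traces
#' and a framewise-displacement trace that is elevated exactly at the
#' spike frames.
#'
#' The run's random stream is derived deterministically from
#' `spec$rng_seed` and the (subject, run) identity, so any run can be
#' regenerated in isolation.
#'
#' @param spec A [phantom_spec()].
#' @param geometry Matching [make_geometry()] output.
#' @param truth Matching [plant_design()] output.
#' @param subject Subject index (1-based).
#' @param run Run index within subject (1-based).
#' @return An object of class `run_ts`: `data` (frames x voxels matrix),
#'   `tr_seconds`, `subject_id`, `run_id`, `nuisance` (data frame with
#'   `wm`, `csf`, `fd`), `censor` (logical, all `TRUE` before scrubbing),
#'   `spike_frames`, and `latents` (frames x 3, the seed latent signals).
#' @export
simulate_run <- function(spec, geometry, truth, subject, run) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(geometry, "vip_geometry"),
            inherits(truth, "vip_truth"))
  if (subject < 1 || subject > spec$n_subjects) stop("unknown subject index")
  if (run < 1 || run > spec$runs_per_subject[subject]) stop("unknown run index")
  n <- spec$frames_per_run[subject]
  if (n < 64)
    stop("frames_per_run must be >= 64 (band-pass filter unstable on shorter series)")
  tr <- spec$tr_seconds[subject]
  V <- geometry$n_voxels

  run_seed <- derive_run_seed(spec$rng_seed, subject, run)
  with_seed(run_seed, {
    latents <- band_limited_signals(n, 3, tr, spec$latent_band)
    colnames(latents) <- seed_names()
    g <- band_limited_signals(n, 1, tr, spec$latent_band)[, 1]
    n_wm <- band_limited_signals(n, 1, tr, spec$latent_band)[, 1]
    n_csf <- band_limited_signals(n, 1, tr, spec$latent_band)[, 1]
    spikes <- which(runif(n) < spec$spike_prob)
    fd <- runif(n, 0, 0.2)
    fd[spikes] <- runif(length(spikes), 1, 2)
    noise <- if (spec$noise_sd > 0)
      matrix(rnorm(n * V, sd = spec$noise_sd), n, V)
    else matrix(0, n, V)

    data <- latents %*% t(truth$loadings)
    if (spec$global_amp > 0) data <- data + spec$global_amp * g
    if (spec$wm_amp > 0)
      data <- data + (spec$wm_amp * n_wm) %*% t(truth$wm_coupling)
    if (spec$csf_amp > 0)
      data <- data + (spec$csf_amp * n_csf) %*% t(truth$csf_coupling)
    data <- data + noise
    if (length(spikes)) data[spikes, ] <- data[spikes, ] + 5

    structure(list(
      data = data,
      tr_seconds = tr,
      subject_id = sprintf("sub-%02d", subject),
      run_id = sprintf("run-%02d", run),
      nuisance = data.frame(wm = n_wm, csf = n_csf, fd = fd),
      censor = rep(TRUE, n),
      spike_frames = spikes,
      latents = latents
    ), class = "run_ts")
  })
}

#' @export
print.run_ts <- function(x, ...) {
  cat(sprintf("Run time series %s %s: %d frames x %d voxels, TR %.3g s, %d/%d frames kept\n",
              x$subject_id, x$run_id, nrow(x$data), ncol(x$data),
              x$tr_seconds, sum(x$censor), length(x$censor)))
  invisible(x)
}

n_kept <- function(run) sum(run$censor)

#' Emulate a heterogeneous acquisition table
#'
#' Returns a copy of `spec` whose per-subject run counts, frame counts,
#' and TR are drawn (with replacement, reproducibly) from the rows of a
#' published-style acquisition table such as [example_acquisitions()]
#' aggregated per animal.
#'
#' @param spec A [phantom_spec()].
#' @param table Per-subject acquisition summary with columns `n_runs`,
#'   `frames_per_run`, `tr_seconds`; defaults to the packaged example
#'   table.
#' @return A modified `phantom_spec`.
#' @export
emulate_acquisition <- function(spec, table = NULL) {
  if (is.null(table)) {
    man <- example_acquisitions()
    agg <- do.call(rbind, lapply(split(man, man$subject_id), function(d)
      data.frame(n_runs = nrow(d), frames_per_run = d$n_frames[1],
                 tr_seconds = d$tr_seconds[1])))
    table <- agg
  }
  rows <- with_seed(spec$rng_seed + 2L,
                    sample(nrow(table), spec$n_subjects, replace = TRUE))
  phantom_spec(
    n_subjects = spec$n_subjects,
    runs_per_subject = table$n_runs[rows],
    frames_per_run = table$frames_per_run[rows],
    tr_seconds = table$tr_seconds[rows],
    grid_dims = spec$grid_dims, voxel_mm = spec$voxel_mm,
    n_areas = spec$n_areas, seed_scheme = spec$seed_scheme,
    area_design = spec$area_design, latent_band = spec$latent_band,
    noise_sd = spec$noise_sd, global_amp = spec$global_amp,
    wm_amp = spec$wm_amp, csf_amp = spec$csf_amp,
    spike_prob = spec$spike_prob, loading_jitter = spec$loading_jitter,
    rng_seed = spec$rng_seed
  )
}
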