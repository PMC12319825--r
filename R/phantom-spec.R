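#' Specification of the synthetic resting-state phantom
#'
#' A `phantom_spec` fixes every parameter of the synthetic multi-subject
#' resting-state dataset: cohort size and run structure, the voxel grid and
#' parcellation, the seed-ROI construction scheme, the latent-signal band,
#' and the noise/nuisance amplitudes. Two specs with equal fields (including
#' `rng_seed`) generate bit-identical data.
#'
#' The defaults emulate the scale of a typical awake-monkey resting-state
#' study: 10 subjects with 8 runs of 300 frames each at TR 2 s, 1.25 mm
#' isotropic voxels, a two-hemisphere grid of 24 x 24 x 18 voxels per
#' hemisphere (~20k in-mask voxels), and a two-level parcellation of 16
#' areas per hemisphere grouped into 8 lobar regions. Per-subject run
#' counts, frame counts, and TR may instead be given as length-`n_subjects`
#' vectors to emulate a heterogeneous acquisition table.
#'
#' @param n_subjects Number of simulated animals.
#' @param runs_per_subject Runs per subject; scalar or per-subject vector.
#' @param frames_per_run Frames (volumes) per run; scalar or per-subject
#'   vector. Must be at least 64 so the band-pass filter is stable.
#' @param tr_seconds Repetition time in seconds; scalar or per-subject
#'   vector. The study protocols used 2.0 or 1.4 s.
#' @param grid_dims Per-hemisphere voxel grid (x = medio-lateral,
#'   y = antero-posterior, z = dorso-ventral). The full volume stacks the
#'   two hemispheres along x.
#' @param voxel_mm Isotropic voxel edge length in mm.
#' @param n_areas Number of cortical areas per hemisphere (>= 1).
#' @param seed_scheme Per-seed `(n_slices, voxels_per_slice)` used to build
#'   the three VIP seed ROIs from consecutive coronal slices; the default
#'   (aVIP 4x5, mVIP 4x5, pVIP 5x4) gives 20 voxels per ROI.
#' @param area_design Named list mapping every area name to a non-negative
#'   loading triple `(w_a, w_m, w_p)` on the three seed latent signals;
#'   `NULL` uses [default_area_design()].
#' @param latent_band Frequency band (Hz) of the latent signals; must lie
#'   inside (0, Nyquist).
#' @param noise_sd Standard deviation of the white thermal noise.
#' @param global_amp Amplitude of the shared global fluctuation.
#' @param wm_amp,csf_amp Amplitudes of the white-matter and ventricle
#'   nuisance signals (coupled voxel-wise).
#' @param spike_prob Per-frame probability of a motion spike; spikes add a
#'   shared artefact and elevate framewise displacement so scrubbing can
#'   censor them.
#' @param loading_jitter SD of multiplicative voxel-level jitter applied to
#'   nonzero loadings (0 = loadings exactly constant within an area).
#' @param rng_seed Integer seed governing all phantom randomness.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [make_geometry()], [plant_design()], [simulate_run()]
#' @export
#' @examples
#' spec <- phantom_spec(n_subjects = 2, runs_per_subject = 2,
#'                      frames_per_run = 96, grid_dims = c(12, 14, 8),
#'                      n_areas = 8)
#' spec$n_subjects
phantom_spec <- function(n_subjects = 10,
                         runs_per_subject = 8,
                         frames_per_run = 300,
                         tr_seconds = 2,
                         grid_dims = c(24, 24, 18),
                         voxel_mm = 1.25,
                         n_areas = 16,
                         seed_scheme = list(aVIP = c(4, 5),
                                            mVIP = c(4, 5),
                                            pVIP = c(5, 4)),
                         area_design = NULL,
                         latent_band = c(0.01, 0.1),
                         noise_sd = 1,
                         global_amp = 0.15,
                         wm_amp = 0.3,
                         csf_amp = 0.3,
                         spike_prob = 0.02,
                         loading_jitter = 0,
                         rng_seed = 42L) {
  stopifnot(length(grid_dims) == 3, all(grid_dims >= 1))
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1) stop("n_subjects must be >= 1")

  expand <- function(x, what) {
    if (length(x) == 1) rep(x, n_subjects)
    else if (length(x) == n_subjects) x
    else stop(sprintf("%s must be scalar or length n_subjects", what))
  }
  runs <- as.integer(expand(runs_per_subject, "runs_per_subject"))
  frames <- as.integer(expand(frames_per_run, "frames_per_run"))
  tr <- as.numeric(expand(tr_seconds, "tr_seconds"))

  if (any(runs < 1)) stop("runs_per_subject must be >= 1")
  if (any(frames < 64))
    stop("frames_per_run must be >= 64 (band-pass filter unstable on shorter series)")
  if (any(tr <= 0)) stop("tr_seconds must be positive")

  amps <- c(noise_sd = noise_sd, global_amp = global_amp,
            wm_amp = wm_amp, csf_amp = csf_amp)
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  if (spike_prob < 0 || spike_prob >= 1) stop("spike_prob must be in [0, 1)")
  if (loading_jitter < 0) stop("loading_jitter must be >= 0")

  latent_band <- as.numeric(latent_band)
  if (length(latent_band) != 2 || latent_band[1] <= 0 ||
      latent_band[2] <= latent_band[1])
    stop("latent_band must be an increasing pair of positive frequencies")
  nyquist <- 1 / (2 * max(tr))
  if (latent_band[2] >= nyquist)
    stop(sprintf("latent_band upper edge %.4g Hz must lie below Nyquist %.4g Hz",
                 latent_band[2], nyquist))

  n_areas <- as.integer(n_areas)
  if (n_areas < 1) stop("n_areas must be >= 1")

  if (!is.list(seed_scheme) ||
      !setequal(names(seed_scheme), seed_names()))
    stop("seed_scheme must name exactly aVIP, mVIP, pVIP")

  spec <- structure(list(
    n_subjects = n_subjects,
    runs_per_subject = runs,
    frames_per_run = frames,
    tr_seconds = tr,
    grid_dims = as.integer(grid_dims),
    voxel_mm = voxel_mm,
    n_areas = n_areas,
    seed_scheme = seed_scheme,
    area_design = area_design,
    latent_band = latent_band,
    noise_sd = noise_sd,
    global_amp = global_amp,
    wm_amp = wm_amp,
    csf_amp = csf_amp,
    spike_prob = spike_prob,
    loading_jitter = loading_jitter,
    rng_seed = as.integer(rng_seed)
  ), class = "phantom_spec")

  if (is.null(spec$area_design))
    spec$area_design <- default_area_design(area_names(spec))
  validate_area_design(spec$area_design, area_names(spec))
  spec
}

#' Area names implied by a phantom spec
#'
#' Areas are named `area01`, `area02`, ... except the designated VIP host
#' area, which is named `VIP`. Names are shared across hemispheres.
#' @param spec A [phantom_spec()].
#' @return Character vector of length `spec$n_areas`.
#' @export
area_names <- function(spec) {
  n <- spec$n_areas
  nm <- sprintf("area%02d", seq_len(n))
  nm[vip_area_index(n)] <- "VIP"
  nm
}

#' Lobar region names in the conventional anterior-to-posterior order
#' @return Character vector of the 8 region names.
#' @export
region_names <- function() {
  c("orbitofrontal", "prefrontal", "motor/premotor", "cingulate",
    "limbic", "temporal", "parietal", "occipital")
}

# Which area (1..n_areas) hosts VIP: the first area of the parietal region
# under the contiguous region assignment, or the last area when there are
# too few areas for a parietal region to exist.
vip_area_index <- function(n_areas) {
  reg <- region_assignment(n_areas)
  i <- which(reg == "parietal")
  if (length(i)) i[1] else n_areas
}

# Contiguous assignment of n_areas areas to (up to) 8 regions.
region_assignment <- function(n_areas) {
  n_reg <- min(8L, n_areas)
  sizes <- rep(n_areas %/% n_reg, n_reg)
  extra <- n_areas %% n_reg
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(region_names()[seq_len(n_reg)], times = sizes)
}

#' Default planted connectivity design
#'
#' Assigns each area a loading triple on the (anterior, middle, posterior)
#' latent signals so that all eight overlap categories occur, anterior-only
#' and posterior-only areas exist for preference testing, and the
#' anterior-middle overlap exceeds the anterior-posterior overlap (the
#' antero-posterior gradient signature). Single-seed areas load at 0.7,
#' two-seed at 0.5 each, the VIP host at 0.6 on all three; a few areas are
#' left unconnected.
#'
#' @param names Character vector of area names (one hemisphere's worth;
#'   the design is mirrored in both hemispheres).
#' @return Named list of numeric loading triples `(w_a, w_m, w_p)`.
#' @export
default_area_design <- function(names) {
  n <- length(names)
  # cycle of category templates guaranteeing coverage and the gradient
  templates <- list(
    NONE = c(0, 0, 0),
    AP   = c(0.5, 0, 0.5),
    A1   = c(0.7, 0, 0),
    AM1  = c(0.5, 0.5, 0),
    A2   = c(0.7, 0, 0),
    AM2  = c(0.5, 0.5, 0),
    A3   = c(0.7, 0, 0),
    NONE2 = c(0, 0, 0),
    NONE3 = c(0, 0, 0),
    MP1  = c(0, 0.5, 0.5),
    M1   = c(0, 0.7, 0),
    P1   = c(0, 0, 0.7),
    VIP  = c(0.6, 0.6, 0.6),
    AMP  = c(0.5, 0.5, 0.5),
    MP2  = c(0, 0.5, 0.5),
    P2   = c(0, 0, 0.7)
  )
  design <- vector("list", n)
  names(design) <- names
  for (i in seq_len(n)) {
    if (names[i] == "VIP") {
      design[[i]] <- templates$VIP
    } else {
      design[[i]] <- templates[[((i - 1L) %% length(templates)) + 1L]]
    }
  }
  design
}

validate_area_design <- function(design, names) {
  if (!is.list(design)) stop("area_design must be a named list")
  missing <- setdiff(names, names(design))
  if (length(missing))
    stop("area_design must assign every area a loading triple; missing: ",
         paste(missing, collapse = ", "))
  for (nm in names) {
    w <- design[[nm]]
    if (length(w) != 3 || !is.numeric(w) || any(!is.finite(w)))
      stop(sprintf("area_design[['%s']] must be a numeric triple", nm))
    if (any(w < 0))
      stop(sprintf("negative weight in area_design[['%s']]", nm))
  }
  invisible(TRUE)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Synthetic resting-state phantom specification\n")
  cat(sprintf("  subjects: %d, runs/subject: %s, frames/run: %s, TR: %s s\n",
              x$n_subjects,
              paste(unique(x$runs_per_subject), collapse = "/"),
              paste(unique(x$frames_per_run), collapse = "/"),
              paste(unique(x$tr_seconds), collapse = "/")))
  cat(sprintf("  grid: %s per hemisphere (%.3g mm voxels), %d areas/hemisphere\n",
              paste(x$grid_dims, collapse = "x"), x$voxel_mm, x$n_areas))
  cat(sprintf("  latent band: %.4g-%.4g Hz; noise sd %.3g; global %.3g; wm %.3g; csf %.3g; spike p %.3g\n",
              x$latent_band[1], x$latent_band[2], x$noise_sd,
              x$global_amp, x$wm_amp, x$csf_amp, x$spike_prob))
  cat(sprintf("  rng seed: %d\n", x$rng_seed))
  invisible(x)
}
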