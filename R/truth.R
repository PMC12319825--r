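#' Plant the ground-truth connectivity design into the phantom volume
#'
#' Assigns every in-mask voxel a non-negative loading triple
#' `(w_a, w_m, w_p)` on the three seed latent signals according to the
#' spec's per-area design, and derives the implied true overlap category
#' from the zero-pattern of the loadings (seed s participates iff
#' `w_s > 0`). Voxels belonging to a seed ROI are overridden to load 1.0
#' on their own seed's latent and 0 on the others, so each seed's own
#' voxels carry the maximum weight in the design.
#'
#' Also draws the fixed voxel-wise couplings to the white-matter and
#' ventricle nuisance signals used by [simulate_run()].
#'
#' @param spec A [phantom_spec()].
#' @param geometry The matching [make_geometry()] output.
#' @return An object of class `vip_truth`: `loadings` (n_voxels x 3 matrix,
#'   columns aVIP/mVIP/pVIP), `category` (factor over the 8 levels),
#'   `wm_coupling`, `csf_coupling` (per-voxel), and `design` (the per-area
#'   table actually applied).
#' @export
plant_design <- function(spec, geometry) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(geometry, "vip_geometry"))
  design <- spec$area_design
  validate_area_design(design, area_names(spec))

  n <- geometry$n_voxels
  L <- matrix(0, n, 3, dimnames = list(NULL, seed_names()))
  for (nm in names(design)) {
    rows <- geometry$voxels$area_name == nm
    if (any(rows)) L[rows, ] <- matrix(design[[nm]], sum(rows), 3, byrow = TRUE)
  }

  # seed ROI voxels load maximally on their own latent only
  for (h in hemi_names()) {
    for (s in seed_names()) {
      vox <- geometry$seeds[[h]][[s]]
      L[vox, ] <- 0
      L[vox, s] <- 1
    }
  }

  extras <- with_seed(spec$rng_seed + 1L, {
    jit <- if (spec$loading_jitter > 0)
      matrix(pmax(0, 1 + rnorm(n * 3, 0, spec$loading_jitter)), n, 3)
    else NULL
    list(jitter = jit,
         wm = runif(n, 0.5, 1.5),
         csf = runif(n, 0.5, 1.5))
  })
  if (!is.null(extras$jitter)) L <- L * extras$jitter

  structure(list(
    loadings = L,
    category = loading_category(L),
    wm_coupling = extras$wm,
    csf_coupling = extras$csf,
    design = design
  ), class = "vip_truth")
}

#' True overlap category implied by a loading matrix
#'
#' Deterministic function of the zero-pattern: seed s participates at a
#' voxel iff its loading is strictly positive.
#' @param loadings n x 3 non-negative matrix (columns aVIP, mVIP, pVIP).
#' @return Factor over the 8 category levels.
#' @export
loading_category <- function(loadings) {
  stopifnot(ncol(loadings) == 3, all(loadings >= 0))
  bits <- (loadings[, 1] > 0) + 2L * (loadings[, 2] > 0) +
    4L * (loadings[, 3] > 0)
  category_from_bits(bits)
}

#' @export
print.vip_truth <- function(x, ...) {
  cat("Planted ground truth:\n")
  print(table(x$category))
  invisible(x)
}
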