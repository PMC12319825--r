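#' Build the phantom volume geometry, surface model, and projection map
#'
#' Constructs a deterministic two-hemisphere voxel grid with a two-level
#' (region -> area) parcellation, the three VIP seed ROIs per hemisphere,
#' an abstract surface vertex table, and the voxel-to-vertex projection.
#'
#' The full volume stacks the left and right hemisphere grids along x.
#' Every in-mask voxel belongs to exactly one area; every area belongs to
#' exactly one region; the designated `VIP` host area sits in the parietal
#' region and spans all coronal (y) slices so the seed ROIs can be carved
#' from consecutive slices. Each in-mask voxel projects to one, two, or
#' three surface vertices and each vertex has exactly one source voxel.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `vip_geometry` with elements:
#' \describe{
#'   \item{dims}{full-volume grid dimensions (both hemispheres).}
#'   \item{mask}{logical 3D array of in-mask voxels.}
#'   \item{voxels}{data frame (one row per in-mask voxel, in `which(mask)`
#'     order): `i, j, k` grid coordinates, `hemisphere`, `area_id`,
#'     `area_name`, `region`.}
#'   \item{areas}{area lookup table: `area_id, area_name, region,
#'     hemisphere`.}
#'   \item{seeds}{`seeds[[hemisphere]][[seed]]` = ordered in-mask voxel
#'     indices (anterior to posterior).}
#'   \item{surface}{vertex table: `vertex_id, voxel, hemisphere, area_id,
#'     area_name, region`.}
#'   \item{projection}{data frame `voxel -> vertex_id` (same content as
#'     the surface table's voxel column, kept for serialization).}
#' }
#' @export
#' @examples
#' g <- make_geometry(phantom_spec(n_subjects = 1, grid_dims = c(12, 14, 8),
#'                                 n_areas = 8, frames_per_run = 96))
#' nrow(g$voxels)          # in-mask voxels
#' lengths(g$seeds$left)   # 20 voxels per seed ROI
make_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  hd <- spec$grid_dims
  dims <- c(2L * hd[1], hd[2], hd[3])
  mask <- array(TRUE, dim = dims)

  idx <- which(mask)
  coord <- arrayInd(idx, dims)
  hemi <- ifelse(coord[, 1] <= hd[1], "left", "right")

  # per-hemisphere x coordinate used for the area partition
  xh <- ifelse(hemi == "left", coord[, 1], coord[, 1] - hd[1])

  nm <- area_names(spec)
  regions <- region_assignment(spec$n_areas)
  fac <- area_block_factors(spec$n_areas, hd[1], hd[3])
  x_bin <- block_bin(xh, hd[1], fac[1])
  z_bin <- block_bin(coord[, 3], hd[3], fac[2])
  area_idx <- (z_bin - 1L) * fac[1] + x_bin # 1..n_areas within hemisphere

  # check every area is populated and large enough in each hemisphere
  for (h in hemi_names()) {
    cnt <- tabulate(area_idx[hemi == h], nbins = spec$n_areas)
    bad <- which(cnt < 8)
    if (length(bad))
      stop(sprintf(
        "grid too small: area '%s' (%s hemisphere) has %d voxels (< 8)",
        nm[bad[1]], h, cnt[bad[1]]))
  }

  hemi_off <- ifelse(hemi == "left", 0L, spec$n_areas)
  area_id <- area_idx + hemi_off

  areas <- data.frame(
    area_id = seq_len(2L * spec$n_areas),
    area_name = rep(nm, 2),
    region = rep(regions, 2),
    hemisphere = rep(hemi_names(), each = spec$n_areas),
    stringsAsFactors = FALSE
  )

  voxels <- data.frame(
    i = coord[, 1], j = coord[, 2], k = coord[, 3],
    hemisphere = hemi,
    area_id = area_id,
    area_name = nm[area_idx],
    region = regions[area_idx],
    stringsAsFactors = FALSE
  )

  geom <- structure(list(
    dims = dims, hemi_dims = hd, voxel_mm = spec$voxel_mm,
    mask = mask, voxels = voxels, areas = areas,
    n_voxels = nrow(voxels)
  ), class = "vip_geometry")

  geom$seeds <- build_seed_rois(geom, spec$seed_scheme)

  # voxel -> vertices: 1 to 3 vertices per voxel, drawn reproducibly
  nv <- with_seed(spec$rng_seed, sample(1:3, geom$n_voxels, replace = TRUE))
  src <- rep.int(seq_len(geom$n_voxels), nv)
  geom$surface <- data.frame(
    vertex_id = seq_along(src),
    voxel = src,
    hemisphere = voxels$hemisphere[src],
    area_id = voxels$area_id[src],
    area_name = voxels$area_name[src],
    region = voxels$region[src],
    stringsAsFactors = FALSE
  )
  geom$projection <- geom$surface[, c("voxel", "vertex_id")]
  geom
}

# factor n_areas into (f_x, f_z) blocks with near-square voxel blocks
area_block_factors <- function(n_areas, nx, nz) {
  divs <- which(n_areas %% seq_len(n_areas) == 0)
  best <- NULL
  best_score <- Inf
  for (fx in divs) {
    fz <- n_areas %/% fx
    if (fx > nx || fz > nz) next
    score <- abs(nx / fx - nz / fz)
    if (score < best_score) {
      best <- c(fx, fz)
      best_score <- score
    }
  }
  if (is.null(best))
    stop(sprintf("grid too small: cannot place %d areas on a %dx%d cross-section",
                 n_areas, nx, nz))
  best
}

# near-equal binning of coordinates 1..n into f blocks
block_bin <- function(x, n, f) {
  edges <- round(seq(0, n, length.out = f + 1))
  as.integer(cut(x, breaks = edges, labels = FALSE))
}

#' Construct the three VIP seed ROIs from consecutive coronal slices
#'
#' Builds the anterior, middle, and posterior VIP seed ROIs within the
#' VIP-labeled voxels of each hemisphere, taking consecutive coronal (y)
#' slices in anterior-to-posterior order: by default five voxels from each
#' of four slices for aVIP and mVIP, and four voxels from each of five
#' slices for pVIP, so that all three ROIs contain 20 voxels. The three
#' ROIs occupy disjoint slice ranges with mVIP strictly between aVIP and
#' pVIP.
#'
#' @param geometry A `vip_geometry` (the `seeds` element may be absent).
#' @param scheme Named list `seed -> c(n_slices, voxels_per_slice)`.
#' @return `list(left = list(aVIP=, mVIP=, pVIP=), right = ...)` of ordered
#'   in-mask voxel indices.
#' @export
build_seed_rois <- function(geometry,
                            scheme = list(aVIP = c(4, 5), mVIP = c(4, 5),
                                          pVIP = c(5, 4))) {
  stopifnot(inherits(geometry, "vip_geometry"))
  if (!setequal(names(scheme), seed_names()))
    stop("scheme must name exactly aVIP, mVIP, pVIP")
  sizes <- vapply(scheme, function(s) as.integer(s[1] * s[2]), integer(1))
  if (length(unique(sizes)) != 1)
    warning("seed scheme gives unequal ROI sizes: ",
            paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "))

  vox <- geometry$voxels
  out <- list()
  for (h in hemi_names()) {
    in_vip <- which(vox$area_name == "VIP" & vox$hemisphere == h)
    if (!length(in_vip))
      stop(sprintf("no VIP-labeled voxels in %s hemisphere", h))
    slices <- sort(unique(vox$j[in_vip]))
    need <- sum(vapply(scheme, function(s) as.integer(s[1]), integer(1)))
    if (length(slices) < need)
      stop(sprintf(
        "insufficient VIP extent in %s hemisphere: %d coronal slices available, %d required",
        h, length(slices), need))
    # consecutive anterior-to-posterior assignment: aVIP first, then mVIP,
    # then pVIP
    rois <- list()
    offset <- 0L
    for (s in seed_names()) {
      n_sl <- as.integer(scheme[[s]][1])
      per <- as.integer(scheme[[s]][2])
      picked <- integer(0)
      for (sl in slices[offset + seq_len(n_sl)]) {
        cand <- in_vip[vox$j[in_vip] == sl]
        if (length(cand) < per)
          stop(sprintf(
            "insufficient VIP voxels on coronal slice y=%d (%s hemisphere): %d available, %d required for %s",
            sl, h, length(cand), per, s))
        # deterministic within-slice order: ventral-to-dorsal, then lateral
        ord <- order(vox$k[cand], vox$i[cand])
        picked <- c(picked, cand[ord][seq_len(per)])
      }
      rois[[s]] <- picked
      offset <- offset + n_sl
    }
    out[[h]] <- rois
  }
  out
}

#' @export
print.vip_geometry <- function(x, ...) {
  cat(sprintf("Phantom geometry: %s grid, %d in-mask voxels, %d areas, %d vertices\n",
              paste(x$dims, collapse = "x"), x$n_voxels, nrow(x$areas),
              nrow(x$surface)))
  invisible(x)
}

#' Per-voxel hemisphere lookup
#' @noRd
voxel_hemisphere <- function(geometry) geometry$voxels$hemisphere
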