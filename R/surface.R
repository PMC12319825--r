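#' Project a volume map onto the surface vertex table
#'
#' Every vertex takes the value of its unique source voxel (a voxel may
#' feed several vertices). Vertices whose source voxel is missing —
#' contralateral to the seed, for instance — are missing on the surface
#' too.
#'
#' @param volume_map A `zmap` or a plain numeric vector over the
#'   geometry's in-mask voxels.
#' @param geometry A `vip_geometry` (holds the projection and the vertex
#'   table).
#' @return A `surface_map`: numeric vector over vertices with attributes
#'   `seed`, `hemisphere`, `level` carried over when available.
#' @export
project_to_surface <- function(volume_map, geometry) {
  stopifnot(inherits(geometry, "vip_geometry"))
  values <- if (inherits(volume_map, "zmap")) volume_map$values else volume_map
  if (length(values) != geometry$n_voxels)
    stop("volume map length does not match the geometry's in-mask voxels")
  out <- values[geometry$surface$voxel]
  attr(out, "seed") <- if (inherits(volume_map, "zmap")) volume_map$seed else NA
  attr(out, "hemisphere") <-
    if (inherits(volume_map, "zmap")) volume_map$hemisphere else NA
  attr(out, "level") <- if (inherits(volume_map, "zmap")) volume_map$level else NA
  class(out) <- c("surface_map", class(out))
  out
}

#' Threshold a surface map
#'
#' `TRUE` exactly where the value is present and strictly greater than
#' `z_thr`; boundary values equal to the threshold and missing vertices
#' are `FALSE`.
#'
#' @param map A `surface_map` or numeric vector.
#' @param z_thr Positive z threshold (default 0.05, with 0.03-0.07 the
#'   conventional robustness sweep).
#' @return Logical vector per vertex.
#' @export
threshold_surface <- function(map, z_thr = 0.05) {
  if (z_thr <= 0) stop("z_thr must be > 0")
  v <- as.numeric(map)
  !is.na(v) & v > z_thr
}

#' Eight-way overlap categorization of three thresholded seed maps
#'
#' Combines the boolean anterior/middle/posterior maps into one exclusive
#' category per vertex: `NONE`, single-seed `A`, `M`, `P`, pairwise `AM`,
#' `MP`, `AP`, and `AMP` for vertices covered by all three.
#'
#' @param a_bin,m_bin,p_bin Logical vectors on identical vertex sets.
#' @param threshold_used The z threshold that produced the inputs
#'   (bookkeeping).
#' @return A `category_map`: factor over the 8 levels with attribute
#'   `threshold_used`.
#' @export
categorize <- function(a_bin, m_bin, p_bin, threshold_used = NA_real_) {
  n <- length(a_bin)
  if (length(m_bin) != n || length(p_bin) != n)
    stop("the three thresholded maps must cover identical vertex sets")
  bits <- as.integer(a_bin) + 2L * as.integer(m_bin) + 4L * as.integer(p_bin)
  out <- category_from_bits(bits)
  attr(out, "threshold_used") <- threshold_used
  class(out) <- c("category_map", class(out))
  out
}

#' Seed-combination display colors
#'
#' The additive RGB convention: anterior blue, middle green, posterior
#' red; pairwise overlaps are the componentwise maxima (anterior-middle
#' cyan, middle-posterior yellow, anterior-posterior magenta); triple
#' overlap white; unconnected black.
#'
#' @param categories A `category_map` (or factor over the 8 levels).
#' @return Data frame with `category`, `r`, `g`, `b`, `hex` per vertex.
#' @export
rgb_encode <- function(categories) {
  pal <- matrix(c(
    0, 0, 0,       # NONE  black
    0, 0, 255,     # A     blue
    0, 255, 0,     # M     green
    255, 0, 0,     # P     red
    0, 255, 255,   # AM    cyan
    255, 255, 0,   # MP    yellow
    255, 0, 255,   # AP    magenta
    255, 255, 255  # AMP   white
  ), ncol = 3, byrow = TRUE,
  dimnames = list(category_levels(), c("r", "g", "b")))
  idx <- match(as.character(categories), rownames(pal))
  out <- data.frame(category = as.character(categories),
                    pal[idx, , drop = FALSE],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$hex <- sprintf("#%02X%02X%02X", out$r, out$g, out$b)
  out
}

#' Category composition percentages by hemisphere, region, or area
#'
#' Counts vertices per category within each scope unit (hemisphere;
#' hemisphere x region; or hemisphere x area) and expresses them as
#' percentages of the unit's vertex total, which makes each unit's eight
#' percentages sum to 100. Empty units keep zero counts with undefined
#' (NA) percentages and are flagged.
#'
#' @param categories A `category_map` over the geometry's vertices.
#' @param geometry A `vip_geometry`.
#' @param scope `"hemisphere"`, `"region"`, or `"area"`.
#' @return Data frame with the unit labels, `category`, `count`, `total`,
#'   and `pct`.
#' @export
composition <- function(categories, geometry,
                        scope = c("hemisphere", "region", "area")) {
  scope <- match.arg(scope)
  surf <- geometry$surface
  if (length(categories) != nrow(surf))
    stop("category map length does not match the surface vertex table")
  unit <- switch(scope,
    hemisphere = surf$hemisphere,
    region = paste(surf$hemisphere, surf$region, sep = "|"),
    area = paste(surf$hemisphere, surf$area_name, sep = "|"))
  tab <- table(unit = unit, category = factor(categories,
                                              levels = category_levels()))
  counts <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(counts) <- c("unit", "category", "count")
  totals <- rowSums(tab)
  counts$total <- totals[counts$unit]
  counts$pct <- ifelse(counts$total > 0, 100 * counts$count / counts$total,
                       NA_real_)
  if (scope != "hemisphere") {
    parts <- do.call(rbind, strsplit(counts$unit, "|", fixed = TRUE))
    counts$hemisphere <- parts[, 1]
    counts[[scope]] <- parts[, 2]
  } else {
    counts$hemisphere <- counts$unit
  }
  counts$unit <- NULL
  empty <- unique(counts$hemisphere[counts$total == 0])
  if (length(empty))
    vip_log("empty scope unit(s): ", paste(empty, collapse = ", "))
  counts[order(counts$hemisphere, counts[[if (scope == "hemisphere") "hemisphere" else scope]],
               match(counts$category, category_levels())), , drop = FALSE]
}

#' Spearman similarity between two whole-hemisphere maps
#'
#' Rank correlation (average-rank tie handling, two-sided p from the
#' large-sample t approximation) over the jointly non-missing vertices of
#' two unthresholded surface maps.
#'
#' @param map1,map2 `surface_map`s (or numeric vectors) on the same
#'   vertex set.
#' @param min_n Minimum number of jointly non-missing vertices.
#' @return `list(rho, p, n)`; `rho` is NA (with a warning) when either
#'   map is constant over the joint support.
#' @export
map_similarity <- function(map1, map2, min_n = 10) {
  v1 <- as.numeric(map1)
  v2 <- as.numeric(map2)
  if (length(v1) != length(v2)) stop("maps must cover the same vertex set")
  ok <- !is.na(v1) & !is.na(v2)
  n <- sum(ok)
  if (n < min_n)
    stop(sprintf("only %d jointly non-missing vertices (need >= %d)", n, min_n))
  if (sd(v1[ok]) == 0 || sd(v2[ok]) == 0) {
    warning("constant map: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  ct <- suppressWarnings(cor.test(v1[ok], v2[ok], method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}
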