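#' Extract a seed's time series from a run
#'
#' The seed signal is the unweighted mean of the seed voxels' time series
#' over the run's kept frames (the conventional reading of "the signal of
#' the 20 voxels"). `agg = "first_pc"` uses the first principal component
#' instead, sign-aligned with the mean signal.
#'
#' @param run A `run_ts`.
#' @param voxels In-mask voxel indices of the seed ROI.
#' @param agg `"mean"` (default) or `"first_pc"`.
#' @return Numeric vector over the kept frames with attributes preserved
#'   for provenance.
#' @export
extract_seed_signal <- function(run, voxels, agg = c("mean", "first_pc")) {
  stopifnot(inherits(run, "run_ts"))
  agg <- match.arg(agg)
  if (!length(voxels)) stop("empty seed voxel set")
  d <- run$data[run$censor, voxels, drop = FALSE]
  if (agg == "mean") {
    sig <- rowMeans(d)
  } else {
    pc <- svd(sweep(d, 2, colMeans(d)), nu = 1, nv = 0)$u[, 1]
    m <- rowMeans(d)
    if (sum(pc * m) < 0) pc <- -pc
    sig <- pc
  }
  sig
}

#' Seed-to-whole-hemisphere correlation map for one run
#'
#' Pearson correlation of the seed signal with every ipsilateral in-mask
#' voxel over the kept frames, followed by the Fisher r-to-z transform
#' `z = atanh(r)`. `|r|` is clipped to `1 - 1e-7` so the transform stays
#' finite at the seed's own voxels. Zero-variance voxels get `z = 0` (the
#' count is logged, never NaN). Contralateral voxels are missing, not
#' zero.
#'
#' @param run A preprocessed `run_ts`.
#' @param seed_signal Numeric vector over the kept frames (from
#'   [extract_seed_signal()]).
#' @param hemisphere `"left"` or `"right"`.
#' @param geometry A `vip_geometry`.
#' @param seed Seed label (`"aVIP"`, `"mVIP"`, `"pVIP"`), bookkeeping only.
#' @return A `zmap` (level `"run"`) whose `values` span all in-mask voxels
#'   with NA outside the seed's hemisphere.
#' @export
run_correlation_map <- function(run, seed_signal, hemisphere, geometry,
                                seed = NA_character_) {
  stopifnot(inherits(run, "run_ts"), inherits(geometry, "vip_geometry"))
  hemisphere <- match.arg(hemisphere, hemi_names())
  n <- sum(run$censor)
  if (n < 32) stop("fewer than 32 kept frames; correlation map refused")
  if (length(seed_signal) != n)
    stop("seed signal length must equal the number of kept frames")

  ipsi <- which(geometry$voxels$hemisphere == hemisphere)
  d <- run$data[run$censor, ipsi, drop = FALSE]
  s <- seed_signal - mean(seed_signal)
  dc <- sweep(d, 2, colMeans(d))
  num <- drop(crossprod(dc, s))
  den <- sqrt(colSums(dc^2)) * sqrt(sum(s^2))
  r <- rep(0, length(ipsi))
  pos <- den > 0
  r[pos] <- num[pos] / den[pos]
  n_degenerate <- sum(!pos)
  if (n_degenerate > 0)
    vip_log(sprintf("%s %s %s/%s: %d zero-variance voxel(s) set to z = 0",
                    run$subject_id, run$run_id, seed, hemisphere,
                    n_degenerate))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  values <- rep(NA_real_, geometry$n_voxels)
  values[ipsi] <- atanh(r)

  structure(list(
    values = values, level = "run", seed = seed, hemisphere = hemisphere,
    subject_id = run$subject_id, run_id = run$run_id,
    n_frames = n, n_zero_variance = n_degenerate
  ), class = "zmap")
}

#' Aggregate run-level z-maps into a subject-level map
#'
#' Per voxel, the subject value is the mean Fisher z across runs and the
#' p-value comes from a two-sided one-sample t-test of the run z values
#' against zero. The significance mask is `p < alpha` (default 0.001,
#' uncorrected). Voxels whose run values have zero across-run variance
#' get `p = 0` when the mean is nonzero and `p = 1` when it is zero.
#'
#' @param run_maps List of run-level `zmap`s for one subject, seed, and
#'   hemisphere (at least two).
#' @param alpha Per-voxel significance level.
#' @return A `zmap` (level `"subject"`) with `values`, `pvals`,
#'   `sig_mask`, and `n_runs`.
#' @export
subject_aggregate <- function(run_maps, alpha = 0.001) {
  if (length(run_maps) < 2)
    stop("subject aggregation requires at least two run maps (t-test undefined)")
  key <- unique(t(vapply(run_maps, function(m)
    c(m$seed, m$hemisphere, m$subject_id), character(3))))
  if (nrow(key) != 1)
    stop("run maps must share seed, hemisphere, and subject")
  Z <- do.call(rbind, lapply(run_maps, `[[`, "values"))
  nr <- nrow(Z)
  m <- colMeans(Z)
  ss <- colSums(Z^2) - nr * m^2
  s <- sqrt(pmax(ss, 0) / (nr - 1))
  tt <- rep(NA_real_, length(m))
  p <- rep(NA_real_, length(m))
  ok <- !is.na(m)
  zero_var <- ok & s < 1e-12
  reg <- ok & !zero_var
  tt[reg] <- m[reg] / (s[reg] / sqrt(nr))
  p[reg] <- 2 * pt(-abs(tt[reg]), df = nr - 1)
  p[zero_var & abs(m) > 0] <- 0
  p[zero_var & m == 0] <- 1

  structure(list(
    values = m, pvals = p, sig_mask = !is.na(p) & p < alpha,
    level = "subject", seed = key[1, 1], hemisphere = key[1, 2],
    subject_id = key[1, 3], n_runs = nr, alpha = alpha
  ), class = "zmap")
}

#' Average subject-level maps into a group map
#'
#' Per voxel, the group value is the unweighted mean over subjects of the
#' thresholded subject values: a subject contributes its mean z where its
#' significance mask is true and 0 where it is not (the zero-fill
#' convention, documented in the methods vignette). Also returns the
#' per-voxel standard error of those contributions across subjects.
#'
#' @param subject_maps List of subject-level `zmap`s sharing seed and
#'   hemisphere (at least one).
#' @return A `zmap` (level `"group"`) with `values`, `sem`, and
#'   `n_subjects`.
#' @export
group_average <- function(subject_maps) {
  if (!length(subject_maps)) stop("no subject maps to average")
  key <- unique(t(vapply(subject_maps, function(m)
    c(m$seed, m$hemisphere), character(2))))
  if (nrow(key) != 1)
    stop("subject maps must share seed and hemisphere")
  M <- do.call(rbind, lapply(subject_maps, function(m) {
    v <- ifelse(m$sig_mask, m$values, 0)
    v[is.na(m$values)] <- NA
    v
  }))
  ns <- nrow(M)
  values <- colMeans(M)
  sem <- if (ns > 1) apply(M, 2, sd) / sqrt(ns) else rep(NA_real_, ncol(M))
  structure(list(
    values = values, sem = sem, level = "group",
    seed = key[1, 1], hemisphere = key[1, 2], n_subjects = ns
  ), class = "zmap")
}

#' @export
print.zmap <- function(x, ...) {
  cat(sprintf("z-map [%s] seed %s, %s hemisphere: %d voxels (%d missing)\n",
              x$level, x$seed, x$hemisphere, length(x$values),
              sum(is.na(x$values))))
  invisible(x)
}
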