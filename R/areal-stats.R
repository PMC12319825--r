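#' Per-area ratios of connected vertices and mean supra-threshold z
#'
#' For every subject x hemisphere x area x seed cell, computes the
#' fraction of the area's vertices whose subject-level surface z exceeds
#' the threshold, and the mean z over those supra-threshold vertices
#' (missing when the ratio is 0).
#'
#' @param subject_surface_maps Nested list
#'   `[[subject_id]][[hemisphere]][[seed]]` of subject-level surface maps
#'   (numeric per-vertex vectors from [project_to_surface()]).
#' @param geometry A `vip_geometry`.
#' @param z_thr z threshold (strict `>`), default 0.05.
#' @return An `areal_ratio_table` data frame with columns `subject_id`,
#'   `hemisphere`, `area_name`, `region`, `seed`, `n_vertices`, `ratio`,
#'   `mean_z`.
#' @export
areal_ratios <- function(subject_surface_maps, geometry, z_thr = 0.05) {
  stopifnot(inherits(geometry, "vip_geometry"))
  surf <- geometry$surface
  rows <- list()
  for (subj in names(subject_surface_maps)) {
    for (h in names(subject_surface_maps[[subj]])) {
      vert_h <- surf$hemisphere == h
      for (s in names(subject_surface_maps[[subj]][[h]])) {
        v <- as.numeric(subject_surface_maps[[subj]][[h]][[s]])
        if (length(v) != nrow(surf))
          stop("surface map length does not match the vertex table")
        supra <- threshold_surface(v, z_thr)
        for (a in unique(surf$area_name[vert_h])) {
          in_area <- vert_h & surf$area_name == a
          nv <- sum(in_area)
          if (nv == 0) {
            vip_log(sprintf("area %s (%s) has no vertices; excluded", a, h))
            next
          }
          hit <- supra & in_area
          ratio <- sum(hit) / nv
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = subj, hemisphere = h, area_name = a,
            region = surf$region[which(in_area)[1]], seed = s,
            n_vertices = nv, ratio = ratio,
            mean_z = if (ratio > 0) mean(v[hit]) else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("areal_ratio_table", class(out))
  out
}

#' Across-animal summary of the areal ratio table
#'
#' Mean and standard error (sd / sqrt(n subjects)) of the per-subject
#' ratios and of the per-subject mean supra-threshold z, per hemisphere x
#' area x seed.
#'
#' @param ratios An [areal_ratios()] table.
#' @return Data frame with `hemisphere`, `area_name`, `region`, `seed`,
#'   `n_subjects`, `mean_ratio`, `sem_ratio`, `mean_z`.
#' @export
summarize_areal_ratios <- function(ratios) {
  key <- interaction(ratios$hemisphere, ratios$area_name, ratios$seed,
                     drop = TRUE)
  parts <- lapply(split(ratios, key), function(d) data.frame(
    hemisphere = d$hemisphere[1], area_name = d$area_name[1],
    region = d$region[1], seed = d$seed[1],
    n_subjects = nrow(d),
    mean_ratio = mean(d$ratio),
    sem_ratio = sd(d$ratio) / sqrt(nrow(d)),
    mean_z = if (all(is.na(d$mean_z))) NA_real_
             else mean(d$mean_z, na.rm = TRUE),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis comparison of the three seeds within each area
#'
#' Ranks the per-subject connected-vertex ratios across the three seed
#' groups within each area and computes the tie-corrected Kruskal-Wallis
#' H with a chi-square (2 df) p-value. The pooled scope concatenates the
#' two hemispheres' observations, doubling the sample per group; areas
#' whose ratios are all identical get H = 0, p = 1.
#'
#' @param ratios An [areal_ratios()] table.
#' @param scope `"left"`, `"right"`, or `"pooled"`.
#' @param bh_alpha Significance level applied after Benjamini-Hochberg
#'   correction across areas.
#' @return An `areal_test_table` data frame: `area_name`, `scope`, `H`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
kruskal_wallis_per_area <- function(ratios, scope = c("pooled", "left", "right"),
                                    bh_alpha = 0.05) {
  scope <- match.arg(scope)
  d <- if (scope == "pooled") ratios else ratios[ratios$hemisphere == scope, ]
  areas <- unique(d$area_name)
  res <- lapply(areas, function(a) {
    da <- d[d$area_name == a, ]
    if (length(unique(da$seed)) < 2 || nrow(da) < 3)
      stop(sprintf("area %s: not enough groups/observations for a test", a))
    if (length(unique(da$ratio)) == 1) {
      h <- 0; p <- 1
    } else {
      kt <- kruskal.test(da$ratio, factor(da$seed))
      h <- unname(kt$statistic); p <- kt$p.value
    }
    data.frame(area_name = a, scope = scope, H = h, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_correct(out$p_raw)
  out$significant <- out$p_adj < bh_alpha
  class(out) <- c("areal_test_table", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `p.adjust(method = "BH")`: adjusted p-values are the
#' running minima of `m * p_(j) / j` from the largest rank downward,
#' capped at 1 and returned in the input order.
#'
#' @param p_raw Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_correct <- function(p_raw) {
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_raw, method = "BH")
}

#' Classify each area's anterior-versus-posterior seed preference
#'
#' Implements the display rule for seed preference: areas significant in
#' both hemispheres or in the pooled test are assigned the seed (aVIP or
#' pVIP) with the higher pooled mean ratio — or `both` when the two are
#' within `tie_tol` relative difference; areas significant in exactly one
#' hemisphere are judged on the average supra-threshold z instead; areas
#' significant nowhere get `none`. The middle seed is never preferred.
#'
#' @param tests Row-bound [kruskal_wallis_per_area()] tables for the
#'   `left`, `right`, and `pooled` scopes.
#' @param summary A [summarize_areal_ratios()] table.
#' @param tie_tol Relative difference below which aVIP and pVIP are
#'   called `both`.
#' @return A `preference_table` data frame: `area_name`, `preferred`
#'   (`aVIP`, `pVIP`, `both`, `none`), `basis` (`significant_test`,
#'   `mean_z_tiebreak`, or `none`).
#' @export
classify_preference <- function(tests, summary, tie_tol = 0.1) {
  need <- c("left", "right", "pooled")
  if (!all(need %in% tests$scope))
    stop("tests must cover the left, right, and pooled scopes")
  areas <- unique(tests$area_name)

  pick <- function(qa, qp) {
    if (is.na(qa)) qa <- 0
    if (is.na(qp)) qp <- 0
    if (qa == 0 && qp == 0) return("none")
    if (abs(qa - qp) <= tie_tol * max(qa, qp)) "both"
    else if (qa > qp) "aVIP" else "pVIP"
  }

  rows <- lapply(areas, function(a) {
    sig <- vapply(need, function(sc)
      any(tests$significant[tests$area_name == a & tests$scope == sc]),
      logical(1))
    sa <- summary[summary$area_name == a, ]
    pooled_stat <- function(col, seed)
      mean(sa[[col]][sa$seed == seed], na.rm = TRUE)
    if ((sig["left"] && sig["right"]) || sig["pooled"]) {
      pref <- pick(pooled_stat("mean_ratio", "aVIP"),
                   pooled_stat("mean_ratio", "pVIP"))
      basis <- "significant_test"
    } else if (xor(sig["left"], sig["right"])) {
      pref <- pick(pooled_stat("mean_z", "aVIP"),
                   pooled_stat("mean_z", "pVIP"))
      basis <- "mean_z_tiebreak"
    } else {
      pref <- "none"
      basis <- "none"
    }
    data.frame(area_name = a, preferred = pref, basis = basis,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("preference_table", class(out))
  out
}
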