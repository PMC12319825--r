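#' Run the full phantom-to-statistics pipeline
#'
#' Orchestrates the whole analysis in a fixed stage order — simulate,
#' preprocess, connectivity, surface, stats — entirely in memory:
#'
#' 1. **simulate**: build geometry and plant the ground-truth design.
#' 2. **preprocess**: per run, scrub, band-pass, and nuisance-regress.
#' 3. **connectivity**: per run and seed, seed-signal extraction,
#'    correlation map, Fisher z, optional map smoothing; per subject,
#'    run-level aggregation with one-sample t-tests at `alpha`; group
#'    averaging with the zero-fill convention.
#' 4. **surface**: projection of group maps to the vertex table,
#'    thresholding at `z_thr` (plus the sweep), eight-way categorization,
#'    composition tables, and pairwise Spearman map similarity.
#' 5. **stats**: per-area connected-vertex ratios from the subject maps,
#'    Kruskal-Wallis per area for the left/right/pooled scopes with
#'    Benjamini-Hochberg correction, seed-preference classification, and
#'    recovery scoring against the planted truth.
#'
#' Rerunning with an identical spec and configuration reproduces
#' identical outputs: every random draw is seeded from the spec.
#'
#' @param spec A [phantom_spec()].
#' @param settings A [filter_settings()].
#' @param alpha Per-voxel significance level of the subject-level t-test.
#' @param z_thr Surface z threshold for categorization and ratios.
#' @param z_sweep Thresholds for the robustness sweep.
#' @param bh_alpha Significance level after Benjamini-Hochberg correction.
#' @param smooth_stage Where spatial smoothing is applied: `"map"`
#'   (z-maps, default) or `"timeseries"`.
#' @param seed_agg Seed-signal aggregation, `"mean"` or `"first_pc"`.
#' @return A `vip_pipeline` list; see Details. Key elements:
#'   `group_maps`, `categories` (per-vertex `category_map`),
#'   `composition_hemisphere`, `composition_region`, `similarity`,
#'   `areal` (ratios, summary, tests, preference), `recovery`, `sweep`,
#'   `stages`, `config`.
#' @export
run_pipeline <- function(spec,
                         settings = filter_settings(voxel_mm = spec$voxel_mm),
                         alpha = 0.001,
                         z_thr = 0.05,
                         z_sweep = c(0.03, 0.05, 0.07),
                         bh_alpha = 0.05,
                         smooth_stage = c("map", "timeseries"),
                         seed_agg = c("mean", "first_pc")) {
  stopifnot(inherits(spec, "phantom_spec"))
  smooth_stage <- match.arg(smooth_stage)
  seed_agg <- match.arg(seed_agg)
  if (z_thr <= 0 || any(z_sweep <= 0)) stop("z thresholds must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stages <- list()
  clock <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    list(res = res, secs = proc.time()[["elapsed"]] - t0)
  }

  ## stage 1: simulate (geometry + truth; runs are generated lazily below)
  st <- clock({
    geometry <- make_geometry(spec)
    truth <- plant_design(spec, geometry)
    list(geometry = geometry, truth = truth)
  })
  geometry <- st$res$geometry
  truth <- st$res$truth
  stages$simulate <- data.frame(stage = "simulate",
                                n_records = geometry$n_voxels,
                                seconds = st$secs)

  ## stages 2+3: preprocess and connectivity, streamed run by run
  combos <- expand.grid(seed = seed_names(), hemisphere = hemi_names(),
                        stringsAsFactors = FALSE)
  subject_maps <- list()   # [[combo]][[subject]] subject-level zmap
  for (ci in seq_len(nrow(combos)))
    subject_maps[[paste(combos$seed[ci], combos$hemisphere[ci])]] <- list()
  n_runs_used <- 0L
  n_runs_excluded <- 0L
  subjects_dropped <- character(0)
  t_pre <- 0
  t_conn <- 0

  for (subj in seq_len(spec$n_subjects)) {
    run_maps <- lapply(seq_len(nrow(combos)), function(i) list())
    names(run_maps) <- paste(combos$seed, combos$hemisphere)
    for (r in seq_len(spec$runs_per_subject[subj])) {
      st <- clock({
        run <- simulate_run(spec, geometry, truth, subj, r)
        preprocess_run(run, settings, geometry, smooth_stage)
      })
      t_pre <- t_pre + st$secs
      run <- st$res
      if (is.null(run)) {
        n_runs_excluded <- n_runs_excluded + 1L
        next
      }
      n_runs_used <- n_runs_used + 1L
      st <- clock({
        for (ci in seq_len(nrow(combos))) {
          s <- combos$seed[ci]
          h <- combos$hemisphere[ci]
          sig <- extract_seed_signal(run, geometry$seeds[[h]][[s]],
                                     agg = seed_agg)
          zm <- run_correlation_map(run, sig, h, geometry, seed = s)
          if (smooth_stage == "map")
            zm$values <- smooth_volume(zm$values, geometry, settings)
          key <- paste(s, h)
          run_maps[[key]][[length(run_maps[[key]]) + 1L]] <- zm
        }
        NULL
      })
      t_conn <- t_conn + st$secs
    }
    if (length(run_maps[[1]]) < 2) {
      subjects_dropped <- c(subjects_dropped, sprintf("sub-%02d", subj))
      vip_log(sprintf("sub-%02d dropped: fewer than 2 usable runs", subj))
      next
    }
    st <- clock({
      for (key in names(run_maps))
        subject_maps[[key]][[sprintf("sub-%02d", subj)]] <-
          subject_aggregate(run_maps[[key]], alpha = alpha)
      NULL
    })
    t_conn <- t_conn + st$secs
  }
  stages$preprocess <- data.frame(stage = "preprocess",
                                  n_records = n_runs_used,
                                  seconds = t_pre)
  stages$connectivity <- data.frame(stage = "connectivity",
                                    n_records = length(subject_maps[[1]]) *
                                      nrow(combos),
                                    seconds = t_conn)

  ## stage 4: group maps, surface categorization, similarity
  st <- clock({
    group_maps <- lapply(subject_maps, group_average)

    # per-seed surface maps joining both hemispheres (each group map is
    # NA off its own hemisphere, so elementwise combination is exact)
    seed_surface <- lapply(seed_names(), function(s) {
      l <- project_to_surface(group_maps[[paste(s, "left")]], geometry)
      r <- project_to_surface(group_maps[[paste(s, "right")]], geometry)
      ifelse(is.na(l), as.numeric(r), as.numeric(l))
    })
    names(seed_surface) <- seed_names()

    bins <- lapply(seed_surface, threshold_surface, z_thr = z_thr)
    categories <- categorize(bins$aVIP, bins$mVIP, bins$pVIP,
                             threshold_used = z_thr)

    sweep_counts <- do.call(rbind, lapply(sort(z_sweep), function(zt) {
      data.frame(z_thr = zt,
                 seed = seed_names(),
                 n_connected = vapply(seed_surface, function(v)
                   sum(threshold_surface(v, zt)), integer(1)),
                 row.names = NULL)
    }))

    pairs <- list(c("aVIP", "mVIP"), c("mVIP", "pVIP"), c("aVIP", "pVIP"))
    similarity <- do.call(rbind, lapply(hemi_names(), function(h) {
      vert_h <- geometry$surface$hemisphere == h
      do.call(rbind, lapply(pairs, function(pr) {
        v1 <- seed_surface[[pr[1]]]
        v2 <- seed_surface[[pr[2]]]
        v1[!vert_h] <- NA
        v2[!vert_h] <- NA
        sim <- map_similarity(v1, v2)
        data.frame(hemisphere = h, seed1 = pr[1], seed2 = pr[2],
                   rho = sim$rho, p = sim$p, n = sim$n,
                   stringsAsFactors = FALSE)
      }))
    }))

    list(group_maps = group_maps, seed_surface = seed_surface,
         categories = categories,
         composition_hemisphere = composition(categories, geometry,
                                              "hemisphere"),
         composition_region = composition(categories, geometry, "region"),
         sweep = sweep_counts, similarity = similarity)
  })
  surface_res <- st$res
  stages$surface <- data.frame(stage = "surface",
                               n_records = nrow(geometry$surface),
                               seconds = st$secs)

  ## stage 5: areal statistics and recovery scoring
  st <- clock({
    subj_surface <- list()
    for (subj_id in names(subject_maps[[1]])) {
      subj_surface[[subj_id]] <- list()
      for (h in hemi_names()) {
        subj_surface[[subj_id]][[h]] <- list()
        for (s in seed_names()) {
          m <- subject_maps[[paste(s, h)]][[subj_id]]
          masked <- ifelse(m$sig_mask, m$values, 0)
          masked[is.na(m$values)] <- NA
          subj_surface[[subj_id]][[h]][[s]] <-
            project_to_surface(masked, geometry)
        }
      }
    }
    ratios <- areal_ratios(subj_surface, geometry, z_thr = z_thr)
    summary <- summarize_areal_ratios(ratios)
    tests <- do.call(rbind, lapply(c("left", "right", "pooled"), function(sc)
      kruskal_wallis_per_area(ratios, sc, bh_alpha = bh_alpha)))
    preference <- classify_preference(tests, summary)
    recovery <- score_recovery(surface_res$categories, truth, geometry)
    list(ratios = ratios, summary = summary, tests = tests,
         preference = preference, recovery = recovery)
  })
  stats_res <- st$res
  stages$stats <- data.frame(stage = "stats",
                             n_records = nrow(stats_res$ratios),
                             seconds = st$secs)

  structure(list(
    geometry = geometry,
    truth = truth,
    subject_maps = subject_maps,
    group_maps = surface_res$group_maps,
    seed_surface = surface_res$seed_surface,
    categories = surface_res$categories,
    composition_hemisphere = surface_res$composition_hemisphere,
    composition_region = surface_res$composition_region,
    sweep = surface_res$sweep,
    similarity = surface_res$similarity,
    areal = stats_res[c("ratios", "summary", "tests", "preference")],
    recovery = stats_res$recovery,
    stages = do.call(rbind, stages),
    excluded = list(runs = n_runs_excluded, subjects = subjects_dropped),
    config = list(alpha = alpha, z_thr = z_thr, z_sweep = sort(z_sweep),
                  bh_alpha = bh_alpha, smooth_stage = smooth_stage,
                  seed_agg = seed_agg, settings = settings,
                  rng_seed = spec$rng_seed)
  ), class = "vip_pipeline")
}

#' Score recovery of the planted vertex categories
#'
#' Maps the ground-truth voxel categories onto the surface through the
#' projection (each vertex inherits its unique source voxel's category)
#' and compares them with an estimated category map.
#'
#' @param estimated A `category_map` over the geometry's vertices.
#' @param truth A `vip_truth`.
#' @param geometry The matching `vip_geometry`.
#' @return `list(accuracy, confusion, sensitivity)`: overall vertex
#'   accuracy in `[0, 1]`, the 8 x 8 confusion table (rows = truth,
#'   columns = estimate; rows sum to the per-category truth counts), and
#'   per-category sensitivity.
#' @export
score_recovery <- function(estimated, truth, geometry) {
  stopifnot(inherits(truth, "vip_truth"), inherits(geometry, "vip_geometry"))
  if (length(estimated) != nrow(geometry$surface))
    stop("estimated category map does not match the geometry's vertex set")
  truth_vertex <- truth$category[geometry$surface$voxel]
  est <- factor(as.character(estimated), levels = category_levels())
  confusion <- table(truth = truth_vertex, estimate = est)
  accuracy <- mean(as.character(truth_vertex) == as.character(est))
  sens <- diag(confusion) / rowSums(confusion)
  list(accuracy = accuracy, confusion = confusion, sensitivity = sens)
}

#' @export
print.vip_pipeline <- function(x, ...) {
  cat("VIP gradient pipeline result\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("Category recovery accuracy: %.3f\n", x$recovery$accuracy))
  inv <- x$similarity
  for (h in unique(inv$hemisphere)) {
    d <- inv[inv$hemisphere == h, ]
    cat(sprintf("Spearman rho (%s): a-m %.2f, m-p %.2f, a-p %.2f\n", h,
                d$rho[d$seed1 == "aVIP" & d$seed2 == "mVIP"],
                d$rho[d$seed1 == "mVIP" & d$seed2 == "pVIP"],
                d$rho[d$seed1 == "aVIP" & d$seed2 == "pVIP"]))
  }
  invisible(x)
}
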