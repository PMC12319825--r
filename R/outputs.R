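#' Write a z-map as a NIfTI volume with a JSON sidecar
#'
#' Serializes the map's values into the geometry's grid (missing voxels
#' as NaN) and records level, seed, hemisphere, subject, the t-test
#' alpha, and run count in a sidecar JSON next to the volume.
#'
#' @param zmap A `zmap` at any level.
#' @param geometry The matching `vip_geometry`.
#' @param path Output path ending in `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_zmap <- function(zmap, geometry, path) {
  stopifnot(inherits(zmap, "zmap"), inherits(geometry, "vip_geometry"))
  vol <- as_volume(zmap$values, geometry, fill = NaN)
  write_nifti_vol(vol, path, geometry$voxel_mm)
  side <- list(level = zmap$level, seed = zmap$seed,
               hemisphere = zmap$hemisphere,
               subject_id = zmap$subject_id %||% NULL,
               alpha = zmap$alpha %||% NULL,
               n_runs = zmap$n_runs %||% NULL,
               n_subjects = zmap$n_subjects %||% NULL)
  side <- side[!vapply(side, is.null, logical(1))]
  jsonlite::write_json(side, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write the pipeline's tabular outputs
#'
#' Serializes a [run_pipeline()] result the way the pipeline's consumers
#' expect it: group z-maps as NIfTI volumes with JSON sidecars
#' (`group_<seed>_<hemisphere>.nii.gz`), the per-vertex surface values
#' and category map as TSV (with hex display colors), composition tables
#' and areal statistics as CSV (`areal_ratios.csv`, `areal_tests.csv`,
#' `preference.csv`), and a JSON run manifest recording every threshold
#' actually applied.
#'
#' @param result A `vip_pipeline`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
save_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "vip_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- result$geometry
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)

  for (key in names(result$group_maps)) {
    m <- result$group_maps[[key]]
    p <- file.path(dir, sprintf("group_%s_%s.nii.gz", m$seed, m$hemisphere))
    add(write_zmap(m, g, p))
  }

  surf <- data.frame(vertex_id = g$surface$vertex_id,
                     hemisphere = g$surface$hemisphere,
                     region = g$surface$region,
                     area_name = g$surface$area_name)
  for (s in names(result$seed_surface))
    surf[[paste0("z_", s)]] <- as.numeric(result$seed_surface[[s]])
  add(write_tsv(surf, file.path(dir, "surface_maps.tsv")))

  cats <- data.frame(vertex_id = g$surface$vertex_id,
                     category = as.character(result$categories),
                     hex = rgb_encode(result$categories)$hex)
  add(write_tsv(cats, file.path(dir, "category_map.tsv")))
  jsonlite::write_json(list(threshold_used =
                              attr(result$categories, "threshold_used")),
                       file.path(dir, "category_map.json"),
                       auto_unbox = TRUE)
  add(file.path(dir, "category_map.json"))

  write.csv(result$composition_hemisphere,
            file.path(dir, "composition_hemisphere.csv"), row.names = FALSE)
  add(file.path(dir, "composition_hemisphere.csv"))
  write.csv(result$composition_region,
            file.path(dir, "composition_region.csv"), row.names = FALSE)
  add(file.path(dir, "composition_region.csv"))
  write.csv(result$areal$ratios, file.path(dir, "areal_ratios.csv"),
            row.names = FALSE)
  add(file.path(dir, "areal_ratios.csv"))
  write.csv(result$areal$tests, file.path(dir, "areal_tests.csv"),
            row.names = FALSE)
  add(file.path(dir, "areal_tests.csv"))
  write.csv(result$areal$preference, file.path(dir, "preference.csv"),
            row.names = FALSE)
  add(file.path(dir, "preference.csv"))

  manifest <- c(result$config[c("alpha", "z_thr", "z_sweep", "bh_alpha",
                                "smooth_stage", "seed_agg", "rng_seed")],
                list(band_hz = result$config$settings$band_hz,
                     fwhm_mm = result$config$settings$fwhm_mm,
                     fd_threshold_mm = result$config$settings$fd_threshold_mm,
                     excluded_runs = result$excluded$runs,
                     dropped_subjects = result$excluded$subjects,
                     stages = result$stages$stage))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  add(file.path(dir, "run_manifest.json"))
  invisible(paths)
}
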