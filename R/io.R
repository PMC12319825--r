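# On-disk phantom layout: NIfTI volumes plus TSV sidecars, BIDS-like
# naming (sub-XX_run-YY_bold.nii.gz, nuisance_sub-XX_run-YY.tsv).

as_volume <- function(values, geometry, fill = 0) {
  vol <- array(fill, geometry$dims)
  vol[which(geometry$mask)] <- values
  vol
}

write_nifti_vol <- function(vol, path, voxel_mm, tr = NULL) {
  img <- RNifti::asNifti(vol)
  pd <- if (length(dim(vol)) == 4) c(voxel_mm, voxel_mm, voxel_mm, tr %||% 1)
        else rep(voxel_mm, 3)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete phantom dataset to disk
#'
#' Generates the phantom defined by `spec` and serializes it in an open
#' layout: per-run 4D NIfTI bold series, mask and atlas label volumes,
#' area/seed/projection/ground-truth TSV tables, per-run nuisance traces,
#' a run manifest, and the spec itself as JSON.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the run manifest data frame.
#' @export
write_phantom <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geometry <- make_geometry(spec)
  truth <- plant_design(spec, geometry)

  write_nifti_vol(as_volume(rep(1L, geometry$n_voxels), geometry),
                  file.path(out_dir, "mask.nii.gz"), spec$voxel_mm)
  write_nifti_vol(as_volume(geometry$voxels$area_id, geometry),
                  file.path(out_dir, "atlas.nii.gz"), spec$voxel_mm)
  write_tsv(geometry$areas, file.path(out_dir, "areas.tsv"))

  seeds <- do.call(rbind, lapply(hemi_names(), function(h)
    do.call(rbind, lapply(seed_names(), function(s) {
      v <- geometry$seeds[[h]][[s]]
      data.frame(seed = s, hemisphere = h,
                 i = geometry$voxels$i[v], j = geometry$voxels$j[v],
                 k = geometry$voxels$k[v])
    }))))
  write_tsv(seeds, file.path(out_dir, "seeds.tsv"))

  proj <- data.frame(
    i = geometry$voxels$i[geometry$surface$voxel],
    j = geometry$voxels$j[geometry$surface$voxel],
    k = geometry$voxels$k[geometry$surface$voxel],
    vertex_id = geometry$surface$vertex_id)
  write_tsv(proj, file.path(out_dir, "projection.tsv"))
  write_tsv(geometry$surface[, c("vertex_id", "hemisphere", "region",
                                 "area_id", "area_name")],
            file.path(out_dir, "vertices.tsv"))

  gt <- data.frame(geometry$voxels[, c("i", "j", "k")],
                   w_a = truth$loadings[, 1], w_m = truth$loadings[, 2],
                   w_p = truth$loadings[, 3],
                   category = as.character(truth$category))
  write_tsv(gt, file.path(out_dir, "ground_truth.tsv"))

  manifest <- list()
  for (subj in seq_len(spec$n_subjects)) {
    for (r in seq_len(spec$runs_per_subject[subj])) {
      run <- simulate_run(spec, geometry, truth, subj, r)
      bold <- file.path(out_dir,
                        sprintf("%s_%s_bold.nii.gz", run$subject_id, run$run_id))
      vol4 <- array(0, c(geometry$dims, nrow(run$data)))
      midx <- which(geometry$mask)
      nvol <- prod(geometry$dims)
      for (t in seq_len(nrow(run$data)))
        vol4[(t - 1L) * nvol + midx] <- run$data[t, ]
      write_nifti_vol(vol4, bold, spec$voxel_mm, tr = run$tr_seconds)
      nuis <- file.path(out_dir, sprintf("nuisance_%s_%s.tsv",
                                         run$subject_id, run$run_id))
      write_tsv(data.frame(frame = seq_len(nrow(run$data)), run$nuisance),
                nuis)
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject_id = run$subject_id, session_id = 1L, run_id = run$run_id,
        n_frames = nrow(run$data), tr_seconds = run$tr_seconds,
        bold_path = basename(bold), nuisance_path = basename(nuis),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  spec_json <- spec
  class(spec_json) <- NULL
  jsonlite::write_json(spec_json, file.path(out_dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Validate an on-disk phantom directory
#'
#' Checks the NIfTI headers (grid dimensions, TR), the TSV schemas, the
#' projection's vertex uniqueness, and seed/mask containment,
#' distinguishing fatal findings from warnings.
#'
#' @param dir A directory written by [write_phantom()] (or laid out the
#'   same way).
#' @return A data frame of findings with columns `level` (`"fatal"` or
#'   `"warning"`) and `message`; zero rows means a clean layout.
#' @export
validate_inputs <- function(dir) {
  findings <- list()
  note <- function(level, msg)
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)

  need <- c("mask.nii.gz", "atlas.nii.gz", "areas.tsv", "seeds.tsv",
            "projection.tsv", "manifest.tsv", "phantom_spec.json")
  for (f in need)
    if (!file.exists(file.path(dir, f))) note("fatal", paste("missing file:", f))
  if (length(findings)) return(do.call(rbind, findings))

  spec_json <- jsonlite::read_json(file.path(dir, "phantom_spec.json"),
                                   simplifyVector = TRUE)
  mask <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  atlas <- RNifti::readNifti(file.path(dir, "atlas.nii.gz"))
  if (!identical(dim(mask), dim(atlas)))
    note("fatal", sprintf("shape mismatch: mask %s vs atlas %s",
                          paste(dim(mask), collapse = "x"),
                          paste(dim(atlas), collapse = "x")))

  seeds <- read.delim(file.path(dir, "seeds.tsv"))
  areas <- read.delim(file.path(dir, "areas.tsv"))
  vip_ids <- areas$area_id[areas$area_name == "VIP"]
  for (i in seq_len(nrow(seeds))) {
    co <- as.integer(seeds[i, c("i", "j", "k")])
    if (any(co < 1) || any(co > dim(mask)) || mask[co[1], co[2], co[3]] == 0)
      note("fatal", sprintf("seed voxel outside mask: %s %s (%d, %d, %d)",
                            seeds$seed[i], seeds$hemisphere[i],
                            co[1], co[2], co[3]))
    else if (!(atlas[co[1], co[2], co[3]] %in% vip_ids))
      note("fatal", sprintf("seed voxel not VIP-labeled: %s %s (%d, %d, %d)",
                            seeds$seed[i], seeds$hemisphere[i],
                            co[1], co[2], co[3]))
  }

  proj <- read.delim(file.path(dir, "projection.tsv"))
  if (anyDuplicated(proj$vertex_id))
    note("fatal", "projection assigns some vertex to more than one voxel")

  manifest <- read.delim(file.path(dir, "manifest.tsv"))
  for (i in seq_len(nrow(manifest))) {
    bold_path <- file.path(dir, manifest$bold_path[i])
    if (!file.exists(bold_path)) {
      note("fatal", paste("missing bold file:", manifest$bold_path[i]))
      next
    }
    hdr <- RNifti::niftiHeader(bold_path)
    d <- hdr$dim[2:5]
    if (!identical(d[1:3], as.integer(dim(mask))))
      note("fatal", sprintf("shape mismatch between bold and mask in %s",
                            manifest$bold_path[i]))
    if (d[4] != manifest$n_frames[i])
      note("warning", sprintf("frame count header %d vs manifest %d in %s",
                              d[4], manifest$n_frames[i],
                              manifest$bold_path[i]))
    if (abs(hdr$pixdim[5] - manifest$tr_seconds[i]) > 1e-6)
      note("warning", sprintf("TR mismatch header %.3g vs manifest %.3g in %s %s",
                              hdr$pixdim[5], manifest$tr_seconds[i],
                              manifest$subject_id[i], manifest$run_id[i]))
    nuis_path <- file.path(dir, manifest$nuisance_path[i])
    if (!file.exists(nuis_path))
      note("fatal", paste("missing nuisance file:", manifest$nuisance_path[i]))
  }

  if (length(findings)) do.call(rbind, findings)
  else data.frame(level = character(0), message = character(0))
}

#' Read a phantom run from disk
#'
#' Loads one bold series and its nuisance traces from a directory written
#' by [write_phantom()] into a `run_ts` on the given geometry's voxel
#' ordering.
#'
#' @param dir Phantom directory.
#' @param manifest_row One row of the directory's manifest.
#' @param geometry The matching `vip_geometry`.
#' @return A `run_ts` (without latents or spike bookkeeping).
#' @export
read_phantom_run <- function(dir, manifest_row, geometry) {
  vol4 <- RNifti::readNifti(file.path(dir, manifest_row$bold_path))
  n <- dim(vol4)[4]
  midx <- which(geometry$mask)
  nvol <- prod(geometry$dims)
  data <- matrix(0, n, length(midx))
  for (t in seq_len(n)) data[t, ] <- vol4[(t - 1L) * nvol + midx]
  if (any(!is.finite(data))) stop("non-finite values in bold series")
  nuis <- read.delim(file.path(dir, manifest_row$nuisance_path))
  if (nrow(nuis) != n) stop("nuisance trace length does not match frames")
  structure(list(
    data = data,
    tr_seconds = manifest_row$tr_seconds,
    subject_id = manifest_row$subject_id,
    run_id = manifest_row$run_id,
    nuisance = nuis[, c("wm", "csf", "fd")],
    censor = rep(TRUE, n),
    spike_frames = integer(0),
    latents = NULL
  ), class = "run_ts")
}
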