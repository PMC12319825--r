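test_that("phantom spec validation rejects out-of-range parameters", {
  expect_error(phantom_spec(frames_per_run = 32), "64")
  expect_error(phantom_spec(noise_sd = -1), ">= 0")
  expect_error(phantom_spec(spike_prob = 1), "spike_prob")
  expect_error(phantom_spec(latent_band = c(0.01, 0.3), tr_seconds = 2),
               "Nyquist")
  expect_error(phantom_spec(latent_band = c(0.1, 0.01)), "increasing")
  expect_error(tiny_spec(area_design = list(area01 = c(-1, 0, 0))),
               "missing|negative")
  bad <- tiny_design()
  bad$area02 <- c(-0.5, 0, 0)
  expect_error(tiny_spec(area_design = bad), "negative weight")
})

test_that("default area design covers every area and all eight categories", {
  spec <- phantom_spec()
  expect_setequal(names(spec$area_design), area_names(spec))
  cats <- vapply(spec$area_design, function(w)
    as.character(loading_category(matrix(w, 1))), character(1))
  expect_setequal(unique(cats), category_levels())
})

test_that("geometry partitions the mask into areas and regions", {
  g <- tiny_geom()
  # every in-mask voxel has exactly one area; union of areas = mask
  expect_equal(nrow(g$voxels), sum(g$mask))
  expect_false(any(is.na(g$voxels$area_id)))
  counts <- table(g$voxels$area_id)
  expect_equal(sum(counts), g$n_voxels)
  expect_true(all(counts >= 8))
  # every area belongs to exactly one region
  expect_equal(anyDuplicated(g$areas$area_id), 0L)
  per_area_regions <- tapply(g$voxels$region, g$voxels$area_id,
                             function(r) length(unique(r)))
  expect_true(all(per_area_regions == 1))
  expect_setequal(unique(g$voxels$hemisphere), c("left", "right"))
})

test_that("degenerate one-area parcellation labels every voxel identically", {
  spec <- phantom_spec(n_subjects = 1, grid_dims = c(12, 14, 8), n_areas = 1,
                       area_design = list(VIP = c(0.5, 0.5, 0.5)))
  g <- make_geometry(spec)
  expect_equal(unique(g$voxels$area_name), "VIP")
  expect_equal(length(unique(g$voxels$area_id)), 2) # one label per hemisphere
})

test_that("undersized grids raise a sizing error naming the area", {
  spec <- tiny_spec()
  spec$grid_dims <- c(2, 14, 2)
  expect_error(make_geometry(spec), "grid too small")
})

test_that("seed ROIs have the prescribed sizes and slice layout", {
  g <- tiny_geom()
  for (h in c("left", "right")) {
    sizes <- lengths(g$seeds[[h]])
    expect_equal(unname(sizes), c(20L, 20L, 20L))
    # disjoint within hemisphere
    all_vox <- unlist(g$seeds[[h]])
    expect_equal(anyDuplicated(all_vox), 0L)
    # all inside the VIP label
    expect_true(all(g$voxels$area_name[all_vox] == "VIP"))
    # mVIP strictly between aVIP and pVIP along the antero-posterior axis
    ya <- g$voxels$j[g$seeds[[h]]$aVIP]
    ym <- g$voxels$j[g$seeds[[h]]$mVIP]
    yp <- g$voxels$j[g$seeds[[h]]$pVIP]
    expect_lt(max(ya), min(ym))
    expect_lt(max(ym), min(yp))
    # slice structure: aVIP/mVIP 4 slices x 5, pVIP 5 slices x 4
    expect_equal(length(unique(ya)), 4L)
    expect_equal(length(unique(ym)), 4L)
    expect_equal(length(unique(yp)), 5L)
  }
})

test_that("custom seed schemes work down to a singleton ROI", {
  g0 <- tiny_geom()
  rois <- suppressWarnings(
    build_seed_rois(g0, list(aVIP = c(1, 1), mVIP = c(1, 1), pVIP = c(1, 1))))
  expect_equal(lengths(rois$left), c(aVIP = 1L, mVIP = 1L, pVIP = 1L))
  # a scheme needing more slices than the VIP label spans must fail loudly
  expect_error(suppressWarnings(
    build_seed_rois(g0, list(aVIP = c(10, 5), mVIP = c(10, 5), pVIP = c(10, 4)))),
    "insufficient VIP")
})

test_that("projection gives every voxel >= 1 vertex and every vertex one voxel", {
  g <- tiny_geom()
  expect_setequal(unique(g$surface$voxel), seq_len(g$n_voxels))
  expect_equal(anyDuplicated(g$surface$vertex_id), 0L)
  per_voxel <- table(g$surface$voxel)
  expect_true(all(per_voxel >= 1 & per_voxel <= 3))
})

test_that("geometry and truth are deterministic for a fixed spec", {
  s1 <- tiny_spec()
  s2 <- tiny_spec()
  expect_identical(make_geometry(s1), make_geometry(s2))
  expect_identical(plant_design(s1, tiny_geom()),
                   plant_design(s2, tiny_geom()))
})

test_that("planted loadings imply the stated categories", {
  tr <- tiny_truth()
  g <- tiny_geom()
  # category is a pure function of the loading zero-pattern
  expect_identical(tr$category, loading_category(tr$loadings))
  # per-area constancy away from seed voxels
  seed_vox <- unlist(lapply(g$seeds, unlist))
  free <- setdiff(seq_len(g$n_voxels), seed_vox)
  a1 <- free[g$voxels$area_name[free] == "area01"]
  expect_true(all(tr$category[a1] == "NONE"))
  a2 <- free[g$voxels$area_name[free] == "area02"]
  expect_true(all(tr$category[a2] == "A"))
  vip <- free[g$voxels$area_name[free] == "VIP"]
  expect_true(all(tr$category[vip] == "AMP"))
  # seed voxels load maximally on their own latent only
  for (h in c("left", "right"))
    for (s in c("aVIP", "mVIP", "pVIP")) {
      L <- tr$loadings[g$seeds[[h]][[s]], , drop = FALSE]
      expect_true(all(L[, s] == 1))
      expect_true(all(L[, setdiff(colnames(L), s)] == 0))
      expect_true(all(tr$category[g$seeds[[h]][[s]]] ==
                        c(aVIP = "A", mVIP = "M", pVIP = "P")[[s]]))
    }
})

test_that("latent signals are band-limited with unit variance", {
  set.seed(1)
  n <- 200; tr_s <- 2
  s <- band_limited_signals(n, 3, tr_s, c(0.01, 0.1))
  expect_equal(apply(s, 2, sd), rep(1, 3))
  expect_equal(colMeans(s), rep(0, 3), tolerance = 1e-12)
  # >= 95% of spectral power inside the band (here: all of it)
  for (j in 1:3) {
    pw <- Mod(fft(s[, j]))^2
    freqs <- seq(0, n - 1) / (n * tr_s)
    freqs <- pmin(freqs, 1 / tr_s - freqs)
    in_band <- freqs >= 0.01 & freqs <= 0.1
    expect_gte(sum(pw[in_band]) / sum(pw), 0.95)
  }
})

test_that("noiseless voxels reproduce their latent signal exactly", {
  spec <- clean_spec()
  g <- make_geometry(spec)
  tr <- plant_design(spec, g)
  run <- simulate_run(spec, g, tr, 1, 1)
  # a pure-anterior voxel (loading (1,0,0)): series equals s_a
  v <- which(tr$loadings[, 1] == 1 & tr$loadings[, 2] == 0 &
               tr$loadings[, 3] == 0)[1]
  expect_equal(run$data[, v], unname(run$latents[, "aVIP"]))
  expect_equal(cor(run$data[, v], run$latents[, "aVIP"]), 1)
})

test_that("null voxels are uncorrelated with the latents (Monte-Carlo)", {
  # 1000 independent null voxels against one latent; |r| < 3/sqrt(n)
  # should hold in ~99% of draws (normal-approximation null)
  set.seed(99)
  n <- 96
  s <- band_limited_signals(n, 1, 2, c(0.01, 0.1))[, 1]
  noise <- matrix(rnorm(n * 1000), n)
  r <- abs(drop(cor(s, noise)))
  expect_gte(mean(r < 3 / sqrt(n)), 0.97)
  expect_lt(mean(r), 2 / sqrt(n))
})

test_that("spike counts follow the planted Binomial law", {
  spec <- tiny_spec(spike_prob = 0.05)
  g <- tiny_geom()
  tr <- plant_design(spec, g)
  counts <- integer(0)
  for (subj in 1:3) for (r in 1:8) {
    run <- simulate_run(spec, g, tr, subj, r)
    counts <- c(counts, length(run$spike_frames))
    # fd is elevated exactly at spike frames
    expect_identical(which(run$nuisance$fd > 0.5), run$spike_frames)
  }
  total <- sum(counts)
  n_frames <- 24 * 96
  ci <- qbinom(c(0.005, 0.995), n_frames, 0.05)
  expect_gte(total, ci[1])
  expect_lte(total, ci[2])
})

test_that("runs are reproducible from their (subject, run) identity", {
  spec <- tiny_spec()
  g <- tiny_geom()
  tr <- tiny_truth()
  r1 <- simulate_run(spec, g, tr, 2, 3)
  r2 <- simulate_run(spec, g, tr, 2, 3)
  expect_identical(r1, r2)
  r3 <- simulate_run(spec, g, tr, 2, 4)
  expect_false(identical(r1$data, r3$data))
})
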