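# Shared small fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# design covering all 8 categories on an 8-area parcellation (area07 = VIP)
tiny_design <- function() {
  nm <- sprintf("area%02d", 1:8)
  nm[7] <- "VIP"
  d <- list(c(0, 0, 0),       # NONE
            c(1, 0, 0),       # A
            c(0, 1, 0),       # M
            c(0, 0, 1),       # P
            c(0.7, 0.7, 0),   # AM
            c(0, 0.7, 0.7),   # MP
            c(0.6, 0.6, 0.6), # AMP (VIP host)
            c(0.7, 0, 0.7))   # AP
  names(d) <- nm
  d
}

tiny_spec <- function(area_design = tiny_design(), ...) {
  phantom_spec(n_subjects = 3, runs_per_subject = 8, frames_per_run = 96,
               grid_dims = c(12, 14, 8), n_areas = 8,
               area_design = area_design, rng_seed = 7L, ...)
}

tiny_geom <- function() memo("tiny_geom", make_geometry(tiny_spec()))
tiny_truth <- function() memo("tiny_truth", plant_design(tiny_spec(), tiny_geom()))

# one simulated + preprocessed run of the tiny phantom
tiny_run <- function() memo("tiny_run", {
  simulate_run(tiny_spec(), tiny_geom(), tiny_truth(), 1, 1)
})
tiny_run_pre <- function() memo("tiny_run_pre", {
  preprocess_run(tiny_run(), filter_settings())
})

# a noiseless, nuisance-free spec for exact-identity checks
clean_spec <- function(...) {
  phantom_spec(n_subjects = 1, runs_per_subject = 1, frames_per_run = 96,
               grid_dims = c(12, 14, 8), n_areas = 8,
               area_design = tiny_design(),
               noise_sd = 0, global_amp = 0, wm_amp = 0, csf_amp = 0,
               spike_prob = 0, rng_seed = 11L, ...)
}

# hand-rolled run_ts constructor for unit tests on small matrices
make_run <- function(data, tr = 2, fd = NULL, wm = NULL, csf = NULL) {
  n <- nrow(data)
  structure(list(
    data = data, tr_seconds = tr,
    subject_id = "sub-01", run_id = "run-01",
    nuisance = data.frame(wm = wm %||% rep(0, n), csf = csf %||% rep(0, n),
                          fd = fd %||% rep(0, n)),
    censor = rep(TRUE, n), spike_frames = integer(0), latents = NULL
  ), class = "run_ts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run-level zmap wrapper for aggregation tests
make_zmap <- function(values, seed = "aVIP", hemi = "left",
                      subject = "sub-01", run = "run-01") {
  structure(list(values = values, level = "run", seed = seed,
                 hemisphere = hemi, subject_id = subject, run_id = run,
                 n_frames = 100L),
            class = "zmap")
}
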