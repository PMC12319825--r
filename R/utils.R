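# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded fixture generation does
#' not perturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a per-run RNG seed from the phantom seed and run identity
#'
#' Deterministic mixing of (rng_seed, subject index, run index) into a
#' 31-bit seed so every run draws an independent, reproducible stream.
#' @noRd
derive_run_seed <- function(rng_seed, subject, run) {
  m <- 2147483629 # prime below 2^31
  s <- (as.numeric(rng_seed) %% m)
  s <- (s * 48271 + as.numeric(subject) * 16807) %% m
  s <- (s * 48271 + as.numeric(run) * 69621 + 12345) %% m
  as.integer(s)
}

vip_verbose <- function() isTRUE(getOption("vipgradient.verbose", FALSE))

vip_log <- function(...) {
  if (vip_verbose()) message("[vipgradient] ", ...)
  invisible(NULL)
}

#' Seed names in anterior-to-posterior order
#' @noRd
seed_names <- function() c("aVIP", "mVIP", "pVIP")

hemi_names <- function() c("left", "right")

#' The eight exclusive connectivity categories
#'
#' Order matters: index = 1 + a + 2*m + 4*p for the boolean seed triple
#' (a, m, p) gives the position in this vector.
#' @noRd
category_levels <- function() c("NONE", "A", "M", "P", "AM", "MP", "AP", "AMP")

# position lookup for the (a, m, p) bit code 0..7
category_from_bits <- function(bits) {
  lv <- category_levels()
  code <- c("NONE", "A", "M", "AM", "P", "AP", "MP", "AMP")[bits + 1L]
  factor(code, levels = lv)
}
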