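#' Load the example acquisition manifest
#'
#' Expands the packaged per-session acquisition table of the ten-monkey
#' resting-state cohort (sessions, runs per session, pulses per run, TR)
#' into a run manifest with one row per run. Monkey initials are used as
#' subject identifiers.
#'
#' @return A `run_manifest` data frame: `subject_id`, `session_id`,
#'   `run_id`, `n_frames`, `tr_seconds`.
#' @export
example_acquisitions <- function() {
  path <- system.file("extdata", "table1_acquisitions.tsv",
                      package = "vipgradient", mustWork = TRUE)
  tab <- read.delim(path, colClasses = c(monkey = "character"),
                    na.strings = character(0))
  rows <- lapply(seq_len(nrow(tab)), function(i) data.frame(
    subject_id = tab$monkey[i],
    session_id = tab$session[i],
    run_id = seq_len(tab$n_runs[i]),
    n_frames = tab$pulses_per_run[i],
    tr_seconds = tab$tr_seconds[i],
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  class(out) <- c("run_manifest", class(out))
  out
}

#' Summarize an acquisition manifest
#'
#' Per-subject session/run counts and total scan time, plus the
#' study-wide minima that matter for data-quality recommendations: the
#' shortest cumulated scan duration, the lowest run count, and the
#' shortest single-run duration. Total minutes are
#' `sum(n_frames * tr_seconds) / 60`, reported at full precision.
#'
#' @param manifest A run manifest (one row per run) with `subject_id`,
#'   `session_id`, `n_frames`, `tr_seconds`.
#' @return `list(per_subject = data frame, global = list(min_total_minutes,
#'   min_run_count, min_run_minutes))`.
#' @export
summarize_acquisition <- function(manifest) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0)
    stop("empty or invalid acquisition manifest")
  need <- c("subject_id", "session_id", "n_frames", "tr_seconds")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "))

  per <- lapply(split(manifest, manifest$subject_id), function(d) data.frame(
    subject_id = d$subject_id[1],
    n_sessions = length(unique(d$session_id)),
    n_runs = nrow(d),
    frames_per_run = paste(unique(d$n_frames), collapse = ";"),
    tr_seconds = paste(unique(d$tr_seconds), collapse = ";"),
    min_run_minutes = min(d$n_frames * d$tr_seconds) / 60,
    total_minutes = sum(d$n_frames * d$tr_seconds) / 60,
    stringsAsFactors = FALSE))
  per <- do.call(rbind, per)
  rownames(per) <- NULL

  list(per_subject = per,
       global = list(min_total_minutes = min(per$total_minutes),
                     min_run_count = min(per$n_runs),
                     min_run_minutes = min(per$min_run_minutes)))
}
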