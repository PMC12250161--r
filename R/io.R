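#' Write a frame stack as a 16-bit multi-page TIFF
#'
#' Intensities are rounded to integer digital units and stored one frame per
#' page. Values outside `[0, 65535]` are clamped.
#'
#' @param stack A [frame_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  pages <- lapply(seq_len(d[1]), function(k) {
    m <- stack$data[k, , , drop = TRUE]
    dim(m) <- d[2:3]
    m <- round(m)
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into a frame stack
#'
#' @param path TIFF file path.
#' @param fps Frame rate to attach (frames per second).
#' @param origin Acquisition start time, seconds.
#' @return A [frame_stack()] in integer digital units.
#' @export
read_stack <- function(path, fps = 10, origin = 0) {
  if (!file.exists(path))
    stop(sprintf("stack file not found: '%s'", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
  frame_stack(arr, fps = fps, origin = origin)
}

event_columns <- c("event_time_s", "force_g", "animal_id", "cohort",
                   "phase", "drug", "time_block_min")

read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(event_columns, "time_block_min"), names(ev))
  if (length(missing))
    stop(errorCondition(
      sprintf("events file '%s' lacks required column(s): %s",
              path, paste(missing, collapse = ", ")),
      class = c("evokedff_validation_error", "error", "condition")))
  if (!"time_block_min" %in% names(ev)) ev$time_block_min <- NA_real_
  ev[, event_columns]
}

#' Read and validate a recording bundle
#'
#' Loads a multi-page TIFF stack and its stimulation-event sidecar CSV
#' (columns `event_time_s, force_g, animal_id, cohort, phase, drug,
#' time_block_min`), checking that event times are sorted, non-negative and
#' lie within the recording, and that every event's full 250-frame epoch
#' (50 baseline + 200 evaluation frames at the default alignment) fits
#' inside the stack. Validation failures name the offending row.
#'
#' @param stack_path Path to the TIFF stack.
#' @param events_path Path to the events CSV.
#' @param fps Frame rate of the stack.
#' @return A list of class `recording_bundle` with elements `stack`,
#'   `events` and `metadata`.
#' @export
read_bundle <- function(stack_path, events_path, fps = 10) {
  stack <- read_stack(stack_path, fps = fps)
  events <- read_events(events_path)
  dur <- n_frames(stack) / fps
  bad <- which(events$event_time_s < 0 | events$event_time_s >= dur)
  if (length(bad))
    stop(errorCondition(
      sprintf("event row(s) %s fall outside the %.1f s recording",
              paste(bad, collapse = ", "), dur),
      class = c("evokedff_validation_error", "error", "condition")))
  if (nrow(events) > 1 && is.unsorted(events$event_time_s))
    stop(errorCondition("event times must be non-decreasing",
      class = c("evokedff_validation_error", "error", "condition")))
  meta <- list(
    animal_id = if (nrow(events)) events$animal_id[1] else NA_character_,
    cohort = if (nrow(events)) events$cohort[1] else NA_character_,
    phase = if (nrow(events)) events$phase[1] else NA_character_,
    drug = if (nrow(events)) events$drug[1] else NA_character_,
    fps = fps)
  structure(list(stack = stack, events = events, metadata = meta),
            class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  d <- dim(x$stack$data)
  cat(sprintf("Recording bundle: %d frames (%d x %d px) @ %g fps, %d event(s)\n",
              d[1], d[2], d[3], x$metadata$fps, nrow(x$events)))
  invisible(x)
}

#' Write analysis result tables
#'
#' Writes the per-epoch normalized traces (long format: one row per epoch per
#' evaluation frame), the window AUC table (long format: one row per epoch
#' per window), the condition mean +/- SE trace table (one row per frame
#' offset per condition) and, when supplied, the statistical comparison
#' table, as CSV files with fixed headers. Output is deterministic given the
#' same inputs.
#'
#' @param epochs An `epoch_set` with computed dF/F0 (see [compute_dff()]).
#' @param auc A window-AUC table from [window_auc()]; `NULL` to skip.
#' @param stats A comparison table from [run_comparison_suite()]; `NULL` to
#'   skip.
#' @param out_dir Output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(epochs, auc = NULL, stats = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  files <- character(0)

  dff_path <- file.path(out_dir, "epoch_dff.csv")
  n <- epoch_count(epochs)
  if (n > 0 && !is.null(epochs$dff)) {
    long <- data.frame(
      epochs$meta[rep(seq_len(n), each = ncol(epochs$dff)), , drop = FALSE],
      frame_offset = rep(seq_len(ncol(epochs$dff)) - 1L, times = n),
      dff_pct = as.vector(t(epochs$dff)),
      row.names = NULL)
    utils::write.csv(long, dff_path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(
      data.frame(epochs$meta[0, , drop = FALSE], frame_offset = integer(0),
                 dff_pct = numeric(0)),
      dff_path, row.names = FALSE, quote = FALSE)
  }
  files <- c(files, dff_path)

  if (!is.null(auc)) {
    auc_path <- file.path(out_dir, "window_auc.csv")
    utils::write.csv(auc_long(auc), auc_path, row.names = FALSE, quote = FALSE)
    files <- c(files, auc_path)
  }
  if (!is.null(stats)) {
    st_path <- file.path(out_dir, "stat_results.csv")
    utils::write.csv(stats, st_path, row.names = FALSE, quote = FALSE)
    files <- c(files, st_path)
  }
  invisible(files)
}

# wide AUC table -> long (one row per epoch per window)
auc_long <- function(auc) {
  wcols <- intersect(c("auc_pre", "auc_stim", "auc_early_post", "auc_late_post"),
                     names(auc))
  meta <- auc[, setdiff(names(auc), wcols), drop = FALSE]
  if (nrow(auc) == 0)
    return(data.frame(meta, window = character(0), auc = numeric(0)))
  out <- NULL
  for (w in wcols) {
    out <- rbind(out, data.frame(meta, window = sub("^auc_", "", w),
                                 auc = auc[[w]], row.names = NULL))
  }
  ord <- order(rep(seq_len(nrow(auc)), times = length(wcols)))
  out[ord, , drop = FALSE]
}
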