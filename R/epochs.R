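#' Segment a trace into event-locked epochs
#'
#' Each stimulation yields a 250-frame epoch: 50 baseline frames followed by
#' a 200-frame evaluation block. Under the default alignment the filament
#' contact (the event time) falls on evaluation frame 50, i.e. the
#' evaluation starts `align_offset_s = -5` seconds before contact, so its
#' four 50-frame windows are pre-stimulation, stimulation, early
#' post-stimulation and late post-stimulation. With the event at `t` seconds
#' and 10 fps the raw frames are therefore (0-based trace indices)
#' `10 t - 100 ... 10 t + 149`: baseline `10 t - 100 ... 10 t - 51`,
#' evaluation `10 t - 50 ... 10 t + 149`.
#'
#' Epochs that would reach outside the recording raise an error listing the
#' offending events. Epochs from events spaced closer than the 25-s epoch
#' span are flagged with a warning and, when `drop_overlap = TRUE`, dropped.
#'
#' @param trace A `trace` from [extract_trace()] (or any list with `values`,
#'   `fps`, `origin`).
#' @param events Event schedule data frame (see [read_bundle()]).
#' @param align_offset_s Evaluation start relative to the event time,
#'   seconds (default -5: contact opens the stimulation window).
#' @param baseline_frames,eval_frames Epoch block lengths in frames.
#' @param drop_overlap Drop (rather than just flag) overlapping epochs.
#' @return An object of class `epoch_set`: `meta` (one row per epoch),
#'   `raw` (n x 250 matrix), `fps`, and `f0_global` (mean of the first
#'   `baseline_frames` trace values, for the global-baseline comparison in
#'   [compute_dff()]).
#' @export
segment_epochs <- function(trace, events, align_offset_s = -5,
                           baseline_frames = 50L, eval_frames = 200L,
                           drop_overlap = FALSE) {
  fps <- trace$fps
  n <- nrow(events)
  span <- baseline_frames + eval_frames
  if (n == 0) {
    return(structure(list(
      meta = data.frame(events, f0 = numeric(0), row.names = NULL),
      raw = matrix(numeric(0), 0, span), fps = fps,
      baseline_frames = baseline_frames, eval_frames = eval_frames,
      f0_global = mean(trace$values[seq_len(min(baseline_frames,
                                                length(trace$values)))])),
      class = "epoch_set"))
  }
  k0 <- round((events$event_time_s - trace$origin) * fps)  # 0-based contact frame
  eval_start <- k0 + round(align_offset_s * fps)
  raw_start <- eval_start - baseline_frames
  raw_end <- eval_start + eval_frames - 1L
  n_t <- length(trace$values)
  bad <- which(raw_start < 0 | raw_end > n_t - 1L)
  if (length(bad)) {
    stop(errorCondition(
      sprintf("epoch(s) for event row(s) %s (t = %s s) exceed the recording bounds",
              paste(bad, collapse = ", "),
              paste(events$event_time_s[bad], collapse = ", ")),
      class = c("evokedff_epoch_error", "error", "condition")))
  }
  keep <- rep(TRUE, n)
  if (n > 1) {
    gaps <- diff(sort(raw_start))
    if (any(gaps < span)) {
      warning(sprintf("%d epoch pair(s) overlap (events < %g s apart)",
                      sum(gaps < span), span / fps), call. = FALSE)
      if (drop_overlap) {
        ord <- order(raw_start)
        last_end <- -Inf
        for (i in ord) {
          if (raw_start[i] <= last_end) keep[i] <- FALSE
          else last_end <- raw_end[i]
        }
      }
    }
  }
  idx <- which(keep)
  raw <- matrix(0, length(idx), span)
  for (j in seq_along(idx)) {
    i <- idx[j]
    raw[j, ] <- trace$values[(raw_start[i] + 1):(raw_end[i] + 1)]
  }
  structure(list(
    meta = data.frame(events[idx, , drop = FALSE], row.names = NULL),
    raw = raw, fps = fps,
    baseline_frames = baseline_frames, eval_frames = eval_frames,
    f0_global = mean(trace$values[seq_len(baseline_frames)])),
    class = "epoch_set")
}

epoch_count <- function(epochs) nrow(epochs$raw)

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d epoch(s) of %d frames (%d baseline + %d evaluation) @ %g fps\n",
              epoch_count(x), x$baseline_frames + x$eval_frames,
              x$baseline_frames, x$eval_frames, x$fps))
  if (!is.null(x$dff)) cat("  dF/F0 computed (percent)\n")
  invisible(x)
}

#' Per-stimulation dynamic-baseline dF/F0 normalization
#'
#' For each epoch, the baseline fluorescence F0 is the reduction (mean by
#' default) of its 50 baseline frames, and every evaluation frame F is
#' expressed as `(F - F0) / F0 * 100` percent. Recomputing F0 for every
#' stimulation makes the normalization invariant to multiplicative rescaling
#' and insensitive to slow drift — photobleaching and tonic drug effects —
#' which is the point of the dynamic baseline. A `baseline = "global"`
#' alternative (single F0 from the first 50 frames of the whole recording)
#' is provided for comparison only.
#'
#' @param epochs An `epoch_set` from [segment_epochs()].
#' @param reducer Function collapsing the baseline frames to F0 (default
#'   `mean`; `median` is the robust alternative).
#' @param baseline `"dynamic"` (per stimulation, default) or `"global"`.
#' @return The `epoch_set` with `meta$f0` and an n x 200 `dff` matrix in
#'   percent. Idempotent.
#' @export
compute_dff <- function(epochs, reducer = mean,
                        baseline = c("dynamic", "global")) {
  baseline <- match.arg(baseline)
  n <- epoch_count(epochs)
  bf <- seq_len(epochs$baseline_frames)
  ef <- epochs$baseline_frames + seq_len(epochs$eval_frames)
  f0 <- if (baseline == "dynamic") apply(epochs$raw[, bf, drop = FALSE], 1, reducer)
        else rep(epochs$f0_global, n)
  if (n > 0 && any(f0 <= 0))
    stop(errorCondition(
      sprintf("non-positive baseline F0 for epoch(s) %s (dead sensor region?)",
              paste(which(f0 <= 0), collapse = ", ")),
      class = c("evokedff_baseline_error", "error", "condition")))
  epochs$meta$f0 <- f0
  epochs$dff <- (epochs$raw[, ef, drop = FALSE] - f0) / f0 * 100
  epochs$baseline <- baseline
  epochs
}

window_names <- c("pre", "stim", "early_post", "late_post")

#' Four-window area under the curve
#'
#' Splits the 200 evaluation frames into four consecutive 50-frame windows —
#' pre-stimulation, stimulation, early post-stimulation, late
#' post-stimulation, each 5 s at 10 fps — and integrates the percent dF/F0
#' against time over each. The default trapezoidal rule over 50 samples
#' spans 4.9 s, so a constant -2 percent window integrates to -9.8
#' percent-seconds; values are signed (evoked depression gives negative
#' AUC). `rule = "rectangle"` (sum times dt) and `rule = "mean"` (per-window
#' mean, a positive rescaling of the rectangle AUC) are provided for
#' sensitivity checks.
#'
#' @param epochs An `epoch_set` with computed dF/F0.
#' @param rule Integration rule: `"trapezoid"` (default), `"rectangle"`,
#'   or `"mean"`.
#' @return Data frame: epoch metadata plus `auc_pre`, `auc_stim`,
#'   `auc_early_post`, `auc_late_post` (percent-seconds; percent for
#'   `rule = "mean"`).
#' @export
window_auc <- function(epochs, rule = c("trapezoid", "rectangle", "mean")) {
  rule <- match.arg(rule)
  if (is.null(epochs$dff))
    stop("call compute_dff() before window_auc()", call. = FALSE)
  n <- epoch_count(epochs)
  wlen <- epochs$eval_frames %/% 4L
  dt <- 1 / epochs$fps
  out <- matrix(0, n, 4)
  for (w in 1:4) {
    cols <- (w - 1L) * wlen + seq_len(wlen)
    seg <- epochs$dff[, cols, drop = FALSE]
    out[, w] <- switch(rule,
      trapezoid = (rowSums(seg) - (seg[, 1] + seg[, wlen]) / 2) * dt,
      rectangle = rowSums(seg) * dt,
      mean = rowMeans(seg))
  }
  colnames(out) <- paste0("auc_", window_names)
  res <- data.frame(epochs$meta, out, row.names = NULL)
  attr(res, "rule") <- rule
  res
}
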