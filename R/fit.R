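#' Fit the event-locked evoked-response analysis to a recording
#'
#' The central entry point: takes a recording (a `recording_bundle` from
#' [read_bundle()], a synthetic `recording` from [simulate_recording()], or
#' a [frame_stack()] plus an event table), selects the region of interest,
#' reduces it to a fluorescence trace, segments event-locked epochs,
#' normalizes each with its dynamic per-stimulation baseline, and quantifies
#' the four 5-s analysis windows by signed AUC.
#'
#' @param x A `recording_bundle`, `recording`, or `frame_stack`.
#' @param events Event table (required when `x` is a `frame_stack`).
#' @param roi `"auto"` (default: max-mean-intensity 10 x 10 search via
#'   [auto_select_roi()]) or an explicit [roi_spec()] mirroring hand
#'   selection.
#' @param align_offset_s,baseline_frames,eval_frames Passed to
#'   [segment_epochs()].
#' @param reducer Baseline reducer for [compute_dff()].
#' @param rule Integration rule for [window_auc()].
#' @param drop_overlap Drop overlapping epochs (see [segment_epochs()]).
#' @return An object of class `evoked_fit` with components `roi`, `trace`,
#'   `epochs` (with dF/F0), `auc` (window-AUC table) and `call`.
#' @examples
#' p <- sim_params(n_rows = 12, n_cols = 16, seed = 42)
#' rec <- simulate_recording(p, n_events = 5, force_list = c(0.04, 0.16, 1.4))
#' fit <- evoked_response(rec)
#' coef(fit)
#' @export
evoked_response <- function(x, events = NULL, roi = "auto",
                            align_offset_s = -5, baseline_frames = 50L,
                            eval_frames = 200L, reducer = mean,
                            rule = "trapezoid", drop_overlap = FALSE) {
  if (inherits(x, c("recording_bundle", "recording"))) {
    stack <- x$stack
    if (is.null(events)) events <- x$events
  } else if (inherits(x, "frame_stack")) {
    stack <- x
    if (is.null(events))
      stop("events table required when fitting a bare frame_stack", call. = FALSE)
  } else stop("x must be a recording bundle, recording, or frame_stack",
              call. = FALSE)
  if (identical(roi, "auto")) roi <- auto_select_roi(stack)
  trace <- extract_trace(stack, roi)
  epochs <- segment_epochs(trace, events, align_offset_s = align_offset_s,
                           baseline_frames = baseline_frames,
                           eval_frames = eval_frames,
                           drop_overlap = drop_overlap)
  epochs <- compute_dff(epochs, reducer = reducer)
  auc <- window_auc(epochs, rule = rule)
  structure(list(roi = roi, trace = trace, epochs = epochs, auc = auc,
                 rule = rule, call = match.call()),
            class = "evoked_fit")
}

#' @export
print.evoked_fit <- function(x, ...) {
  cat("Event-locked evoked-response fit\n")
  cat(sprintf("  ROI: %d x %d at (row %d, col %d); %d epoch(s) of %d frames\n",
              x$roi$height, x$roi$width, x$roi$row0, x$roi$col0,
              epoch_count(x$epochs),
              x$epochs$baseline_frames + x$epochs$eval_frames))
  if (epoch_count(x$epochs)) {
    cat(sprintf("  mean stim-window AUC: %.2f %%*s (%s rule)\n",
                mean(x$auc$auc_stim), x$rule))
  }
  invisible(x)
}

#' Mean window AUCs by condition
#'
#' @param object An `evoked_fit`.
#' @param by Metadata columns defining the conditions.
#' @param ... Unused.
#' @return Matrix of mean signed AUC (percent-seconds), one row per
#'   condition, columns `pre`, `stim`, `early_post`, `late_post`.
#' @export
coef.evoked_fit <- function(object,
                            by = c("cohort", "phase", "drug", "force_g"),
                            ...) {
  auc <- object$auc
  by <- intersect(by, names(auc))
  key <- interaction(auc[by], drop = TRUE, sep = " ")
  wcols <- paste0("auc_", window_names)
  m <- t(vapply(levels(key), function(l)
    colMeans(as.matrix(auc[key == l, wcols, drop = FALSE])), numeric(4)))
  colnames(m) <- window_names
  m
}

#' Summarize an evoked-response fit
#'
#' Aggregates epochs per condition (mean +/- SE traces, per-animal AUC
#' means) and runs the default normality-routed paired comparison suite.
#'
#' @param object An `evoked_fit`.
#' @param ... Unused.
#' @return A list of class `summary.evoked_fit`: `conditions` (named list
#'   of [aggregate_condition()] summaries), `comparisons` (the
#'   [run_comparison_suite()] table), `n_epochs`.
#' @export
summary.evoked_fit <- function(object, ...) {
  auc <- object$auc
  keys <- unique(auc[, intersect(c("cohort", "phase", "drug", "force_g",
                                   "time_block_min"), names(auc)),
                     drop = FALSE])
  conditions <- list()
  for (i in seq_len(nrow(keys))) {
    key <- as.list(keys[i, , drop = FALSE])
    key <- key[!vapply(key, is.na, logical(1))]
    lab <- paste(unlist(key), collapse = " ")
    conditions[[lab]] <- suppressWarnings(
      aggregate_condition(object$epochs, key = key))
  }
  comparisons <- tryCatch(run_comparison_suite(auc),
                          evokedff_sample_error = function(e) NULL)
  structure(list(conditions = conditions, comparisons = comparisons,
                 n_epochs = epoch_count(object$epochs)),
            class = "summary.evoked_fit")
}

#' @export
print.summary.evoked_fit <- function(x, ...) {
  cat(sprintf("Evoked-response summary: %d epochs in %d condition(s)\n",
              x$n_epochs, length(x$conditions)))
  for (lab in names(x$conditions)) {
    cs <- x$conditions[[lab]]
    cat(sprintf("  %-40s n = %3d epochs / %d animal(s), min mean dF/F0 %.2f%%\n",
                lab, cs$n_epochs, cs$n_animals, min(cs$mean_trace)))
  }
  if (!is.null(x$comparisons)) {
    cat("Comparisons (per-animal means):\n")
    print(x$comparisons[, c("label", "route", "p_value", "star_code")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Plot condition mean +/- SE evoked traces
#'
#' Base-graphics rendering of the per-condition mean percent dF/F0 over the
#' 20-s evaluation with a shaded +/- SE ribbon; vertical guides mark the
#' four 5-s windows (contact begins at 5 s).
#'
#' @param x An `evoked_fit`.
#' @param by Metadata columns defining the plotted conditions.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.evoked_fit <- function(x, by = c("force_g"), ...) {
  auc <- x$auc
  by <- intersect(by, names(auc))
  key <- interaction(auc[by], drop = TRUE, sep = " ")
  tt <- (seq_len(x$epochs$eval_frames) - 1) / x$epochs$fps
  cols <- grDevices::hcl.colors(max(3, nlevels(key)), "Dark 3")
  ylim <- range(vapply(levels(key), function(l) {
    m <- colMeans(x$epochs$dff[key == l, , drop = FALSE]); range(m)
  }, numeric(2)))
  graphics::plot(NULL, xlim = range(tt), ylim = ylim * 1.3,
                 xlab = "time in evaluation (s)",
                 ylab = expression(Delta * "F/F"[0] * " (%)"), ...)
  graphics::abline(v = c(5, 10, 15), lty = 3, col = "grey60")
  graphics::abline(h = 0, col = "grey80")
  for (i in seq_along(levels(key))) {
    l <- levels(key)[i]
    d <- x$epochs$dff[key == l, , drop = FALSE]
    m <- colMeans(d)
    if (nrow(d) > 1) {
      se <- apply(d, 2, stats::sd) / sqrt(nrow(d))
      graphics::polygon(c(tt, rev(tt)), c(m - se, rev(m + se)),
                        col = grDevices::adjustcolor(cols[i], 0.25),
                        border = NA)
    }
    graphics::lines(tt, m, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = levels(key), col = cols[seq_along(levels(key))],
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}
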