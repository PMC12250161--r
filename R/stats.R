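#' Star code for a p-value
#'
#' `ns` for p >= 0.05, then `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of codes.
#' @export
star_code <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Aggregate epochs matching one condition into a summary
#'
#' Computes the 200-frame mean and standard-error traces of percent dF/F0
#' and the per-animal window-AUC means for all epochs matching `key`. With
#' `unit = "stimulation"` (the convention for condition traces) the SE is
#' across all epochs; with `unit = "animal"` (the inferential convention:
#' stimulations are first averaged within animal) per-animal mean traces are
#' computed first and the SE is across animals.
#'
#' @param epochs An `epoch_set` with computed dF/F0.
#' @param key Named list of condition values to match against the epoch
#'   metadata (e.g. `list(cohort = "sham", force_g = 0.16)`); `NULL` keeps
#'   every epoch.
#' @param unit `"stimulation"` (default) or `"animal"`.
#' @param rule Integration rule passed to [window_auc()].
#' @return An object of class `condition_summary`: `key`, `unit`,
#'   `mean_trace`, `se_trace` (length 200, percent), `n_epochs`,
#'   `n_animals`, and `animal_auc` (per-animal window-AUC means).
#' @export
aggregate_condition <- function(epochs, key = NULL,
                                unit = c("stimulation", "animal"),
                                rule = "trapezoid") {
  unit <- match.arg(unit)
  if (is.null(epochs$dff))
    stop("call compute_dff() before aggregate_condition()", call. = FALSE)
  sel <- rep(TRUE, epoch_count(epochs))
  for (k in names(key)) sel <- sel & (epochs$meta[[k]] == key[[k]])
  if (!any(sel))
    stop(errorCondition("no epochs match the requested condition",
      class = c("evokedff_empty_summary_error", "error", "condition")))
  dff <- epochs$dff[sel, , drop = FALSE]
  meta <- epochs$meta[sel, , drop = FALSE]
  auc <- window_auc(subset_epochs(epochs, sel), rule = rule)
  wcols <- paste0("auc_", window_names)

  animals <- unique(meta$animal_id)
  animal_trace <- t(vapply(animals, function(a)
    colMeans(dff[meta$animal_id == a, , drop = FALSE]), numeric(ncol(dff))))
  animal_auc <- data.frame(animal_id = animals, t(vapply(animals, function(a)
    colMeans(as.matrix(auc[auc$animal_id == a, wcols, drop = FALSE])),
    numeric(4))), row.names = NULL)
  names(animal_auc)[-1] <- wcols

  if (unit == "stimulation") {
    mean_trace <- colMeans(dff)
    se_trace <- if (nrow(dff) > 1) apply(dff, 2, stats::sd) / sqrt(nrow(dff))
                else rep(NA_real_, ncol(dff))
  } else {
    mean_trace <- colMeans(animal_trace)
    se_trace <- if (length(animals) > 1)
      apply(animal_trace, 2, stats::sd) / sqrt(length(animals))
      else rep(NA_real_, ncol(dff))
  }
  if (anyNA(se_trace))
    warning("standard error undefined with a single contributing unit",
            call. = FALSE)
  structure(list(key = key, unit = unit, mean_trace = mean_trace,
                 se_trace = se_trace, n_epochs = nrow(dff),
                 n_animals = length(animals), animal_auc = animal_auc),
            class = "condition_summary")
}

subset_epochs <- function(epochs, sel) {
  epochs$meta <- epochs$meta[sel, , drop = FALSE]
  epochs$raw <- epochs$raw[sel, , drop = FALSE]
  if (!is.null(epochs$dff)) epochs$dff <- epochs$dff[sel, , drop = FALSE]
  epochs
}

#' @export
print.condition_summary <- function(x, ...) {
  keytxt <- if (length(x$key))
    paste(names(x$key), unlist(x$key), sep = "=", collapse = ", ") else "all epochs"
  cat(sprintf("Condition summary (%s; unit = %s): %d epochs from %d animal(s)\n",
              keytxt, x$unit, x$n_epochs, x$n_animals))
  cat(sprintf("  mean dF/F0 range [%.2f, %.2f]%%\n",
              min(x$mean_trace), max(x$mean_trace)))
  invisible(x)
}

#' Normality-routed paired comparison
#'
#' The procedure used throughout: a Shapiro-Wilk test on the paired
#' differences decides the route — paired t-test when the differences look
#' normal (Shapiro p >= 0.05), Wilcoxon signed-rank otherwise. Tests are
#' two-sided at alpha 0.05; the result carries full provenance (normality
#' p-value, route, statistic, p-value, star code).
#'
#' Degenerate inputs: all-zero differences give a flagged result with
#' p = 1; constant non-zero differences (Shapiro inapplicable) fall back to
#' the signed-rank route with a note.
#'
#' @param a,b Paired numeric vectors (same unit order), length >= 3.
#' @param label Comparison label carried into the result.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `paired_test` with fields `label`, `n`,
#'   `normality_p`, `route`, `statistic`, `p_value`, `significant`,
#'   `star_code`, `note`.
#' @export
paired_compare <- function(a, b, label = "", alpha = 0.05) {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(a) < 3)
    stop(errorCondition("need at least 3 pairs",
      class = c("evokedff_sample_error", "error", "condition")))
  d <- a - b
  note <- ""
  if (all(d == 0)) {
    res <- list(label = label, n = length(d), normality_p = NA_real_,
                route = "degenerate", statistic = NA_real_, p_value = 1,
                significant = FALSE, star_code = "ns",
                note = "all paired differences are zero")
    class(res) <- "paired_test"
    return(res)
  }
  if (stats::sd(d) == 0) {
    normality_p <- NA_real_
    route <- "wilcoxon_signed_rank"
    note <- "constant non-zero differences; Shapiro-Wilk inapplicable"
  } else {
    normality_p <- stats::shapiro.test(d)$p.value
    route <- if (normality_p >= 0.05) "paired_t" else "wilcoxon_signed_rank"
  }
  if (route == "paired_t") {
    ht <- stats::t.test(a, b, paired = TRUE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  }
  res <- list(label = label, n = length(d), normality_p = normality_p,
              route = route, statistic = unname(ht$statistic),
              p_value = ht$p.value, significant = ht$p.value < alpha,
              star_code = star_code(ht$p.value), note = note)
  class(res) <- "paired_test"
  res
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("%s (n = %d pairs)\n",
              if (nzchar(x$label)) x$label else "Paired comparison", x$n))
  cat(sprintf("  Shapiro-Wilk p = %s -> %s\n",
              format(x$normality_p, digits = 3), x$route))
  cat(sprintf("  statistic = %s, p = %s %s\n",
              format(x$statistic, digits = 4), format(x$p_value, digits = 4),
              x$star_code))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

as_row <- function(pt) {
  data.frame(label = pt$label, n = pt$n, normality_p = pt$normality_p,
             route = pt$route, statistic = pt$statistic,
             p_value = pt$p_value, significant = pt$significant,
             star_code = pt$star_code, note = pt$note,
             stringsAsFactors = FALSE)
}

# per-animal window means for one condition subset of the AUC table
animal_means <- function(auc, sel, window) {
  sub <- auc[sel, , drop = FALSE]
  ids <- sort(unique(sub$animal_id))
  vapply(ids, function(a) mean(sub[[window]][sub$animal_id == a]), numeric(1))
}

cond_label <- function(...) paste(..., sep = " ")

#' Run the standard comparison suite on a window-AUC table
#'
#' Emits, on per-animal means (the inferential unit: stimulations averaged
#' within animal first), the comparisons mirroring the experimental design:
#' \itemize{
#'   \item within every condition (cohort x phase x drug x force x block):
#'     pre-stimulation vs stimulation window;
#'   \item for every cohort x force with both phases (no-drug sessions):
#'     stimulation-window AUC pre- vs post-surgery;
#'   \item for every cohort x time block with both drugs: stimulation-window
#'     AUC under saline vs morphine.
#' }
#' P-values are unadjusted (matching the reporting convention), with a Holm
#' adjusted column alongside.
#'
#' @param auc Window-AUC table from [window_auc()] (wide format, with the
#'   event metadata columns).
#' @param design Optional data frame restricting/ordering the comparisons,
#'   with columns `type` (`"window"`, `"phase"`, `"drug"`) and the key
#'   columns each type needs (`cohort`, `phase`, `drug`, `force_g`,
#'   `time_block_min`). `NULL` builds every comparison the table supports.
#'   Referencing an absent condition raises an error naming it.
#' @param alpha Significance level.
#' @return Data frame, one row per comparison: `label`, `type`, `n`,
#'   `normality_p`, `route`, `statistic`, `p_value`, `p_holm`,
#'   `significant`, `star_code`, `note`.
#' @export
run_comparison_suite <- function(auc, design = NULL, alpha = 0.05) {
  if (is.null(design)) design <- default_design(auc)
  rows <- NULL
  for (i in seq_len(nrow(design))) {
    dd <- design[i, ]
    if (dd$type == "window") {
      sel <- auc$cohort == dd$cohort & auc$phase == dd$phase &
        auc$drug == dd$drug & auc$force_g == dd$force_g &
        (is.na(dd$time_block_min) | auc$time_block_min == dd$time_block_min)
      if (!any(sel, na.rm = TRUE))
        stop(errorCondition(sprintf("no epochs for condition: %s",
          cond_label(dd$cohort, dd$phase, dd$drug, dd$force_g, dd$time_block_min)),
          class = c("evokedff_design_error", "error", "condition")))
      sel[is.na(sel)] <- FALSE
      pt <- paired_compare(animal_means(auc, sel, "auc_pre"),
                           animal_means(auc, sel, "auc_stim"),
                           label = cond_label(dd$cohort, dd$phase, dd$drug,
                                              dd$force_g,
                                              if (is.na(dd$time_block_min)) ""
                                              else paste0(dd$time_block_min, "min"),
                                              ": pre vs stim"),
                           alpha = alpha)
    } else if (dd$type == "phase") {
      sel1 <- auc$cohort == dd$cohort & auc$phase == "pre_surgery" &
        auc$drug == "none" & auc$force_g == dd$force_g
      sel2 <- auc$cohort == dd$cohort & auc$phase == "post_surgery" &
        auc$drug == "none" & auc$force_g == dd$force_g
      if (!any(sel1) || !any(sel2))
        stop(errorCondition(sprintf("missing phase data for %s at %g g",
          dd$cohort, dd$force_g),
          class = c("evokedff_design_error", "error", "condition")))
      pt <- paired_compare(animal_means(auc, sel1, "auc_stim"),
                           animal_means(auc, sel2, "auc_stim"),
                           label = cond_label(dd$cohort, dd$force_g,
                                              ": stim pre- vs post-surgery"),
                           alpha = alpha)
    } else if (dd$type == "drug") {
      sel1 <- auc$cohort == dd$cohort & auc$drug == "saline" &
        auc$time_block_min == dd$time_block_min
      sel2 <- auc$cohort == dd$cohort & auc$drug == "morphine" &
        auc$time_block_min == dd$time_block_min
      if (!any(sel1, na.rm = TRUE) || !any(sel2, na.rm = TRUE))
        stop(errorCondition(sprintf("missing drug data for %s at %g min",
          dd$cohort, dd$time_block_min),
          class = c("evokedff_design_error", "error", "condition")))
      sel1[is.na(sel1)] <- FALSE; sel2[is.na(sel2)] <- FALSE
      pt <- paired_compare(animal_means(auc, sel1, "auc_stim"),
                           animal_means(auc, sel2, "auc_stim"),
                           label = cond_label(dd$cohort, paste0(dd$time_block_min, "min"),
                                              ": stim saline vs morphine"),
                           alpha = alpha)
    } else stop(sprintf("unknown comparison type '%s'", dd$type), call. = FALSE)
    r <- as_row(pt)
    r$type <- dd$type
    rows <- rbind(rows, r)
  }
  rows$p_holm <- stats::p.adjust(rows$p_value, method = "holm")
  rows[, c("label", "type", "n", "normality_p", "route", "statistic",
           "p_value", "p_holm", "significant", "star_code", "note")]
}

default_design <- function(auc) {
  conds <- unique(auc[, c("cohort", "phase", "drug", "force_g", "time_block_min")])
  design <- data.frame(type = "window", conds, row.names = NULL)
  for (co in unique(auc$cohort)) {
    for (f in unique(auc$force_g[auc$cohort == co & auc$drug == "none"])) {
      if (any(auc$cohort == co & auc$phase == "pre_surgery" & auc$drug == "none" & auc$force_g == f) &&
          any(auc$cohort == co & auc$phase == "post_surgery" & auc$drug == "none" & auc$force_g == f))
        design <- rbind(design, data.frame(type = "phase", cohort = co,
          phase = NA, drug = NA, force_g = f, time_block_min = NA))
    }
    blocks <- unique(auc$time_block_min[auc$cohort == co & auc$drug %in% c("saline", "morphine")])
    blocks <- blocks[!is.na(blocks)]
    for (b in blocks) {
      if (any(auc$cohort == co & auc$drug == "saline" & auc$time_block_min == b, na.rm = TRUE) &&
          any(auc$cohort == co & auc$drug == "morphine" & auc$time_block_min == b, na.rm = TRUE))
        design <- rbind(design, data.frame(type = "drug", cohort = co,
          phase = NA, drug = NA, force_g = NA, time_block_min = b))
    }
  }
  design
}
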