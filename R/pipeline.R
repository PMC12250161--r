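#' Combine epoch sets from several recordings
#'
#' @param sets List of `epoch_set` objects with identical epoch geometry.
#' @return One pooled `epoch_set`.
#' @export
combine_epochs <- function(sets) {
  sets <- sets[vapply(sets, epoch_count, integer(1)) >= 0]
  if (!length(sets)) stop("no epoch sets to combine", call. = FALSE)
  geom <- vapply(sets, function(s) c(s$baseline_frames, s$eval_frames, s$fps),
                 numeric(3))
  if (any(geom != geom[, 1]))
    stop("epoch sets have differing geometry", call. = FALSE)
  out <- sets[[1]]
  out$meta <- do.call(rbind, lapply(sets, `[[`, "meta"))
  rownames(out$meta) <- NULL
  out$raw <- do.call(rbind, lapply(sets, `[[`, "raw"))
  dffs <- lapply(sets, `[[`, "dff")
  out$dff <- if (any(vapply(dffs, is.null, logical(1)))) NULL
             else do.call(rbind, dffs)
  out$f0_global <- NA_real_
  out
}

#' Demo pipeline configuration
#'
#' The full experimental design at a reduced sensor size: for each cohort
#' (sham, PNL), a pre- and a post-surgery pain-threshold session per animal
#' (15 stimulations at each of 0.04 / 0.16 / 1.4 g, interleaved) and a
#' saline and a morphine injection session (15 stimulations at 0.16 g), for
#' 4 animals per cohort — 60 stimulations per cohort-condition. The demo
#' sensor is 12 x 16 px (the 10 x 10 ROI analysis is unchanged) so the whole
#' design simulates in seconds.
#'
#' @param out_dir Output directory for [run_pipeline()].
#' @param seed Base seed.
#' @param n_animals Animals per cohort.
#' @param n_per_force Stimulations per animal per force.
#' @param params_args Extra arguments overriding [sim_params()] defaults.
#' @return A config list accepted by [run_pipeline()].
#' @export
demo_design <- function(out_dir = tempfile("evokedff_demo"), seed = 1L,
                        n_animals = 4, n_per_force = 15,
                        params_args = list()) {
  sessions <- NULL
  forces <- c(0.04, 0.16, 1.4)
  for (co in c("sham", "PNL")) {
    for (a in seq_len(n_animals)) {
      id <- sprintf("%s_m%02d", co, a)
      for (ph in c("pre_surgery", "post_surgery")) {
        sessions <- rbind(sessions, data.frame(
          animal_id = id, cohort = co, phase = ph, drug = "none",
          n_events = n_per_force * length(forces),
          forces = paste(forces, collapse = ","),
          stringsAsFactors = FALSE))
      }
      for (dr in c("saline", "morphine")) {
        sessions <- rbind(sessions, data.frame(
          animal_id = id, cohort = co, phase = "post_surgery", drug = dr,
          n_events = n_per_force, forces = "0.16",
          stringsAsFactors = FALSE))
      }
    }
  }
  list(seed = as.integer(seed), out_dir = out_dir, roi = "auto",
       params = utils::modifyList(list(n_rows = 12, n_cols = 16,
                                       roi_center = c(6, 8),
                                       roi_sigma_px = 4),
                                  params_args),
       sessions = sessions,
       analysis = list(align_offset_s = -5, reducer = "mean",
                       rule = "trapezoid"))
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop(sprintf("config file not found: '%s'", config), call. = FALSE)
    config <- yaml::read_yaml(config)
    if (!is.null(config$sessions))
      config$sessions <- as.data.frame(config$sessions,
                                       stringsAsFactors = FALSE)
  }
  if (is.null(config$out_dir)) stop("config needs out_dir", call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$roi)) config$roi <- "auto"
  if (is.null(config$analysis)) config$analysis <- list()
  an <- config$analysis
  config$analysis <- list(
    align_offset_s = if (is.null(an$align_offset_s)) -5 else an$align_offset_s,
    reducer = if (is.null(an$reducer)) "mean" else an$reducer,
    rule = if (is.null(an$rule)) "trapezoid" else an$rule)
  has_inputs <- !is.null(config$inputs)
  has_sessions <- !is.null(config$sessions)
  if (!has_inputs && !has_sessions)
    stop("config needs either 'sessions' (simulate) or 'inputs' (read)",
         call. = FALSE)
  if (has_inputs) {
    for (inp in config$inputs) {
      for (f in c(inp$stack, inp$events)) {
        if (!file.exists(f))
          stop(errorCondition(sprintf("input file not found: '%s'", f),
            class = c("evokedff_config_error", "error", "condition")))
      }
    }
  }
  config
}

#' Run the full pipeline: simulate/read, analyze, summarize, write
#'
#' Orchestrates all stages for a set of recording sessions described by a
#' config (list or YAML path): either simulates each session with
#' [simulate_recording()] or reads TIFF/CSV inputs with [read_bundle()];
#' selects the ROI and fits [evoked_response()] per recording; pools the
#' window-AUC tables; runs [run_comparison_suite()]; writes all result
#' tables and a JSON run report embedding the resolved config, per-stage
#' timings, epoch counts per condition and MD5 hashes of every output.
#' Identical config and seed give identical outputs.
#'
#' @param config Config list (see [demo_design()]) or path to a YAML file.
#' @return The run report, invisibly (also written as `run_report.json`).
#' @export
run_pipeline <- function(config) {
  config <- resolve_config(config)
  t_all <- proc.time()[["elapsed"]]
  timings <- c()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  t0 <- proc.time()[["elapsed"]]
  recs <- list()
  if (!is.null(config$sessions)) {
    pargs <- if (is.null(config$params)) list() else config$params
    pargs$seed <- config$seed
    params <- do.call(sim_params, pargs)
    ss <- config$sessions
    for (i in seq_len(nrow(ss))) {
      forces <- as.numeric(strsplit(as.character(ss$forces[i]), ",")[[1]])
      recs[[i]] <- simulate_recording(params, n_events = ss$n_events[i],
                                      force_list = forces,
                                      cohort = ss$cohort[i],
                                      phase = ss$phase[i], drug = ss$drug[i],
                                      animal_id = ss$animal_id[i])
    }
  } else {
    for (i in seq_along(config$inputs)) {
      inp <- config$inputs[[i]]
      fps <- if (is.null(inp$fps)) 10 else inp$fps
      recs[[i]] <- read_bundle(inp$stack, inp$events, fps = fps)
    }
  }
  timings["acquire_s"] <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  roi <- config$roi
  if (is.numeric(roi)) {
    roi <- if (length(roi) >= 4) roi_spec(roi[1], roi[2], roi[3], roi[4])
           else roi_spec(roi[1], roi[2])
  }
  reducer <- match.fun(config$analysis$reducer)
  fits <- lapply(recs, function(r)
    evoked_response(r, roi = roi,
                    align_offset_s = config$analysis$align_offset_s,
                    reducer = reducer, rule = config$analysis$rule))
  epochs <- combine_epochs(lapply(fits, `[[`, "epochs"))
  auc <- do.call(rbind, lapply(fits, `[[`, "auc"))
  rownames(auc) <- NULL
  timings["analyze_s"] <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  stats_tab <- run_comparison_suite(auc, alpha = 0.05)
  timings["stats_s"] <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  files <- write_results(epochs, auc = auc, stats = stats_tab,
                         out_dir = config$out_dir)
  trace_path <- file.path(config$out_dir, "condition_traces.csv")
  utils::write.csv(condition_trace_table(epochs), trace_path,
                   row.names = FALSE, quote = FALSE)
  files <- c(files, trace_path)
  timings["write_s"] <- proc.time()[["elapsed"]] - t0

  counts <- stats::aggregate(
    list(n_epochs = rep(1L, epoch_count(epochs))),
    by = epochs$meta[, c("cohort", "phase", "drug", "force_g",
                         "time_block_min")],
    FUN = sum)
  rois <- lapply(fits, `[[`, "roi")
  report <- list(
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    n_recordings = length(recs),
    n_epochs = epoch_count(epochs),
    cohorts = sort(unique(epochs$meta$cohort)),
    epochs_per_condition = counts,
    roi = list(height = rois[[1]]$height, width = rois[[1]]$width,
               positions = vapply(rois, function(r)
                 sprintf("(%d,%d)", r$row0, r$col0), character(1))),
    timings_s = as.list(round(timings, 3)),
    total_s = round(proc.time()[["elapsed"]] - t_all, 3),
    output_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

# mean +/- SE trace per condition, one row per frame offset per condition
condition_trace_table <- function(epochs) {
  meta <- epochs$meta
  key <- interaction(meta$cohort, meta$phase, meta$drug, meta$force_g,
                     meta$time_block_min, drop = TRUE, sep = "|")
  out <- NULL
  tt <- (seq_len(epochs$eval_frames) - 1) / epochs$fps
  for (l in levels(key)) {
    d <- epochs$dff[key == l, , drop = FALSE]
    parts <- strsplit(l, "|", fixed = TRUE)[[1]]
    se <- if (nrow(d) > 1) apply(d, 2, stats::sd) / sqrt(nrow(d)) else NA_real_
    out <- rbind(out, data.frame(
      cohort = parts[1], phase = parts[2], drug = parts[3],
      force_g = as.numeric(parts[4]), time_block_min = parts[5],
      frame_offset = seq_along(tt) - 1L, time_s = tt,
      mean_dff = colMeans(d), se_dff = se, row.names = NULL))
  }
  out
}
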