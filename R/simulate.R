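#' Stimulus-response kernel
#'
#' Closed-form fractional fluorescence response to one filament contact,
#' evaluated at times `t` seconds after contact onset. During the contact
#' (`0 <= t <= stim_duration_s`) the signal falls along a saturating
#' exponential normalized so that the depression reaches exactly
#' `amp_depression` at contact offset. After offset the depression recovers
#' exponentially (`recovery_tau`) while a rebound lobe — a normalized
#' difference of exponentials peaking at exactly `amp_rebound` — rises and
#' decays (`rebound_tau`). The kernel is zero for `t < 0`.
#'
#' @param t Numeric vector of times relative to contact onset, seconds.
#' @param amp_depression Peak fractional depression (<= 0).
#' @param amp_rebound Peak fractional rebound (>= 0).
#' @param params A [sim_params()] supplying the time constants.
#' @return Numeric vector of fractional fluorescence changes.
#' @export
response_kernel <- function(t, amp_depression, amp_rebound, params) {
  on_tau <- params$onset_tau
  rec_tau <- params$recovery_tau
  reb_tau <- params$rebound_tau
  dur <- params$stim_duration_s
  k <- numeric(length(t))
  during <- t >= 0 & t <= dur
  after <- t > dur
  if (any(during)) {
    k[during] <- amp_depression * (1 - exp(-t[during] / on_tau)) /
      (1 - exp(-dur / on_tau))
  }
  if (any(after)) {
    s <- t[after] - dur
    # peak of exp(-s/reb) - exp(-s/on), for unit-peak rebound normalization
    s_star <- log(reb_tau / on_tau) / (1 / on_tau - 1 / reb_tau)
    h_peak <- exp(-s_star / reb_tau) - exp(-s_star / on_tau)
    k[after] <- amp_depression * exp(-s / rec_tau) +
      amp_rebound * (exp(-s / reb_tau) - exp(-s / on_tau)) / h_peak
  }
  k
}

# deterministic 31-bit sub-seed from the base seed and labels
derive_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "|")
  h <- 0
  for (v in utf8ToInt(lab)) h <- (h * 131 + v) %% 2147483629
  as.integer(h)
}

schedule_events <- function(params, n_events, force_list, animal_id,
                            cohort, phase, drug, duration_s = NULL) {
  gap <- max(params$inter_event_gap_s, 0)
  if (n_events > 0) {
    times <- params$lead_in_s + (seq_len(n_events) - 1) * gap
    last <- times[n_events]
  } else {
    times <- numeric(0)
    last <- 0
  }
  need <- last + params$tail_s
  if (is.null(duration_s)) duration_s <- need
  if (duration_s < need - 1e-9) {
    stop(errorCondition(
      sprintf("recording of %.1f s cannot hold %d events at a %.0f s gap (needs %.1f s)",
              duration_s, n_events, gap, need),
      class = c("evokedff_schedule_error", "error", "condition")))
  }
  forces <- if (n_events > 0) rep_len(force_list, n_events) else numeric(0)
  events <- data.frame(
    event_time_s = times,
    force_g = forces,
    animal_id = rep_len(as.character(animal_id), n_events),
    cohort = rep_len(cohort, n_events),
    phase = rep_len(phase, n_events),
    drug = rep_len(drug, n_events),
    time_block_min = if (n_events > 0) 30 * (floor(times / 1800) + 1) else numeric(0),
    stringsAsFactors = FALSE)
  list(events = events, duration_s = duration_s)
}

#' Generate one synthetic recording session
#'
#' Simulates a micro-CMOS movie with a bright GCaMP-expressing region, slow
#' photobleaching, a shared slow background fluctuation, per-pixel read
#' noise, and stimulus-locked responses at the scheduled event times.
#' Pixelwise intensity is
#' `base(r,c) * [exp(-t/bleach_tau) * (1 + response(t) + background(t)) + tonic(t)]
#'  + noise`, clipped at zero, where `response(t)` is the superposition of
#' per-event [response_kernel()] terms whose amplitudes are the force-anchored
#' maps scaled by the [condition_gain()] and multiplicative trial jitter.
#' Under morphine a slow additive tonic ramp is added so the dynamic
#' per-stimulation baseline can be shown to filter it.
#'
#' Events are laid out at the minimum inter-event gap starting after the
#' lead-in; output is a pure function of `(params, arguments)` through the
#' seed derived from the base seed and the session labels.
#'
#' @param params A [sim_params()].
#' @param n_events Number of stimulations (>= 0).
#' @param force_list Forces in grams, recycled across events.
#' @param cohort,phase,drug,animal_id Condition labels for the session.
#' @param duration_s Optional recording length, seconds; an error of class
#'   `evokedff_schedule_error` is raised when the events cannot fit.
#' @param zero_response Force both evoked amplitudes to exactly zero
#'   (sham stimulation times; used by [null_recording()]).
#' @return A list of class `recording` with elements `stack`
#'   ([frame_stack()]), `events` (event schedule data frame) and `truth`
#'   (per-event realized amplitudes plus generator globals as attributes).
#' @export
simulate_recording <- function(params, n_events = 15,
                               force_list = 0.16,
                               cohort = "sham", phase = "pre_surgery",
                               drug = "none", animal_id = "m1",
                               duration_s = NULL, zero_response = FALSE) {
  validate_sim_params(params)
  if (n_events < 0) stop("n_events must be >= 0", call. = FALSE)
  sched <- schedule_events(params, n_events, force_list, animal_id,
                           cohort, phase, drug, duration_s)
  events <- sched$events
  fps <- params$fps
  n_t <- as.integer(ceiling(sched$duration_s * fps))
  t <- (seq_len(n_t) - 1) / fps

  seed <- derive_seed(params$seed, animal_id, cohort, phase, drug,
                      n_events, signif(sum(events$force_g), 10))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  gain <- condition_gain(params, cohort, phase, drug)
  n_ev <- nrow(events)
  jit_d <- if (n_ev) stats::rnorm(n_ev, 0, params$amp_jitter_cv) else numeric(0)
  jit_r <- if (n_ev) stats::rnorm(n_ev, 0, params$amp_jitter_cv) else numeric(0)
  if (zero_response) {
    amp_d <- amp_r <- numeric(n_ev)
    gain_used <- 0
  } else {
    amp_d <- amp_at_force(params$depression_amp, events$force_g) * gain * (1 + jit_d)
    amp_r <- amp_at_force(params$rebound_amp, events$force_g) * (1 + jit_r)
    gain_used <- gain
  }

  resp <- numeric(n_t)
  for (i in seq_len(n_ev)) {
    resp <- resp + response_kernel(t - events$event_time_s[i],
                                   amp_d[i], amp_r[i], params)
  }

  bg <- if (params$ou_sd > 0) ou_process(n_t, 1 / fps, params$ou_sd, params$ou_tau)
        else numeric(n_t)
  tonic <- if (identical(drug, "morphine")) params$morphine_tonic_slope * t
           else numeric(n_t)
  bleach <- if (is.finite(params$bleach_tau)) exp(-t / params$bleach_tau)
            else rep(1, n_t)

  base_map <- baseline_map(params)
  temporal <- bleach * (1 + resp + bg) + tonic
  intensity <- outer(temporal, base_map)  # T x rows x cols
  if (params$noise_sd > 0)
    intensity <- intensity + stats::rnorm(length(intensity), 0, params$noise_sd)
  intensity[intensity < 0] <- 0

  truth <- data.frame(
    animal_id = events$animal_id, event_time_s = events$event_time_s,
    force_g = events$force_g,
    condition_gain = rep_len(gain_used, n_ev),
    amp_depression = amp_d, amp_rebound = amp_r,
    stringsAsFactors = FALSE)
  attr(truth, "bleach_tau") <- params$bleach_tau
  attr(truth, "noise_sd") <- params$noise_sd
  attr(truth, "seed") <- seed

  structure(list(stack = frame_stack(intensity, fps = fps),
                 events = events, truth = truth),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  d <- dim(x$stack$data)
  cat(sprintf("Synthetic recording: %d frames (%d x %d px), %d stimulation(s)\n",
              d[1], d[2], d[3], nrow(x$events)))
  if (nrow(x$events)) {
    cat(sprintf("  forces: %s g; condition %s/%s/%s\n",
                paste(sort(unique(x$events$force_g)), collapse = ", "),
                x$events$cohort[1], x$events$phase[1], x$events$drug[1]))
  }
  invisible(x)
}

#' Null recording: sham stimulation times, zero evoked response
#'
#' Identical to [simulate_recording()] except both evoked amplitudes are
#' forced to exactly zero; bleaching, background fluctuation and read noise
#' remain. Used for type-I-error calibration of the downstream statistics.
#'
#' @inheritParams simulate_recording
#' @return A `recording`; `truth$amp_depression` and `truth$amp_rebound`
#'   are exactly 0 for every event.
#' @export
null_recording <- function(params, n_events = 15, force_list = 0.16,
                           cohort = "sham", phase = "pre_surgery",
                           drug = "none", animal_id = "m1",
                           duration_s = NULL) {
  simulate_recording(params, n_events, force_list, cohort, phase, drug,
                     animal_id, duration_s, zero_response = TRUE)
}

# stationary Ornstein-Uhlenbeck sample path
ou_process <- function(n, dt, sd, tau) {
  a <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  z <- stats::rnorm(n - 1, 0, innov_sd)
  for (k in seq_len(n - 1)) x[k + 1] <- a * x[k] + z[k]
  x
}

baseline_map <- function(params) {
  r <- seq_len(params$n_rows) - 1
  c <- seq_len(params$n_cols) - 1
  d2 <- outer((r - params$roi_center[1])^2, (c - params$roi_center[2])^2, "+")
  params$baseline_mean *
    (1 + (params$roi_brightness_gain - 1) * exp(-d2 / (2 * params$roi_sigma_px^2)))
}

#' Write a fixture set of recordings to disk
#'
#' Generates one recording per animal for each cohort in the design and
#' writes it as a 16-bit multi-page TIFF plus an event-sidecar CSV, together
#' with a pooled ground-truth CSV and a JSON manifest. The default design —
#' 4 animals with 15 stimulations each — yields 60 stimulations per cohort
#' per condition.
#'
#' @param out_dir Output directory (created if absent).
#' @param params A [sim_params()]; its `seed` drives all randomness.
#' @param animals_per_cohort,events_per_animal Design counts.
#' @param cohorts Character vector of cohorts to generate.
#' @param phase,drug,force_list Condition labels shared by all sessions.
#' @return The manifest, invisibly (also written as `manifest.json`): file
#'   lists, design counts, fps.
#' @export
write_fixture_set <- function(out_dir, params = sim_params(),
                              animals_per_cohort = 4,
                              events_per_animal = 15,
                              cohorts = "sham",
                              phase = "pre_surgery", drug = "none",
                              force_list = 0.16) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  stacks <- character(0); event_files <- character(0)
  truth_all <- NULL
  total_events <- 0L
  for (co in cohorts) {
    for (a in seq_len(animals_per_cohort)) {
      id <- sprintf("%s_m%02d", co, a)
      rec <- simulate_recording(params, events_per_animal, force_list,
                                cohort = co, phase = phase, drug = drug,
                                animal_id = id)
      sp <- file.path(out_dir, paste0(id, ".tif"))
      ep <- file.path(out_dir, paste0(id, "_events.csv"))
      write_stack(rec$stack, sp)
      utils::write.csv(rec$events, ep, row.names = FALSE, quote = FALSE)
      stacks <- c(stacks, sp); event_files <- c(event_files, ep)
      truth_all <- rbind(truth_all, rec$truth)
      total_events <- total_events + nrow(rec$events)
    }
  }
  tp <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(truth_all, tp, row.names = FALSE, quote = FALSE)
  manifest <- list(stacks = stacks, events = event_files, ground_truth = tp,
                   fps = params$fps, seed = params$seed,
                   animals_per_cohort = animals_per_cohort,
                   events_per_animal = events_per_animal,
                   cohorts = cohorts, total_events = total_events)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
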