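#' Simulation parameters for synthetic micro-CMOS recordings
#'
#' Builds and validates the parameter set driving [simulate_recording()].
#' Defaults describe the study conditions the generator emulates: a 40 x 90
#' pixel implantable sensor imaged at 10 frames/s, a bright GCaMP-expressing
#' region, slow mono-exponential photobleaching, stimulus-locked depression
#' whose magnitude grows with von Frey force, and rebound excitation that
#' weakens with force.
#'
#' Amplitude maps (`depression_amp`, `rebound_amp`) are named numeric vectors
#' anchored at the three standard von Frey forces; other forces are
#' interpolated linearly in log10(force) and clamped at the anchors, keeping
#' the maps serializable (YAML/JSON) rather than opaque closures.
#'
#' `condition_gain` multiplies the depression amplitude: chronic pain
#' (`PNL` cohort, `post_surgery` phase) exaggerates the evoked depression
#' (mechanical allodynia), morphine nearly eliminates it. Gains compose
#' multiplicatively: `gain = cohort/phase gain * drug gain`.
#'
#' Two stochastic components shape trial-to-trial variability: i.i.d.
#' per-pixel Gaussian read noise (`noise_sd`, digital units) and a shared
#' slow Ornstein-Uhlenbeck background (`ou_sd`, fractional; `ou_tau`,
#' seconds) standing in for spontaneous population activity. The OU term is
#' what gives per-epoch response estimates a realistic noise floor
#' independent of the evoked amplitude.
#'
#' @param n_rows,n_cols Sensor size in pixels.
#' @param fps Frame rate (frames per second).
#' @param baseline_mean Mean background intensity, digital units (DU).
#' @param roi_center `(row, col)` centre (0-based) of the bright
#'   GCaMP-expressing region.
#' @param roi_brightness_gain Peak multiplicative brightness of the
#'   expressing region (> 1).
#' @param roi_sigma_px Gaussian spatial scale (pixels) of the bright region.
#' @param bleach_tau Mono-exponential photobleaching time constant, seconds.
#'   `Inf` disables bleaching.
#' @param noise_sd Per-pixel per-frame Gaussian noise SD, DU.
#' @param ou_sd Stationary SD of the shared slow background fluctuation,
#'   as a fraction of baseline fluorescence. 0 disables it.
#' @param ou_tau Correlation time of the background fluctuation, seconds.
#' @param depression_amp Named numeric: peak fractional depression (negative)
#'   at each anchor force in grams.
#' @param rebound_amp Named numeric: peak fractional rebound (positive,
#'   non-increasing in force) at each anchor force.
#' @param amp_jitter_cv Multiplicative trial-to-trial coefficient of
#'   variation applied to both evoked amplitudes.
#' @param onset_tau,recovery_tau,rebound_tau Response-kernel time constants,
#'   seconds (depression onset, post-contact recovery, rebound decay).
#' @param stim_duration_s Filament contact duration, seconds.
#' @param cohort_phase_gain Named numeric, names `"cohort:phase"`; depression
#'   multiplier for that cohort/phase (unlisted combinations default to 1).
#' @param drug_gain Named numeric depression multiplier per drug condition.
#' @param morphine_tonic_slope Slow additive baseline ramp (fraction of
#'   baseline per second) applied under morphine, emulating its tonic
#'   excitation of dopaminergic activity.
#' @param inter_event_gap_s Minimum spacing between stimulations, seconds.
#' @param lead_in_s Recording time before the first stimulation, seconds.
#' @param tail_s Recording time after the last stimulation, seconds.
#' @param seed Base random seed; all generator output is a pure function of
#'   the parameters and this seed.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [simulate_recording()], [response_kernel()]
#' @export
sim_params <- function(n_rows = 40L,
                       n_cols = 90L,
                       fps = 10,
                       baseline_mean = 1000,
                       roi_center = c(20, 45),
                       roi_brightness_gain = 2,
                       roi_sigma_px = 6,
                       bleach_tau = 14400,
                       noise_sd = 10,
                       ou_sd = 0.013,
                       ou_tau = 2,
                       depression_amp = c("0.04" = -0.01,
                                          "0.16" = -0.02,
                                          "1.4"  = -0.04),
                       rebound_amp = c("0.04" = 0.008,
                                       "0.16" = 0.005,
                                       "1.4"  = 0.002),
                       amp_jitter_cv = 0.2,
                       onset_tau = 0.5,
                       recovery_tau = 1.5,
                       rebound_tau = 2,
                       stim_duration_s = 5,
                       cohort_phase_gain = c("PNL:post_surgery" = 2),
                       drug_gain = c(none = 1, saline = 1, morphine = 0.02),
                       morphine_tonic_slope = 2e-4,
                       inter_event_gap_s = 30,
                       lead_in_s = 12,
                       tail_s = 16,
                       seed = 1L) {
  p <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            fps = fps, baseline_mean = baseline_mean,
            roi_center = as.numeric(roi_center),
            roi_brightness_gain = roi_brightness_gain,
            roi_sigma_px = roi_sigma_px,
            bleach_tau = bleach_tau, noise_sd = noise_sd,
            ou_sd = ou_sd, ou_tau = ou_tau,
            depression_amp = depression_amp, rebound_amp = rebound_amp,
            amp_jitter_cv = amp_jitter_cv,
            onset_tau = onset_tau, recovery_tau = recovery_tau,
            rebound_tau = rebound_tau, stim_duration_s = stim_duration_s,
            cohort_phase_gain = cohort_phase_gain, drug_gain = drug_gain,
            morphine_tonic_slope = morphine_tonic_slope,
            inter_event_gap_s = inter_event_gap_s,
            lead_in_s = lead_in_s, tail_s = tail_s,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (p$n_rows < 1 || p$n_cols < 1) stop("sensor must have >= 1 pixel", call. = FALSE)
  taus <- c(p$bleach_tau, p$ou_tau, p$onset_tau, p$recovery_tau, p$rebound_tau)
  if (any(taus <= 0)) stop("all time constants must be > 0", call. = FALSE)
  if (p$onset_tau == p$rebound_tau)
    stop("onset_tau and rebound_tau must differ (kernel normalization)",
         call. = FALSE)
  if (p$noise_sd < 0 || p$ou_sd < 0) stop("noise SDs must be >= 0", call. = FALSE)
  if (p$roi_brightness_gain <= 1)
    stop("roi_brightness_gain must exceed 1", call. = FALSE)
  if (p$inter_event_gap_s < 0) stop("inter_event_gap_s must be >= 0", call. = FALSE)
  forces <- as.numeric(names(p$depression_amp))
  if (anyNA(forces) || is.unsorted(forces, strictly = TRUE))
    stop("depression_amp anchors must be named by increasing force", call. = FALSE)
  dmag <- abs(as.numeric(p$depression_amp))
  if (any(as.numeric(p$depression_amp) > 0))
    stop("depression_amp values must be <= 0", call. = FALSE)
  if (is.unsorted(dmag, strictly = TRUE))
    stop("|depression_amp| must increase strictly with force", call. = FALSE)
  rf <- as.numeric(names(p$rebound_amp))
  if (anyNA(rf) || is.unsorted(rf, strictly = TRUE))
    stop("rebound_amp anchors must be named by increasing force", call. = FALSE)
  ramp <- as.numeric(p$rebound_amp)
  if (any(ramp < 0)) stop("rebound_amp values must be >= 0", call. = FALSE)
  if (any(diff(ramp) > 0))
    stop("rebound_amp must be non-increasing in force", call. = FALSE)
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic recording parameters\n")
  cat(sprintf("  sensor: %d x %d px @ %g fps, baseline %g DU (bright region gain %g)\n",
              x$n_rows, x$n_cols, x$fps, x$baseline_mean, x$roi_brightness_gain))
  cat(sprintf("  bleach tau %g s, pixel noise %g DU, background OU sd %g (tau %g s)\n",
              x$bleach_tau, x$noise_sd, x$ou_sd, x$ou_tau))
  cat("  peak depression:",
      paste(sprintf("%s g: %+.3f", names(x$depression_amp), x$depression_amp),
            collapse = ", "), "\n")
  cat("  peak rebound:   ",
      paste(sprintf("%s g: %+.3f", names(x$rebound_amp), x$rebound_amp),
            collapse = ", "), "\n")
  cat(sprintf("  min inter-event gap %g s, seed %d\n", x$inter_event_gap_s, x$seed))
  invisible(x)
}

# interpolate an anchor map at arbitrary forces (linear in log10 force,
# clamped at the outer anchors)
amp_at_force <- function(map, force) {
  f <- as.numeric(names(map))
  v <- as.numeric(map)
  if (any(force <= 0)) stop("forces must be positive", call. = FALSE)
  stats::approx(log10(f), v, xout = log10(force), rule = 2)$y
}

#' Condition multiplier on the evoked depression amplitude
#'
#' @param params A [sim_params()] object.
#' @param cohort,phase,drug Condition labels.
#' @return Scalar multiplier (cohort/phase gain times drug gain).
#' @export
condition_gain <- function(params, cohort = "sham", phase = "pre_surgery",
                           drug = "none") {
  key <- paste(cohort, phase, sep = ":")
  g1 <- params$cohort_phase_gain[key]
  if (is.na(g1)) g1 <- 1
  g2 <- params$drug_gain[drug]
  if (is.na(g2)) g2 <- 1
  unname(g1 * g2)
}
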