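# Independent oracles and small parameter sets shared across tests.
# These re-derive expected values with naive arithmetic (loops, direct
# formulas) so they stay independent of the package implementation paths.

# small, fast sensor with the bright region well inside the frame
small_params <- function(...) {
  args <- utils::modifyList(
    list(n_rows = 12L, n_cols = 16L, roi_center = c(6, 8), roi_sigma_px = 4,
         seed = 11L),
    list(...))
  do.call(sim_params, args)
}

# fully deterministic variant: no pixel noise, no background fluctuation,
# no bleaching, no trial-to-trial amplitude jitter
clean_params <- function(...) {
  args <- utils::modifyList(
    list(noise_sd = 0, ou_sd = 0, bleach_tau = 1e15, amp_jitter_cv = 0),
    list(...))
  do.call(small_params, args)
}

# closed-form response kernel, written out directly from the model:
# saturating-exponential depression normalized to reach `ad` at contact
# offset, then exponential recovery plus a unit-peak-normalized
# difference-of-exponentials rebound
oracle_kernel <- function(t, ad, ar, onset, recovery, rebound, dur = 5) {
  vapply(t, function(tt) {
    if (tt < 0) return(0)
    if (tt <= dur) return(ad * (1 - exp(-tt / onset)) / (1 - exp(-dur / onset)))
    s <- tt - dur
    sstar <- log(rebound / onset) / (1 / onset - 1 / rebound)
    hpk <- exp(-sstar / rebound) - exp(-sstar / onset)
    ad * exp(-s / recovery) + ar * (exp(-s / rebound) - exp(-s / onset)) / hpk
  }, numeric(1))
}

# exhaustive-search ROI argmax with lexicographic (row0, col0) tie-break
brute_force_roi <- function(stack, height = 10, width = 10) {
  d <- dim(stack$data)
  best <- NULL
  best_val <- -Inf
  for (r0 in 0:(d[2] - height)) {
    for (c0 in 0:(d[3] - width)) {
      v <- mean(stack$data[, (r0 + 1):(r0 + height), (c0 + 1):(c0 + width)])
      if (v > best_val + 1e-12) {
        best_val <- v
        best <- c(r0, c0)
      }
    }
  }
  best
}

# per-frame loop-based ROI mean
loop_trace <- function(stack, roi) {
  d <- dim(stack$data)
  out <- numeric(d[1])
  for (k in seq_len(d[1])) {
    acc <- 0
    for (r in roi$row0 + seq_len(roi$height))
      for (cc in roi$col0 + seq_len(roi$width))
        acc <- acc + stack$data[k, r, cc]
    out[k] <- acc / (roi$height * roi$width)
  }
  out
}

# direct trapezoid over regularly sampled values
oracle_trapz <- function(y, dt) sum((y[-1] + y[-length(y)]) / 2) * dt

# build an epoch_set directly from a raw vector (bypasses segmentation)
manual_epochs <- function(raw_rows, fps = 10) {
  n <- nrow(raw_rows)
  structure(list(
    meta = data.frame(event_time_s = seq_len(n) * 30, force_g = 0.16,
                      animal_id = paste0("m", seq_len(n)), cohort = "sham",
                      phase = "pre_surgery", drug = "none",
                      time_block_min = NA_real_),
    raw = raw_rows, fps = fps, baseline_frames = 50L, eval_frames = 200L,
    f0_global = mean(raw_rows[1, 1:50])),
    class = "epoch_set")
}
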