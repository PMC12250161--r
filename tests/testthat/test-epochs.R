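trace_of <- function(values, fps = 10) {
  structure(list(values = values, fps = fps, origin = 0), class = "trace")
}

one_event <- function(t, force = 0.16) {
  data.frame(event_time_s = t, force_g = force, animal_id = "m1",
             cohort = "sham", phase = "pre_surgery", drug = "none",
             time_block_min = NA_real_)
}

test_that("epoch frames are located by the contact-at-stim-window alignment", {
  # trace whose value IS its 0-based frame index: recovered raw frames
  # reveal the selected indices directly
  tr <- trace_of(as.numeric(0:999))
  ep <- segment_epochs(tr, one_event(60))
  # contact at frame 600; evaluation starts 5 s earlier (frame 550);
  # baseline occupies the 50 frames before that (500..549)
  expect_identical(epoch_count(ep), 1L)
  expect_equal(ep$raw[1, ], as.numeric(500:749))
  # index-enumeration oracle for several event times
  for (t_ev in c(15, 32.5, 80)) {
    ep2 <- segment_epochs(tr, one_event(t_ev))
    k0 <- round(t_ev * 10)
    expect_equal(ep2$raw[1, ], as.numeric((k0 - 100):(k0 + 149)))
  }
  # the contact frame opens the stimulation window (evaluation frame 50)
  ep3 <- compute_dff(segment_epochs(tr, one_event(60)))
  expect_equal(ep3$raw[1, 101], 600)  # raw col 101 = evaluation frame 50
})

test_that("epochs exceeding the recording bounds raise a per-event error", {
  tr <- trace_of(rep(100, 400))
  err <- expect_error(segment_epochs(tr, one_event(5)),
                      class = "evokedff_epoch_error")
  expect_match(conditionMessage(err), "t = 5 s")
  expect_error(segment_epochs(tr, one_event(39)),
               class = "evokedff_epoch_error")
  # both offenders listed
  ev <- rbind(one_event(5), one_event(20), one_event(39))
  err2 <- expect_error(segment_epochs(tr, ev), class = "evokedff_epoch_error")
  expect_match(conditionMessage(err2), "1, 3")
})

test_that("overlapping epochs are flagged and optionally dropped", {
  tr <- trace_of(rep(100, 1200))
  ev <- rbind(one_event(30), one_event(50), one_event(80))  # 20 s gap < 25 s span
  expect_warning(ep <- segment_epochs(tr, ev), "overlap")
  expect_identical(epoch_count(ep), 3L)  # kept by default
  expect_warning(ep2 <- segment_epochs(tr, ev, drop_overlap = TRUE), "overlap")
  expect_identical(epoch_count(ep2), 2L)
  # 30-s spacing never overlaps
  ev3 <- rbind(one_event(30), one_event(60))
  expect_silent(segment_epochs(tr, ev3))
})

test_that("an empty schedule yields an empty epoch set end-to-end", {
  tr <- trace_of(rep(100, 300))
  ep <- compute_dff(segment_epochs(tr, one_event(15)[0, ]))
  expect_identical(epoch_count(ep), 0L)
  auc <- window_auc(ep)
  expect_identical(nrow(auc), 0L)
})

test_that("dF/F0 follows the printed formula exactly on constructed epochs", {
  # identity: constant raw -> f0 = level, dff identically 0
  ep <- compute_dff(manual_epochs(matrix(100, 1, 250)))
  expect_identical(ep$meta$f0, 100)
  expect_true(all(ep$dff == 0))
  # +/-10%: baseline 100, evaluation 110 or 90 -> exactly +/-10.0
  up <- compute_dff(manual_epochs(matrix(c(rep(100, 50), rep(110, 200)), 1, 250,
                                         byrow = TRUE)))
  expect_true(all(up$dff == 10))
  down <- compute_dff(manual_epochs(matrix(c(rep(100, 50), rep(90, 200)), 1, 250,
                                           byrow = TRUE)))
  expect_true(all(down$dff == -10))
  # formula identity on arbitrary values
  set.seed(8)
  raw <- matrix(runif(250, 80, 120), 1, 250)
  ep2 <- compute_dff(manual_epochs(raw))
  f0 <- mean(raw[1:50])
  expect_equal(ep2$dff[1, ], (raw[51:250] - f0) / f0 * 100, tolerance = 1e-12)
  # idempotent
  expect_equal(compute_dff(ep2)$dff, ep2$dff, tolerance = 0)
})

test_that("dF/F0 is invariant under multiplicative rescaling of the raw trace", {
  set.seed(9)
  raw <- matrix(runif(500, 90, 110), 2, 250)
  a <- compute_dff(manual_epochs(raw))
  for (c_scale in c(1e-3, 0.5, 7, 1e4)) {
    b <- compute_dff(manual_epochs(raw * c_scale))
    expect_equal(b$dff, a$dff, tolerance = 1e-12)
    wc <- paste0("auc_", c("pre", "stim", "early_post", "late_post"))
    expect_equal(window_auc(b)[, wc], window_auc(a)[, wc],
                 tolerance = 1e-12)
  }
})

test_that("a non-positive baseline raises a degenerate-baseline error", {
  raw <- matrix(100, 1, 250)
  raw[1, 1:50] <- 0
  expect_error(compute_dff(manual_epochs(raw)),
               class = "evokedff_baseline_error")
})

test_that("window AUC uses the signed trapezoid over each 5-s window", {
  # constant -2% over the whole evaluation: each window integrates to
  # -2 * 4.9 = -9.8 %*s (50 samples span 4.9 s)
  raw <- matrix(c(rep(100, 50), rep(98, 200)), 1, 250, byrow = TRUE)
  auc <- window_auc(compute_dff(manual_epochs(raw)))
  expect_equal(unlist(auc[1, paste0("auc_", c("pre", "stim", "early_post",
                                              "late_post"))]),
               c(auc_pre = -9.8, auc_stim = -9.8, auc_early_post = -9.8,
                 auc_late_post = -9.8), tolerance = 1e-12)
  # rectangle and per-window-mean rules
  wc <- paste0("auc_", c("pre", "stim", "early_post", "late_post"))
  expect_true(all(window_auc(compute_dff(manual_epochs(raw)),
                             rule = "rectangle")[, wc] == -10))
  expect_true(all(window_auc(compute_dff(manual_epochs(raw)),
                             rule = "mean")[, wc] == -2))
  # zero signal -> all four AUCs zero
  z <- window_auc(compute_dff(manual_epochs(matrix(5, 1, 250))))
  expect_true(all(z[, wc] == 0))
  # against the independent trapezoid oracle on irregular data
  set.seed(10)
  raw2 <- matrix(runif(250, 95, 105), 1, 250)
  ep2 <- compute_dff(manual_epochs(raw2))
  auc2 <- window_auc(ep2)
  for (w in 1:4) {
    expect_equal(auc2[1, wc[w]],
                 oracle_trapz(ep2$dff[1, (w - 1) * 50 + 1:50], 0.1),
                 tolerance = 1e-12)
  }
})

test_that("the four windows tile the 200 evaluation frames exactly", {
  set.seed(11)
  raw <- matrix(runif(250, 95, 105), 1, 250)
  ep <- compute_dff(manual_epochs(raw))
  # rectangle AUCs over the four windows must sum to the rectangle AUC of
  # the whole evaluation: no gaps, no overlaps
  parts <- unlist(window_auc(ep, rule = "rectangle")[
    1, paste0("auc_", c("pre", "stim", "early_post", "late_post"))])
  expect_equal(sum(parts), sum(ep$dff[1, ]) * 0.1, tolerance = 1e-12)
  expect_identical(ncol(ep$dff), 200L)
})

test_that("synthetic noise-free epochs match the kernel ground truth per frame", {
  p <- clean_params()
  rec <- simulate_recording(p, n_events = 2, force_list = c(0.16, 1.4))
  fit <- evoked_response(rec)
  fps <- p$fps
  for (i in 1:2) {
    t_eval <- (round(rec$events$event_time_s[i] * fps) - 50 + 0:199) / fps
    resp <- rep(0, 200)
    for (j in 1:2)
      resp <- resp + oracle_kernel(t_eval - rec$truth$event_time_s[j],
                                   rec$truth$amp_depression[j],
                                   rec$truth$amp_rebound[j],
                                   p$onset_tau, p$recovery_tau, p$rebound_tau,
                                   p$stim_duration_s)
    t_base <- (round(rec$events$event_time_s[i] * fps) - 100 + 0:49) / fps
    base_resp <- rep(0, 50)
    for (j in 1:2)
      base_resp <- base_resp + oracle_kernel(t_base - rec$truth$event_time_s[j],
                                             rec$truth$amp_depression[j],
                                             rec$truth$amp_rebound[j],
                                             p$onset_tau, p$recovery_tau,
                                             p$rebound_tau, p$stim_duration_s)
    expected <- 100 * ((1 + resp) / mean(1 + base_resp) - 1)
    expect_equal(fit$epochs$dff[i, ], expected, tolerance = 1e-9)
  }
  # stimulation window is depressed relative to pre-stimulation
  expect_true(all(fit$auc$auc_stim < fit$auc$auc_pre))
})

test_that("bleaching leakage into window AUCs shrinks as 1/tau and stays bounded", {
  taus <- c(300, 1000, 3000)
  worst <- vapply(taus, function(tau) {
    p <- clean_params(bleach_tau = tau)
    rec <- null_recording(p, n_events = 3)
    fit <- evoked_response(rec)
    max(abs(as.matrix(fit$auc[, paste0("auc_", c("pre", "stim", "early_post",
                                                 "late_post"))])))
  }, numeric(1))
  expect_true(all(worst < 1e4 / taus))  # documented bound: 10^4 / tau %*s
  expect_true(all(diff(worst) < 0))    # monotone improvement with slower bleach
})

test_that("the dynamic baseline filters a tonic morphine-like ramp", {
  p <- clean_params(morphine_tonic_slope = 2e-4)
  rec <- null_recording(p, n_events = 10, drug = "morphine")
  tr <- extract_trace(rec$stack, auto_select_roi(rec$stack))
  ep <- segment_epochs(tr, rec$events)
  dyn <- compute_dff(ep)
  glob <- compute_dff(ep, baseline = "global")
  # per-epoch perturbation from the ramp: dynamic normalization keeps it an
  # order of magnitude below the global-baseline alternative
  expect_lt(max(abs(dyn$dff)) * 10, max(abs(glob$dff)))
})
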