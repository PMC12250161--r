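test_that("null recording with all noise sources off reproduces the baseline map", {
  p <- clean_params()
  rec <- null_recording(p, n_events = 2)
  expect_identical(nrow(rec$truth), 2L)
  expect_true(all(rec$truth$amp_depression == 0))
  expect_true(all(rec$truth$amp_rebound == 0))
  # every frame equals the static baseline map
  f1 <- rec$stack$data[1, , ]
  for (k in c(2, 100, dim(rec$stack$data)[1]))
    expect_equal(rec$stack$data[k, , ], f1, tolerance = 1e-12)
  expect_equal(max(f1), p$baseline_mean * p$roi_brightness_gain,
               tolerance = 1e-9)
})

test_that("identical parameters and seed give bit-identical recordings", {
  p <- small_params(seed = 7L)
  a <- simulate_recording(p, n_events = 3, force_list = 0.16)
  b <- simulate_recording(p, n_events = 3, force_list = 0.16)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
  # a different session label decorrelates the noise
  c <- simulate_recording(p, n_events = 3, force_list = 0.16,
                          animal_id = "m2")
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("simulation does not disturb the global RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_recording(small_params(), n_events = 1))
  expect_identical(.Random.seed, before)
})

test_that("noise-free peak depression equals the configured amplitude", {
  p <- clean_params()
  for (force in c(0.04, 0.16, 1.4)) {
    rec <- simulate_recording(p, n_events = 1, force_list = force)
    fit <- evoked_response(rec)
    expected <- 100 * unname(p$depression_amp[as.character(force)])
    expect_equal(min(fit$epochs$dff), expected, tolerance = 1e-9)
  }
})

test_that("noise-free ROI trace matches the closed-form kernel superposition", {
  p <- clean_params()
  rec <- simulate_recording(p, n_events = 4, force_list = c(0.16, 1.4))
  roi <- auto_select_roi(rec$stack)
  tr <- extract_trace(rec$stack, roi)
  t <- frame_times(rec$stack)
  resp <- rep(0, length(t))
  for (i in seq_len(nrow(rec$truth))) {
    resp <- resp + oracle_kernel(t - rec$truth$event_time_s[i],
                                 rec$truth$amp_depression[i],
                                 rec$truth$amp_rebound[i],
                                 p$onset_tau, p$recovery_tau, p$rebound_tau,
                                 p$stim_duration_s)
  }
  # trace is a constant ROI brightness times (1 + response)
  base <- tr$values[1] / (1 + resp[1])
  expect_equal(tr$values, base * (1 + resp), tolerance = 1e-9)
})

test_that("peak depression magnitudes are strictly force-ordered", {
  p <- clean_params()
  peaks <- vapply(c(0.04, 0.16, 1.4), function(force) {
    fit <- evoked_response(simulate_recording(p, 1, force))
    min(fit$epochs$dff)
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("condition gains respect chronic-pain and analgesia orderings", {
  p <- small_params()
  g_sham_post <- condition_gain(p, "sham", "post_surgery", "none")
  g_pnl_post <- condition_gain(p, "PNL", "post_surgery", "none")
  g_saline <- condition_gain(p, "sham", "post_surgery", "saline")
  g_morphine <- condition_gain(p, "sham", "post_surgery", "morphine")
  expect_gt(g_pnl_post, g_sham_post)
  expect_lt(g_morphine, g_saline)
  # realized amplitudes follow the gains (jitter off)
  pc <- clean_params()
  amp <- function(co, ph, dr)
    simulate_recording(pc, 1, 0.16, cohort = co, phase = ph,
                       drug = dr)$truth$amp_depression
  expect_lt(amp("PNL", "post_surgery", "none"),
            amp("sham", "post_surgery", "none"))
  expect_gt(amp("sham", "post_surgery", "morphine"),
            amp("sham", "post_surgery", "saline"))
})

test_that("parameter validation rejects malformed amplitude maps and taus", {
  expect_error(small_params(fps = 0), "fps")
  expect_error(small_params(onset_tau = -1), "time constants")
  expect_error(small_params(depression_amp = c("0.04" = -0.02, "0.16" = -0.01,
                                               "1.4" = -0.04)),
               "increase strictly")
  expect_error(small_params(rebound_amp = c("0.04" = 0.002, "0.16" = 0.005,
                                            "1.4" = 0.008)),
               "non-increasing")
  expect_error(small_params(noise_sd = -1), "must be >= 0")
})

test_that("infeasible schedules and degenerate event counts are handled", {
  p <- small_params()
  expect_error(simulate_recording(p, n_events = 5, duration_s = 60),
               class = "evokedff_schedule_error")
  rec0 <- null_recording(p, n_events = 0)
  expect_identical(nrow(rec0$events), 0L)
  expect_gte(dim(rec0$stack$data)[1], 1L)
})

test_that("events honour the minimum inter-stimulation gap", {
  p <- small_params()
  rec <- simulate_recording(p, n_events = 6)
  gaps <- diff(rec$events$event_time_s)
  expect_true(all(gaps >= p$inter_event_gap_s))
  expect_false(is.unsorted(rec$events$event_time_s))
})

test_that("null stim-window AUC is centred on zero across seeds", {
  # Monte-Carlo through the full downstream pipeline; no bleaching so the
  # only within-epoch structure is stochastic
  aucs <- vapply(1:200, function(s) {
    p <- small_params(n_rows = 10, n_cols = 10, roi_center = c(5, 5),
                      bleach_tau = 1e15, seed = s)
    rec <- null_recording(p, n_events = 1)
    evoked_response(rec)$auc$auc_stim
  }, numeric(1))
  expect_lt(abs(mean(aucs)), 3 * sd(aucs) / sqrt(length(aucs)))
})

test_that("fixture sets follow the design and are byte-stable", {
  dir1 <- withr::local_tempdir()
  p <- small_params(n_rows = 10, n_cols = 10, roi_center = c(5, 5))
  man <- write_fixture_set(dir1, p, animals_per_cohort = 4,
                           events_per_animal = 15, cohorts = "sham")
  expect_length(man$stacks, 4)
  expect_identical(man$total_events, 60L)
  expect_true(all(file.exists(unlist(man[c("stacks", "events")]))))

  dir2 <- withr::local_tempdir()
  man1 <- write_fixture_set(dir1, p, animals_per_cohort = 1,
                            events_per_animal = 1, cohorts = "sham")
  man2 <- write_fixture_set(dir2, p, animals_per_cohort = 1,
                            events_per_animal = 1, cohorts = "sham")
  expect_length(man1$stacks, 1)
  expect_identical(man1$total_events, 1L)
  expect_identical(readLines(man1$events[1]), readLines(man2$events[1]))
  expect_identical(readLines(man1$ground_truth), readLines(man2$ground_truth))
})
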