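test_that("perfusion kernel ramps from valve delay to full exchange", {
  expect_equal(perfusion_kernel(2, 4, 10), 0)
  expect_equal(perfusion_kernel(10, 4, 10), 1)
  expect_equal(perfusion_kernel(7, 4, 10), 0.5)
  expect_equal(perfusion_kernel(-3, 4, 10), 0)
  expect_error(perfusion_kernel(1, delay_s = 10, full_exchange_s = 10),
               "smaller")
  # bounded and non-decreasing over a dense grid
  t <- seq(-10, 50, by = 0.1)
  k <- perfusion_kernel(t)
  expect_true(all(k >= 0 & k <= 1))
  expect_true(all(diff(k) >= 0))
})

test_that("transient shape peaks at the configured amplitude and time", {
  t_star <- log(10 / 2) * 2 * 10 / (10 - 2)
  # include the analytic argmax in the grid so the sampled max is the max
  time <- sort(c(seq(0, 120, by = 0.25), 20 + t_star))
  s <- make_transient(time, onset = 20, rise_tau = 2, decay_tau = 10,
                      peak = 0.5)
  expect_lt(abs(max(s) - 0.5), 1e-9)
  expect_lt(abs(time[which.max(s)] - (20 + t_star)), 0.25)
  expect_true(all(s[time <= 20] == 0))
  expect_equal(make_transient(time, 20, 2, 10, 0), numeric(length(time)))
  expect_equal(make_transient(time, 500, 2, 10, 0.5),
               numeric(length(time)))
  expect_error(make_transient(time, 20, 10, 2, 0.5), "rise_tau < decay_tau")
  expect_error(make_transient(time, 20, 2, 10, -1), "peak")
})

test_that("Hill occupancy follows c^n / (c^n + EC50^n)", {
  expect_equal(hill_scale(3, 3, 2), 0.5)
  expect_equal(hill_scale(1, 3, 1), 0.25)
  expect_gt(hill_scale(1e6, 3, 1), 0.999)
  expect_error(hill_scale(-1, 3, 1), "positive")
  expect_error(hill_scale(1, 0, 1), "positive")
})

test_that("generator is deterministic and honours degenerate settings", {
  cfg <- synth_config(n_cells = 12, seed = 11)
  g1 <- generate_recording(cfg)
  g2 <- generate_recording(cfg)
  expect_identical(g1, g2)
  # different seed changes the data
  g3 <- generate_recording(synth_config(n_cells = 12, seed = 12))
  expect_false(identical(g1$recording$traces, g3$recording$traces))

  flat <- nonresponder_config(n_cells = 5, noise_sd = 0,
                              bleach_amplitude = 0)
  gf <- generate_recording(flat)
  expect_true(all(apply(gf$recording$traces, 1,
                        function(x) diff(range(x))) == 0))
  expect_equal(unname(gf$recording$traces[, 1]), gf$truth$cells$f0)
})

test_that("generator rejects invalid configurations", {
  expect_error(synth_config(class_probabilities = c(
    non_responder = 0.5, atp_only = 0.4, atp_denatonium = 0,
    atp_sweetener = 0, atp_both = 0, ringer_artifact = 0,
    spontaneous = 0)), "sum to 1")
  expect_error(synth_config(duration_s = 100), "too short")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
})

test_that("realized class counts match configured probabilities", {
  sched <- stim_schedule(compound = c("Ringer", "ATP"),
                         concentration_mM = c(0, 0.03),
                         valve_open_s = c(20, 45), duration_s = 5,
                         role = c("vehicle_control", "viability_control"))
  cfg <- synth_config(n_cells = 3000, duration_s = 110, schedule = sched,
                      seed = 5)
  g <- generate_recording(cfg)
  obs <- table(factor(g$truth$cells$class,
                      levels = names(cfg$class_probabilities)))
  gof <- chisq.test(as.vector(obs), p = cfg$class_probabilities)
  expect_gt(gof$p.value, 0.001)
})

test_that("ground truth is coherent with the schedule", {
  g <- generate_recording(synth_config(n_cells = 80, seed = 3))
  expect_equal(nrow(g$truth$cells), 80)
  sched <- g$recording$schedule
  ev <- g$truth$events[!is.na(g$truth$events$epoch_id), ]
  valve <- sched$valve_open_s[match(ev$epoch_id, sched$epoch_id)]
  delay <- ev$true_onset_s - valve
  expect_true(all(delay >= 0 & delay <= 60))
  # spontaneous events fall outside every search window
  sp <- g$truth$events[is.na(g$truth$events$epoch_id), ]
  if (nrow(sp)) {
    inside <- vapply(sp$true_onset_s, function(t)
      any(t >= sched$valve_open_s & t <= sched$valve_open_s + 60),
      logical(1))
    expect_false(any(inside))
  }
})

test_that("noiseless, bleach-free transients are recovered exactly by dF/F0", {
  cfg <- synth_config(n_cells = 40, noise_sd = 0, bleach_amplitude = 0,
                      seed = 21)
  g <- generate_recording(cfg)
  norm <- compute_dff(g$recording)
  ev <- g$truth$events
  # single-event cells only: overlapping transients sum
  single <- names(which(table(ev$cell_id) == 1))
  expect_gt(length(single), 5)
  for (id in single) {
    e <- ev[ev$cell_id == id, ]
    tp <- cfg$transient_params[[e$compound]]
    # the signal sampled on the recording grid, rebuilt from ground truth
    expected <- make_transient(norm$time, e$true_onset_s, tp$rise_tau,
                               tp$decay_tau, e$true_peak_dff)
    got <- max(norm$dff[match(id, norm$cell_ids), ])
    expect_lt(abs(got - max(expected)), 1e-9)
    # and the sampled max sits within one grid step of the analytic peak
    expect_lt(abs(got - e$true_peak_dff), 1e-3)
  }
})

test_that("synthetic stacks reproduce their traces under ROI extraction", {
  g <- generate_recording(synth_config(
    n_cells = 4, duration_s = 100, noise_sd = 0,
    schedule = stim_schedule("ATP", 0.03, 30, 5, "viability_control"),
    seed = 2))
  sm <- generate_stack(g$recording, frame_dim = c(32, 32), roi_size = 8,
                       pixel_noise_sd = 0)
  rec2 <- extract_rois(sm$stack, sm$mask)
  expect_equal(unname(rec2$traces), unname(g$recording$traces),
               tolerance = 1e-12)
  # with pixel noise the ROI mean shrinks the error by sqrt(pixels)
  smn <- generate_stack(g$recording, frame_dim = c(32, 32), roi_size = 8,
                        pixel_noise_sd = 0.05, seed = 9)
  rec3 <- extract_rois(smn$stack, smn$mask)
  err <- abs(rec3$traces - g$recording$traces) / mean(g$recording$traces)
  expect_lt(mean(err), 3 * 0.05 / 8)
  expect_error(generate_stack(g$recording, frame_dim = c(8, 8),
                              roi_size = 8), "geometry")
})
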