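# Construct a dF/F0 "recording" directly: the calling layer only needs the
# normalized object's fields.
dff_normalized <- function(dff, time, schedule) {
  dff <- matrix(dff, nrow = 1)
  structure(list(time = time, dff = dff, f0 = 1, cell_ids = "cell_1",
                 schedule = schedule, recording = NULL, bleach_fit = NULL,
                 corrected = FALSE), class = "ca_normalized")
}

test_that("threshold is prestimulus mean + k * sample SD", {
  time <- seq(0, 120, by = 3)
  sched <- one_epoch_schedule(valve = 60)
  dff <- numeric(length(time))
  dff[time >= 45 & time < 60] <- c(0, 0, 0, 0.1, -0.1)
  thr <- epoch_threshold(dff, time, sched, 1, call_params())
  expect_equal(thr$mean, 0)
  expect_equal(thr$sd, 0.07071068, tolerance = 1e-6)
  expect_equal(thr$threshold, 0.2121320, tolerance = 1e-6)

  flat <- epoch_threshold(numeric(length(time)), time, sched, 1)
  expect_equal(flat$threshold, 0)
})

test_that("prestimulus windows dodge earlier search windows", {
  # two epochs 40 s apart: epoch 2's naive [valve-15, valve) window sits
  # inside epoch 1's search window, so it must shift earlier
  sched <- stim_schedule(c("Ringer", "ATP"), c(0, 0.03), c(30, 70), 5,
                         c("vehicle_control", "viability_control"))
  time <- seq(0, 200, by = 0.5)
  dff <- numeric(length(time))
  dff[time < 15] <- 1  # contaminate only the recording start
  thr <- epoch_threshold(dff, time, sched, 2, call_params())
  w <- time[thr$window]
  expect_true(all(w >= 15 & w < 30))  # the clean pre-Ringer segment
  expect_equal(thr$threshold, 0)
})

test_that("square pulses are called by amplitude and duration", {
  time <- seq(0, 180, by = 0.5)
  sched <- one_epoch_schedule(valve = 60)
  base <- rep(0, length(time))

  pulse <- base; pulse[time >= 72 & time < 92] <- 0.5
  call <- call_epoch(pulse, time, sched, 1, call_params())
  expect_true(call$responsive)
  expect_lt(abs(call$onset_delay_s - 12), 0.5 + 1e-9)
  expect_equal(call$peak_dff, 0.5)
  expect_gte(call$suprathreshold_duration_s, 20)

  short <- base; short[time >= 72 & time < 74] <- 0.5
  expect_false(call_epoch(short, time, sched, 1)$responsive)

  expect_false(call_epoch(base, time, sched, 1)$responsive)

  # a pulse starting after the search window does not qualify
  late <- base; late[time >= 130 & time < 150] <- 0.5
  expect_false(call_epoch(late, time, sched, 1)$responsive)
})

test_that("threshold ties do not count as supra-threshold", {
  time <- seq(0, 180, by = 0.5)
  sched <- one_epoch_schedule(valve = 60)
  dff <- numeric(length(time))
  dff[time >= 45 & time < 60] <- c(rep(c(0.1, -0.1), 15))
  thr <- epoch_threshold(dff, time, sched, 1)$threshold
  atthr <- dff; atthr[time >= 70 & time < 90] <- thr
  expect_false(call_epoch(atthr, time, sched, 1)$responsive)
  above <- dff; above[time >= 70 & time < 90] <- thr + 1e-9
  expect_true(call_epoch(above, time, sched, 1)$responsive)
})

test_that("scaling a qualifying transient up never de-calls it", {
  time <- seq(0, 180, by = 0.5)
  sched <- one_epoch_schedule(valve = 60)
  set.seed(42)
  for (r in 1:25) {
    noise <- rnorm(length(time), 0, 0.02)
    shape <- make_transient(time, 60 + runif(1, 5, 20), 2, 12, 1)
    amp <- runif(1, 0.1, 0.5)
    lo <- call_epoch(noise + amp * shape, time, sched, 1)
    if (!lo$responsive) next
    hi <- call_epoch(noise + 3 * amp * shape, time, sched, 1)
    expect_true(hi$responsive)
  }
})

test_that("spontaneous detector flags inter-epoch transients only", {
  time <- seq(0, 380, by = 0.5)
  sched <- default_schedule()
  expect_false(detect_spontaneous(numeric(length(time)), time, sched))
  # transient inside an inter-epoch gap
  sp <- make_transient(time, 190, 2, 10, 0.5)
  expect_true(detect_spontaneous(sp, time, sched))
  # the same transient inside an epoch search window is not "spontaneous"
  ok <- make_transient(time, 222, 2, 10, 0.5)
  expect_false(detect_spontaneous(ok, time, sched))
})

test_that("exclusions remove Ringer-responsive and spontaneous cells", {
  time <- seq(0, 380, by = 0.5)
  sched <- default_schedule()
  n <- length(time)
  dff <- rbind(
    make_transient(time, 41, 2, 10, 0.6) +     # responds to Ringer...
      make_transient(time, 131, 2, 10, 0.8),   # ...and to ATP
    make_transient(time, 131, 2, 10, 0.8) +    # clean ATP responder with
      make_transient(time, 190, 2, 10, 0.5),   # a spontaneous transient
    make_transient(time, 131, 2, 10, 0.8))     # clean ATP responder
  norm <- structure(list(time = time, dff = dff, f0 = rep(1, 3),
                         cell_ids = c("ringer", "spont", "clean"),
                         schedule = sched, recording = NULL,
                         bleach_fit = NULL, corrected = FALSE),
                    class = "ca_normalized")
  calls <- call_recording(norm)
  expect_true(all(calls$exclusion_reason[calls$cell_id == "ringer"] ==
                    "ringer_responsive"))
  expect_true(all(calls$exclusion_reason[calls$cell_id == "spont"] ==
                    "spontaneous_activity"))
  expect_true(all(calls$exclusion_reason[calls$cell_id == "clean"] ==
                    "none"))
  expect_true(any(calls$responsive[calls$cell_id == "clean"]))
  # exclusions only ever clear the responsive flag
  raw <- call_recording(norm, exclusions = FALSE)
  expect_true(all(calls$responsive <= raw$responsive))

  no_ringer <- stim_schedule("ATP", 0.03, 120, 10, "viability_control")
  norm2 <- norm; norm2$schedule <- no_ringer
  expect_error(call_recording(norm2), "no vehicle_control")
})

test_that("onset delay summaries report mean, sem and n", {
  calls <- make_calls(c("a", "b", "c"), "denatonium", TRUE)
  calls$onset_delay_s <- c(10, 12, 14)
  s <- onset_delay_summary(calls, "denatonium")
  expect_equal(s$mean, 12)
  expect_equal(s$sem, 1.154701, tolerance = 1e-6)
  expect_equal(s$n, 3L)

  one <- make_calls("a", "denatonium", TRUE)
  one$onset_delay_s <- 12
  s1 <- onset_delay_summary(one, "denatonium")
  expect_equal(s1$mean, 12)
  expect_true(is.na(s1$sem))

  s0 <- onset_delay_summary(calls, "sucralose")
  expect_equal(s0$n, 0L)
  expect_true(is.na(s0$mean))
})
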