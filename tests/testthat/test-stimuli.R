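test_that("EMF waveforms are zero outside the pulse and scale to peak_ku", {
  pulse <- tms_pulse("biphasic")
  t <- seq(-0.5, 1, by = 0.005)
  u <- emf_waveform(pulse, t)
  expect_true(all(u[t < 0 | t > 0.21] == 0))
  expect_equal(max(u), 4, tolerance = 1e-9)
  # a zero-amplitude pulse (constant coil current) induces no EMF at all
  expect_true(all(emf_waveform(tms_pulse("biphasic", peak_ku = 0), t) == 0))
})

test_that("the biphasic pulse induces a tri-phasic EMF with zero total integral", {
  for (shape in c("biphasic", "monophasic")) {
    pulse <- tms_pulse(shape)
    t <- seq(0, 0.21, length.out = 2001) # 100x the required resolution
    u <- emf_waveform(pulse, t)
    lobes <- rle(sign(u[u != 0]))$lengths
    n_lobes <- length(rle(sign(u[abs(u) > 1e-12]))$values)
    if (shape == "biphasic") expect_equal(n_lobes, 3) else expect_equal(n_lobes, 2)
    integ <- sum((u[-1] + u[-length(u)]) / 2) * diff(t)[1]
    expect_lt(abs(integ), 1e-6 * pulse$peak_ku * 0.21)
  }
})

test_that("at equal peak the biphasic EMF delivers at least the monophasic positive-lobe area", {
  t <- seq(0, 0.21, length.out = 4001)
  dtg <- diff(t)[1]
  area <- function(shape) sum(pmax(emf_waveform(tms_pulse(shape), t), 0)) * dtg
  expect_gte(area("biphasic"), area("monophasic"))
  expect_equal(area("biphasic") / area("monophasic"), 2, tolerance = 0.01)
})

test_that("a too-coarse time grid is rejected", {
  expect_error(emf_waveform(tms_pulse(), seq(0, 1, by = 0.05)), "coarse")
})

test_that("TMS trains place pulses at the programmed onsets", {
  # 1 Hz, 2 pulses: supports begin at t = 0 and t = 1000 ms
  tr <- tms_train(tms_pulse(), frequency = 1, n_pulses = 2)
  m <- make_tms_train(tr, duration = 2000, dt = 0.005)
  t <- seq(0, 2000, by = 0.005)
  on <- t[m[, 1] != 0]
  expect_lt(min(on), 0.21)
  expect_true(any(on >= 1000 & on <= 1000.21))
  expect_true(all(on <= 0.21 | (on >= 1000 & on <= 1000.21)))
  # 30 Hz: consecutive onset spacing 1000/30 ms for all pairs
  tr30 <- tms_train(tms_pulse(), frequency = 30, n_pulses = 10)
  m30 <- make_tms_train(tr30, duration = 500, dt = 0.005)
  u <- m30[, 1]
  onsets <- t0 <- seq(0, 500, by = 0.005)[which(u != 0 & c(0, u[-length(u)]) == 0)]
  expect_equal(diff(onsets), rep(1000 / 30, 9), tolerance = 1e-3)
  # identical waveform on every target column
  expect_equal(m30[, 1], m30[, 3], ignore_attr = TRUE)
  # zero pulses -> all-zero arrays
  m0 <- make_tms_train(tms_train(tms_pulse(), 1, n_pulses = 0), 100, 0.005)
  expect_true(all(m0 == 0))
})

test_that("train validation rejects impossible configurations", {
  expect_error(tms_train(tms_pulse(), frequency = 0, n_pulses = 1), "frequency")
  expect_error(tms_train(tms_pulse(width_us = 500), frequency = 5000,
                         n_pulses = 1), "inter-pulse")
  expect_error(make_tms_train(tms_train(tms_pulse(), 1, n_pulses = 5), 2000,
                              0.005), "fit")
})

test_that("rate schedules convert to regular spike trains step by step", {
  # single 40 Hz step over 1 s: 40 spikes at 25 ms intervals
  s <- schedule_to_spike_train(afferent_schedule(0, 40), 1000)
  expect_length(s, 40)
  expect_equal(unique(diff(s)), 25)
  # zero rate -> empty
  expect_length(schedule_to_spike_train(afferent_schedule(0, 0), 1000), 0)
  # three-step storage program: measured per-step rates within one spike
  sch <- afferent_schedule(c(0, 1000, 2000), c(10, 25, 45))
  s3 <- schedule_to_spike_train(sch, 3000)
  for (i in 1:3) {
    w <- c((i - 1) * 1000, i * 1000)
    expect_lte(abs(sum(s3 >= w[1] & s3 < w[2]) - c(10, 25, 45)[i]), 1)
  }
  expect_error(afferent_schedule(c(0, 0), c(1, 2)), "increasing")
  expect_error(afferent_schedule(0, -5), "rates")
})

test_that("the Poisson afferent mode is reproducible under a seed and has the right rate", {
  sch <- afferent_schedule(0, 40, kind = "poisson")
  a <- schedule_to_spike_train(sch, 5000, seed = 7)
  b <- schedule_to_spike_train(sch, 5000, seed = 7)
  expect_identical(a, b)
  expect_lt(abs(length(a) / 5 - 40), 10) # ~40 Hz within sampling noise
})
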