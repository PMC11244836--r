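test_that("spike detection finds exactly the super-threshold excursions", {
  t <- seq(0, 300, by = 0.1)
  flat <- rep(-65, length(t))
  expect_length(detect_spikes(flat, t), 0)
  v <- flat
  for (ct in c(50, 100, 150)) v <- v + 95 * exp(-((t - ct)^2) / (2 * 0.5^2))
  s <- detect_spikes(v, t)
  expect_length(s, 3)
  expect_equal(s, c(50, 100, 150), tolerance = 2)
  expect_error(detect_spikes(v, t[-1]), "length")
  expect_error(detect_spikes(v[1:4], c(0, 1, 3, 7)), "uniform")
})

test_that("spike detection round-trips a generated trace fixture", {
  dir <- withr::local_tempdir()
  fx <- generate_fixture("trace", list(n_bumps = 5, spacing = 40), seed = 3,
                         dir = dir)
  df <- read.csv(fx$data, comment.char = "#")
  truth <- jsonlite::read_json(fx$sidecar, simplifyVector = TRUE)
  s <- detect_spikes(df$voltage, df$time)
  expect_length(s, truth$n_bumps)
  expect_equal(s, truth$centers_ms, tolerance = 2)
})

test_that("firing rate is count over window in Hz", {
  expect_equal(firing_rate(numeric(0), c(0, 1000)), 0)
  train <- seq(0, 975, by = 25)
  expect_equal(firing_rate(train, c(0, 1000)), 40)
  expect_error(firing_rate(train, c(10, 10)), "window")
})

test_that("burst statistics split trains at the ISI gap", {
  one <- burst_stats(100)
  expect_equal(one$n_spikes, 1)
  expect_equal(one$duration, 0)
  two <- burst_stats(c(0, 5, 10, 15, 20, 920, 925, 930, 935, 940), isi_gap = 20)
  expect_equal(nrow(two), 2)
  expect_equal(two$n_spikes, c(5, 5))
  expect_equal(two$rate, c(200, 200))
  expect_error(burst_stats(1, isi_gap = 0), "isi_gap")
})

test_that("coactivation index is a Jaccard over active bins", {
  w <- c(0, 1000)
  a <- seq(50, 950, by = 100)
  expect_equal(coactivation_index(a, a, w), 1)
  b <- a + 5000 # fully outside the window -> no overlap
  expect_equal(coactivation_index(a, b, w), 0)
  expect_equal(coactivation_index(a, numeric(0), w), 0)
  # 10 shared + 10 exclusive bins each -> 10 / 30
  w2 <- c(0, 3000)
  sh <- seq(50, 950, by = 100)
  a2 <- c(sh, seq(1050, 1950, by = 100))
  b2 <- c(sh, seq(2050, 2950, by = 100))
  expect_equal(coactivation_index(a2, b2, w2), 10 / 30, tolerance = 1e-9)
  # symmetry and common-shift invariance
  expect_equal(coactivation_index(a2, b2, w2), coactivation_index(b2, a2, w2))
  expect_equal(coactivation_index(a2 + 37, b2 + 37, w2 + 37),
               coactivation_index(a2, b2, w2))
})

test_that("voiding events require detrusor bursts inside sphincter and sympathetic pauses", {
  w <- c(0, 1000)
  expect_equal(nrow(voiding_event_detect(numeric(0), numeric(0), numeric(0), w)), 0)
  # regular sphincter train with a 100 ms pause; detrusor burst of 80 ms inside
  sph <- setdiff(seq(0, 980, by = 20), seq(500, 600, by = 20))
  sym <- sph
  det <- seq(505, 585, by = 10)
  ev <- voiding_event_detect(det, sph, sym, w)
  expect_equal(nrow(ev), 1)
  expect_lte(ev$duration, 120)
  expect_gte(ev$duration, 60)
  expect_gte(ev$onset, 480)
  expect_lte(ev$offset, 620)
  # no event when the sphincter never pauses
  ev0 <- voiding_event_detect(det, seq(0, 980, by = 20), sym, w)
  expect_equal(nrow(ev0), 0)
})

test_that("post-train persistence measures spiking beyond the train end", {
  expect_equal(post_train_persistence(c(10, 20), 50), 0)
  expect_equal(post_train_persistence(c(10, 125), 50), 75)
})

test_that("metrics are computable from exported CSV alone", {
  dir <- withr::local_tempdir()
  net <- build_network(lesion = lesion_spec("upper_T10"),
                       plasticity = plasticity_spec(preset = "sci"))
  sim <- simulate_network(net, afferent = afferent_schedule(0, 40),
                          duration = 400)
  write_result(sim, dir)
  spk <- read_spikes(file.path(dir, "spikes.csv"))
  expect_equal(firing_rate(spk[["4"]], c(0, 400)),
               firing_rate(sim$spikes[["4"]], c(0, 400)))
  expect_equal(coactivation_index(spk[["4"]], spk[["9"]], c(0, 400)),
               coactivation_index(sim$spikes[["4"]], sim$spikes[["9"]], c(0, 400)))
})
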