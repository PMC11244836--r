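test_that("the healthy preset leaves the topology untouched", {
  topo <- default_topology()
  net <- build_network(topo)
  expect_identical(net$edges$weight, topo$edges$weight)
  expect_equal(nrow(net$edges), nrow(topo$edges))
  expect_false(any(net$nodes$clamped))
})

test_that("an upper lesion zeroes exactly the edges crossing the T10 plane", {
  topo <- default_topology()
  net <- build_network(topo, lesion = lesion_spec("upper_T10"))
  flagged <- topo$edges$crosses == "above_T10"
  expect_true(any(flagged))
  expect_true(all(net$edges$weight[flagged] == 0))
  expect_identical(net$edges$weight[!flagged], topo$edges$weight[!flagged])
})

test_that("a conus lesion silences Nodes 8 and 9 under strong synaptic drive", {
  net <- build_network(lesion = lesion_spec("lower_conus"),
                       plasticity = plasticity_spec(preset = "sci"))
  sim <- simulate_network(net, afferent = afferent_schedule(0, 45),
                          duration = 2000)
  expect_length(sim$spikes[["8"]], 0)
  expect_length(sim$spikes[["9"]], 0)
  expect_gt(length(sim$spikes[["4"]]), 0) # the rest of the cord still works
})

test_that("plasticity multipliers act on the tagged edge groups only", {
  topo <- default_topology()
  net <- build_network(topo, plasticity = plasticity_spec(preset = "sci"))
  key <- paste(topo$edges$pre, topo$edges$post)
  for (spec in list(c("6 7", 2), c("5 7", 2), c("2 4", 2), c("5 4", 0.5))) {
    i <- which(key == spec[1])
    expect_equal(net$edges$weight[i], topo$edges$weight[i] * as.numeric(spec[2]))
  }
  expect_error(plasticity_spec(w67 = 0.5, w57 = 2, w24 = 2, w54 = 0.5),
               "plasticity")
})

test_that("a lesion level that matches nothing raises a warning", {
  topo <- default_topology()
  topo$edges <- topo$edges[topo$edges$crosses != "above_T10", ]
  expect_warning(build_network(topo, lesion = lesion_spec("upper_T10")),
                 "matched no edges")
})

test_that("edges referencing unknown nodes are rejected by name", {
  topo <- default_topology()
  topo$edges <- rbind(topo$edges, micturinet:::.edge_row("ghost", "4", 1))
  expect_error(build_network(topo), "ghost")
})

test_that("TMS may only target the lumbar interneurons", {
  net <- build_network()
  bad <- tms_train(tms_pulse(), frequency = 1, n_pulses = 1, targets = "4")
  expect_error(simulate_network(net, tms = bad, duration = 100), "lumbar")
  worse <- tms_train(tms_pulse(), frequency = 1, n_pulses = 1, targets = "nope")
  expect_error(simulate_network(net, tms = worse, duration = 100), "not in network")
})

test_that("a one-node network reproduces the standalone single-node integrator", {
  mem <- membrane_params("excitatory")
  net <- single_node_net(mem)
  tr <- tms_train(tms_pulse(peak_ku = 8), frequency = 30, n_pulses = 5,
                  targets = "n1")
  dur <- 300; dt <- 0.01
  sim <- simulate_network(net, tms = tr, duration = dur, dt = dt,
                          record_dt = dt)
  ku <- make_tms_train(tr, dur, dt / 2)[, 1]
  ref <- hh_simulate(mem, duration = dur, dt = dt, ku = ku)
  expect_equal(length(sim$spikes[["n1"]]), length(ref$spikes))
  if (length(ref$spikes) > 0)
    expect_lt(max(abs(sim$spikes[["n1"]] - ref$spikes)), 1e-6)
  expect_lt(max(abs(sim$v[, "n1"] - ref$v)), 1e-6)
})

test_that("quiescent healthy network stays silent and at rest", {
  net <- build_network()
  sim <- simulate_network(net, duration = 2000)
  expect_equal(sum(vapply(sim$spikes, length, 1L)), 0)
  for (id in c("4", "8", "9")) {
    v <- sim$v[sim$time >= 500, id]
    expect_lt(max(v) - min(v), 0.5) # within +-0.5 mV of rest
  }
})

test_that("simulation is deterministic: identical runs give identical spike times", {
  net <- build_network(lesion = lesion_spec("upper_T10"),
                       plasticity = plasticity_spec(preset = "sci"))
  a <- simulate_network(net, afferent = afferent_schedule(0, 40), duration = 500)
  b <- simulate_network(net, afferent = afferent_schedule(0, 40), duration = 500)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$v, b$v)
})

test_that("network spike counts converge under step halving", {
  net <- build_network(lesion = lesion_spec("upper_T10"),
                       plasticity = plasticity_spec(preset = "sci"))
  a <- simulate_network(net, afferent = afferent_schedule(0, 40),
                        duration = 500, dt = 0.01)
  b <- simulate_network(net, afferent = afferent_schedule(0, 40),
                        duration = 500, dt = 0.005)
  for (id in c("4", "8", "9"))
    expect_lte(abs(length(a$spikes[[id]]) - length(b$spikes[[id]])), 1)
})

test_that("cable conduction is 1:1 with a delay that grows with compartment count", {
  # empty in, empty out
  expect_length(cable_propagate(cable_spec(10), numeric(0)), 0)
  # single spike: one distal spike at the conduction delay
  d10 <- cable_propagate(cable_spec(10), 0)
  expect_length(d10, 1)
  expect_gt(d10[1], 2)      # physiologically plausible delay
  expect_lt(d10[1], 15)
  d20 <- cable_propagate(cable_spec(20), 0)
  d5 <- cable_propagate(cable_spec(5), 0)
  expect_gt(d20[1], d10[1]) # monotone in compartment count
  expect_gt(d10[1], d5[1])
  # a 40 Hz train conducts one-to-one
  train <- schedule_to_spike_train(afferent_schedule(0, 40), 1000)
  out <- cable_propagate(cable_spec(10), train)
  expect_length(out, length(train))
  expect_equal(attr(out, "dropped"), 0)
  expect_error(cable_spec(3), "5, 20")
})

test_that("relay filter has unity gain, first-order step response and unit impulse area", {
  dt <- 0.01; tau <- 10
  # constant input -> output converges to the input
  y <- relay_filter(rep(2, 20000), dt, tau)
  expect_equal(y[20000], 2, tolerance = 1e-3)
  # step response reaches 63.2% at t = tau
  ystep <- relay_filter(rep(1, 3000), dt, tau)
  expect_equal(ystep[round(tau / dt)], 1 - exp(-1), tolerance = 0.01)
  # impulse response integrates to one
  x <- c(1 / dt, rep(0, 99999))
  expect_equal(sum(relay_filter(x, dt, tau)) * dt, 1, tolerance = 0.001)
})
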