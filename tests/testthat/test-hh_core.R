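test_that("membrane derivative matches an independent textbook HH implementation", {
  p <- membrane_params("excitatory") # classical set, no shifts
  for (st in random_states(10)) {
    state <- neuron_state(st$v, st$m, st$h, st$n, gTMS = 0)
    got <- membrane_derivative(state, p, u = 0)
    want <- oracle_hh_rhs(st$v, st$m, st$h, st$n, p)
    expect_lt(abs(got$dv - want[["dv"]]), 1e-10)
    expect_lt(abs(got$dm - want[["dm"]]), 1e-10)
    expect_lt(abs(got$dh - want[["dh"]]), 1e-10)
    expect_lt(abs(got$dn - want[["dn"]]), 1e-10)
  }
})

test_that("resting state is an equilibrium of the membrane equation", {
  for (mem in list(membrane_params("excitatory"),
                   membrane_params("inhibitory"),
                   interneuron_params("excitatory"))) {
    vr <- hh_rest(mem)
    d <- membrane_derivative(neuron_state(vr, params = mem), mem)
    expect_lt(abs(d$dv), 1e-6)
    expect_lt(abs(d$dm), 1e-8)
  }
})

test_that("gTMS adds to the sodium conductance and deepens the inward current", {
  p <- membrane_params("excitatory")
  st <- neuron_state(-65)
  d0 <- membrane_derivative(st, p)
  # with gTMS > 0 at v < vNa the extra inward sodium current depolarises faster
  dg <- membrane_derivative(neuron_state(-65, gTMS = 1), p)
  expect_gt(dg$dv, d0$dv)
  # and the added term is exactly gTMS * (v - vNa) / c
  expect_equal(dg$dv - d0$dv, -1 * (-65 - p$vNa) / p$c, tolerance = 1e-12)
  # independent check against the oracle with an extra sodium conductance
  want <- oracle_hh_rhs(-65, st$m, st$h, st$n, p, g_extra_na = 1)
  expect_lt(abs(dg$dv - want[["dv"]]), 1e-10)
})

test_that("non-finite state values are rejected as numerical blow-up", {
  p <- membrane_params("excitatory")
  st <- neuron_state(-65)
  st$v <- NaN
  expect_error(membrane_derivative(st, p), "blow-up")
})

test_that("TMS conductance follows the closed-form decay and fixed point", {
  cp <- tms_coupling(k = 1, tau = 30)
  # free decay: g(t) = g0 exp(-t / tau)
  g <- 2
  for (i in 1:300) g <- tms_conductance_step(g, 0, cp, dt = 0.1)
  expect_equal(g, 2 * exp(-1), tolerance = 1e-6) # t = tau = 30 ms
  # constant input: fixed point k * u0
  g <- 0
  for (i in 1:5000) g <- tms_conductance_step(g, 3, cp, dt = 0.1)
  expect_equal(g, 3, tolerance = 1e-6)
  # guards
  expect_warning(tms_conductance_step(1, 0, cp, dt = 40), "inaccurate")
  expect_error(tms_coupling(tau = -1), "tau")
})

test_that("pulse-driven TMS conductance integral matches a fine-step reference", {
  pulse <- tms_pulse("biphasic", width_us = 210, peak_ku = 4)
  tau <- 30
  dt <- 0.002
  t_end <- 150
  drive <- function(t) max(emf_waveform(pulse, t), 0)
  # package path: exact exponential stepping, drive held at its midpoint value
  tg <- seq(0, t_end, by = dt)
  g <- numeric(length(tg))
  cp <- tms_coupling(k = 1, tau = tau)
  for (i in seq_along(tg)[-1]) {
    g[i] <- tms_conductance_step(g[i - 1], drive(tg[i - 1] + dt / 2), cp, dt = dt)
  }
  int_pkg <- sum((g[-1] + g[-length(g)]) / 2) * dt
  # oracle: forward Euler at dt / 100
  ref <- oracle_gtms(drive, tau, t_end, dt / 100)
  int_ref <- sum((ref$g[-1] + ref$g[-length(ref$g)]) / 2) * (dt / 100)
  expect_lt(abs(int_pkg - int_ref) / int_ref, 0.001)
})

test_that("synaptic gates jump on spikes and decay with the closed form", {
  syn <- synapse_params(weight = 0.7, vsyn = 0, tau = 10)
  # pure decay
  g <- 1
  for (i in 1:100) g <- synaptic_gate_step(g, FALSE, syn, dt = 0.1)
  expect_equal(g, exp(-1), tolerance = 1e-9)
  # jump by the weight
  expect_equal(synaptic_gate_step(0.2, TRUE, syn, dt = 1e-9), 0.9,
               tolerance = 1e-6)
  # steady-state peak under a regular 40 Hz train: w / (1 - exp(-25 / tau))
  g <- 0
  for (i in 1:200) { # 200 spikes at 25 ms intervals, decay between
    g <- synaptic_gate_step(g, TRUE, syn, dt = 1e-12)
    for (j in 1:25) g <- synaptic_gate_step(g, FALSE, syn, dt = 1)
  }
  peak <- synaptic_gate_step(g, TRUE, syn, dt = 1e-12)
  expect_equal(peak, 0.7 / (1 - exp(-25 / 10)), tolerance = 0.01)
})

test_that("single-node RK4 trajectories stay at rest without input", {
  for (mem in list(membrane_params("excitatory"),
                   membrane_params("inhibitory"),
                   interneuron_params("excitatory"))) {
    sim <- hh_simulate(mem, duration = 600, dt = 0.02)
    vr <- hh_rest(mem)
    expect_length(sim$spikes, 0)
    expect_lt(max(abs(sim$v[sim$time >= 100] - vr)), 0.5)
  }
})

test_that("suprathreshold drive spikes periodically and converges under step refinement", {
  p <- membrane_params("excitatory")
  s1 <- hh_simulate(p, duration = 1000, dt = 0.02, i_inj = 10)
  s2 <- hh_simulate(p, duration = 1000, dt = 0.01, i_inj = 10)
  expect_gt(length(s1$spikes), 30)
  expect_lte(abs(length(s1$spikes) - length(s2$spikes)), 1)
  isi <- diff(s1$spikes)
  expect_lt(max(isi) - min(isi), 0.5) # periodic
  # independent coarse oracle agrees on the count
  ref <- oracle_hh_integrate(p, i_ext = 10, t_end = 1000, dt = 0.002)
  expect_lte(abs(length(s1$spikes) - length(ref)), 1)
})

test_that("gating variables stay within [0, 1] along driven trajectories", {
  p <- membrane_params("inhibitory")
  nsteps <- round(300 / 0.02)
  ku <- rep(0.02, 2 * nsteps + 1) # sustained strong drive
  sim <- hh_simulate(p, duration = 300, dt = 0.02, ku = ku)
  expect_gt(length(sim$spikes), 3)
  # the integrator clamps and the invariant is asserted on the network engine
  # via its recorded traces being finite and bounded
  expect_true(all(is.finite(sim$v)))
  expect_true(all(sim$gTMS >= 0))
})

test_that("the inhibitory set out-fires the excitatory set at every tested TMS amplitude", {
  for (pk in c(1, 2, 4, 6)) {
    ni <- single_node_tms_response("inhibitory", "biphasic", 1, n_pulses = 2,
                                   peak_ku = pk)$n_spikes
    ne <- single_node_tms_response("excitatory", "biphasic", 1, n_pulses = 2,
                                   peak_ku = pk)$n_spikes
    expect_gte(ni, ne)
  }
})

test_that("membrane parameter invariants are enforced", {
  expect_error(membrane_params("excitatory", vNa = -80, vK = -77), "reversal")
  expect_error(membrane_params("excitatory", bogus = 1), "unknown")
  expect_lt(membrane_params("inhibitory")$gK,
            membrane_params("excitatory")$gK)
  expect_lt(interneuron_params("inhibitory")$gK,
            interneuron_params("excitatory")$gK)
  expect_error(neuron_state(-65, m = 1.5), "gating")
  expect_error(neuron_state(-65, gTMS = -1), "gTMS")
  expect_error(synapse_params(-1), "weight")
  expect_error(synapse_params(1, vsyn = -80, sign = "excitatory"), "excitatory")
})
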