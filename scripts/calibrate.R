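#!/usr/bin/env Rscript
# Re-derives the calibrated operating points of the shipped defaults and
# prints them as a table. Run from the repository root after installing the
# package:
#   Rscript scripts/calibrate.R
#
# The script sweeps the quantities that the default configuration was tuned
# on: the single-pulse TMS response of the two interneuron classes, the
# afferent-rate threshold of the voiding-reflex integrator (Node 7), the
# pelvic-cable conduction delay, and the storage staircase.

suppressPackageStartupMessages(library(micturinet))

cat("== single-pulse TMS response (peak ku = 4, width 210 us, tau = 30 ms) ==\n")
for (cls in c("excitatory", "inhibitory")) {
  for (shape in c("biphasic", "monophasic")) {
    r <- single_node_tms_response(cls, shape, 1, n_pulses = 1, duration = 600)
    cat(sprintf("  %-10s %-10s : %d spikes\n", cls, shape, r$n_spikes))
  }
}

cat("\n== 30 Hz train response (10 pulses) ==\n")
for (cls in c("excitatory", "inhibitory")) {
  r <- single_node_tms_response(cls, "biphasic", 30, n_pulses = 10)
  cat(sprintf("  %-10s : %d spikes (%.2f per pulse), persistence %.1f ms\n",
              cls, r$n_spikes, r$spikes_per_pulse, r$persistence))
}

cat("\n== Node 7 afferent-rate threshold (healthy weight, no inhibition) ==\n")
w <- default_weights(); w$w_6_7 <- 0
for (rate in c(10, 25, 35, 40, 45)) {
  r <- run_scenario("healthy_storage",
                    list(weights = w, duration = 1500,
                         afferent = afferent_schedule(0, rate)))
  cat(sprintf("  afferent %2d Hz -> Node 7 rate %.1f Hz\n", rate,
              firing_rate(r$spikes[["7"]], c(500, 1500))))
}

cat("\n== pelvic-cable conduction delay vs compartment count ==\n")
for (n in c(5, 10, 15, 20)) {
  d <- cable_propagate(cable_spec(n), 0)
  cat(sprintf("  %2d compartments : %.2f ms\n", n, d[1]))
}

cat("\n== storage staircase (Node 4 vs programmed afferent) ==\n")
st <- run_scenario("healthy_storage")
print(round(st$report$rates, 1))
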