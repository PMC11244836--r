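# Single-compartment Hodgkin-Huxley node dynamics, the TMS sodium-conductance
# perturbation, and synaptic gate kinetics.
#
# Units throughout: mV, ms, mS/cm^2, uF/cm^2, uA/cm^2 (1 kOhm^-1/cm^2 = 1 mS/cm^2).

# classical squid-axon parameter set (resting potential ~ -65 mV)
.hh_base <- list(
  c = 1, gNa = 120, gK = 36, gL = 0.3,
  vNa = 50, vK = -77, vL = -54.4,
  vshift_m = 0, vshift_h = 0, vshift_n = 0
)

#' Membrane parameters for a network node
#'
#' Builds the per-node Hodgkin-Huxley parameter set. Two excitability classes
#' are provided. Both share the classical squid-axon channel kinetics; a class
#' is obtained by scaling the channel densities (all maximal conductances and
#' the capacitance) by a common factor, so spike shape and resting potential
#' are preserved while the current threshold scales with the factor.
#' Inhibitory interneurons are modelled as low-threshold, fast-recruited cells:
#' their density scale is much smaller, and in particular their potassium
#' conductance `gK` is far below that of any excitatory node, which is what
#' makes them selectively responsive to weak TMS drive.
#'
#' @param excitability `"excitatory"` or `"inhibitory"`.
#' @param density channel-density scale applied to `c`, `gNa`, `gK`, `gL`.
#'   Defaults: 1 for excitatory projection/effector nodes, 0.03 for
#'   inhibitory interneurons. The calibrated sets for the TMS-facing lumbar
#'   interneurons are in [interneuron_params()].
#' @param ... named overrides of individual fields (`c`, `gNa`, `gK`, `gL`,
#'   `vNa`, `vK`, `vL`, and the gating voltage shifts `vshift_m`, `vshift_h`,
#'   `vshift_n`, which displace the corresponding rate functions along the
#'   voltage axis; positive values raise the recruitment voltage of that
#'   gate).
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(excitability = c("excitatory", "inhibitory"),
                            density = NULL, ...) {
  class <- match.arg(excitability)
  if (is.null(density)) density <- if (class == "inhibitory") 0.03 else 1
  p <- .hh_base
  for (f in c("c", "gNa", "gK", "gL")) p[[f]] <- p[[f]] * density
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown membrane parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  p$excitability_class <- class
  p$density <- density
  .validate_membrane(structure(p, class = "membrane_params"))
}

#' @export
print.membrane_params <- function(x, ...) {
  cat(sprintf(
    "<membrane_params> %s (density %.3g)\n  c=%.3g uF/cm^2  gNa=%.3g  gK=%.3g  gL=%.3g mS/cm^2\n  vNa=%.3g  vK=%.3g  vL=%.3g mV\n",
    x$excitability_class, x$density, x$c, x$gNa, x$gK, x$gL, x$vNa, x$vK, x$vL))
  invisible(x)
}

.validate_membrane <- function(p) {
  stopifnot(p$c > 0, p$gNa >= 0, p$gK >= 0, p$gL >= 0)
  if (!(p$vNa > p$vK)) stop("sodium reversal must lie above potassium reversal")
  p
}

# channel-gating rate functions (1/ms); x/(1-exp(-x/k)) with its limit at 0
.expdiv <- function(x, k) {
  e <- x / k
  ifelse(abs(e) < 1e-7, k * (1 + e / 2), x / (1 - exp(-e)))
}

hh_rates <- function(v, shift = c(0, 0, 0)) {
  vm <- v - shift[1]; vh <- v - shift[2]; vn <- v - shift[3]
  list(
    am = 0.1 * .expdiv(vm + 40, 10), bm = 4 * exp(-(vm + 65) / 18),
    ah = 0.07 * exp(-(vh + 65) / 20), bh = 1 / (1 + exp(-(vh + 35) / 10)),
    an = 0.01 * .expdiv(vn + 55, 10), bn = 0.125 * exp(-(vn + 65) / 80)
  )
}

.shifts <- function(params) {
  c(params$vshift_m %||% 0, params$vshift_h %||% 0, params$vshift_n %||% 0)
}

#' Steady-state gating variables at a holding potential
#' @param v membrane potential (mV)
#' @param shift gating voltage shifts `c(m, h, n)` in mV
#' @return named vector `c(m, h, n)`
#' @export
hh_steady_gating <- function(v, shift = c(0, 0, 0)) {
  r <- hh_rates(v, shift)
  c(m = r$am / (r$am + r$bm), h = r$ah / (r$ah + r$bh), n = r$an / (r$an + r$bn))
}

#' Resting potential of a parameter set
#'
#' Solves for the zero of the steady-state ionic current. For the shipped
#' classes this is the classical ~ -65 mV regardless of density scale.
#' @param params a [membrane_params()] object
#' @return resting potential (mV)
#' @export
hh_rest <- function(params) {
  sh <- .shifts(params)
  f <- function(v) {
    g <- hh_steady_gating(v, sh)
    params$gNa * g["m"]^3 * g["h"] * (v - params$vNa) +
      params$gK * g["n"]^4 * (v - params$vK) + params$gL * (v - params$vL)
  }
  uniroot(f, c(-90, -45), tol = 1e-10)$root
}

#' Dynamic state of a Hodgkin-Huxley node
#'
#' @param v membrane potential (mV)
#' @param m,h,n gating variables in `[0, 1]`; default: steady state at `v`
#' @param gTMS TMS-gated sodium conductance (mS/cm^2), `>= 0`
#' @param params optional [membrane_params()]; when given, the steady-state
#'   gating defaults honour that set's gating voltage shifts
#' @export
neuron_state <- function(v, m = NULL, h = NULL, n = NULL, gTMS = 0,
                         params = NULL) {
  ss <- hh_steady_gating(v, if (is.null(params)) c(0, 0, 0) else .shifts(params))
  if (is.null(m)) m <- unname(ss["m"])
  if (is.null(h)) h <- unname(ss["h"])
  if (is.null(n)) n <- unname(ss["n"])
  s <- list(v = v, m = m, h = h, n = n, gTMS = gTMS)
  if (any(!is.finite(unlist(s)))) stop("non-finite neuron state")
  if (any(c(m, h, n) < 0 | c(m, h, n) > 1)) stop("gating variables must lie in [0, 1]")
  if (gTMS < 0) stop("gTMS must be >= 0")
  structure(s, class = "neuron_state")
}

#' TMS-to-conductance coupling
#'
#' @param k gain (mS/cm^2 per unit EMF); proportional to the inverse square of
#'   the coil-to-neuron distance. The shipped EMF waveforms are already scaled
#'   to a peak `k * u` so the default gain is 1.
#' @param tau closing time constant of the TMS-gated sodium conductance (ms).
#'   The long default produces bursting after single pulses.
#' @export
tms_coupling <- function(k = 1, tau = 30) {
  if (k < 0) stop("TMS gain k must be >= 0")
  if (tau <= 0) stop("TMS time constant tau must be > 0")
  structure(list(k = k, tau = tau), class = "tms_coupling")
}

#' Synapse parameters
#'
#' @param weight coupling strength (conductance increment per presynaptic
#'   spike, mS/cm^2), `>= 0`
#' @param vsyn synaptic reversal potential (mV); at or above 0 for excitatory
#'   synapses, at or below -70 for inhibitory ones
#' @param tau gate decay time constant (ms)
#' @param sign `"excitatory"` or `"inhibitory"`; inferred from `vsyn` if missing
#' @export
synapse_params <- function(weight, vsyn = 0, tau = 5, sign = NULL) {
  if (weight < 0) stop("synaptic weight must be >= 0")
  if (tau <= 0) stop("synaptic tau must be > 0")
  if (is.null(sign)) sign <- if (vsyn >= -40) "excitatory" else "inhibitory"
  if (sign == "excitatory" && vsyn < -40)
    stop("excitatory synapse requires vsyn at or above the threshold region")
  if (sign == "inhibitory" && vsyn > -65)
    stop("inhibitory synapse requires vsyn at or below the resting potential")
  structure(list(weight = weight, vsyn = vsyn, tau = tau, sign = sign),
            class = "synapse_params")
}

#' Time derivative of a Hodgkin-Huxley node state
#'
#' The membrane equation follows the standard convention in which every ionic
#' and synaptic current opposes the capacitive current,
#' `c dv/dt = -(gNa m^3 h + gTMS)(v - vNa) - gK n^4 (v - vK) - gL (v - vL)
#'            - sum_s s (v - vsyn) + I_inj`.
#' The TMS conductance adds to the sodium conductance, so the sodium current is
#' `(gNa m^3 h + gTMS)(v - vNa)`.
#'
#' @param state a [neuron_state()]
#' @param params a [membrane_params()]
#' @param u EMF value at the current time (already including any per-node gain
#'   beyond `coupling$k`)
#' @param syn_inputs list of `list(synapse = synapse_params, gate = value)`
#'   pairs; `gate` is the current conductance of that synapse
#' @param coupling a [tms_coupling()]
#' @param i_inj injected current (uA/cm^2)
#' @param tms_drive `"rectified"` clips negative EMF lobes to zero before they
#'   reach the conductance equation; `"signed"` passes them through (the
#'   conductance itself is floored at zero by the integrators)
#' @return list with elements `dv`, `dm`, `dh`, `dn`, `dgTMS` (per ms)
#' @export
membrane_derivative <- function(state, params, u = 0, syn_inputs = list(),
                                coupling = tms_coupling(), i_inj = 0,
                                tms_drive = c("rectified", "signed")) {
  tms_drive <- match.arg(tms_drive)
  .validate_membrane(params)
  if (any(!is.finite(c(state$v, state$m, state$h, state$n, state$gTMS))))
    stop("non-finite state values: numerical blow-up")
  v <- state$v
  r <- hh_rates(v, .shifts(params))
  isyn <- 0
  for (si in syn_inputs) {
    isyn <- isyn + si$gate * (v - si$synapse$vsyn)
  }
  ion <- (params$gNa * state$m^3 * state$h + state$gTMS) * (v - params$vNa) +
    params$gK * state$n^4 * (v - params$vK) + params$gL * (v - params$vL)
  drv <- coupling$k * u
  if (tms_drive == "rectified") drv <- max(drv, 0)
  list(
    dv = (-(ion) - isyn + i_inj) / params$c,
    dm = r$am * (1 - state$m) - r$bm * state$m,
    dh = r$ah * (1 - state$h) - r$bh * state$h,
    dn = r$an * (1 - state$n) - r$bn * state$n,
    dgTMS = (drv - state$gTMS) / coupling$tau
  )
}

#' Advance the TMS-gated sodium conductance by one step
#'
#' Integrates `gTMS + tau * dgTMS/dt = k u` exactly over a step during which
#' `u` is held constant: `g' = g e^(-dt/tau) + k u (1 - e^(-dt/tau))`.
#'
#' @param gTMS current conductance (mS/cm^2)
#' @param u EMF value over the step
#' @param coupling a [tms_coupling()]
#' @param dt step (ms); a warning is issued when `dt >= tau` since the
#'   held-constant-input assumption is then inaccurate for pulsed inputs
#' @return updated conductance, floored at zero
#' @export
tms_conductance_step <- function(gTMS, u, coupling = tms_coupling(), dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (dt >= coupling$tau)
    warning("dt >= tau: TMS conductance update is inaccurate at this step size")
  a <- exp(-dt / coupling$tau)
  max(gTMS * a + coupling$k * u * (1 - a), 0)
}

#' Advance a synaptic gate by one step
#'
#' The gate jumps by `weight` on a presynaptic spike and otherwise decays
#' exponentially with the synaptic time constant.
#'
#' @param gate current gate value (>= 0)
#' @param spike logical (or 0/1): presynaptic spike at the start of the step
#' @param params a [synapse_params()]
#' @param dt step (ms)
#' @export
synaptic_gate_step <- function(gate, spike, params, dt) {
  if (gate < 0) stop("gate must be >= 0")
  (gate + params$weight * as.numeric(spike)) * exp(-dt / params$tau)
}

#' Integrate a single node with fixed-step RK4
#'
#' Reference single-compartment integrator, written entirely in R. It uses the
#' same fourth-order scheme and half-step stimulus sampling as the compiled
#' network engine, so a one-node network reproduces this trajectory to
#' round-off. Mainly used for validation and calibration; scenario work should
#' go through [simulate_network()].
#'
#' @param params a [membrane_params()]
#' @param duration simulated time (ms)
#' @param dt step (ms)
#' @param ku EMF drive `k * u` sampled on the half-step grid
#'   `seq(0, duration, dt/2)` (length `2 * nsteps + 1`), or a single 0
#' @param coupling a [tms_coupling()] (only `tau` is used; `ku` carries the gain)
#' @param i_inj constant injected current (uA/cm^2)
#' @param syn_times,syn spike times (ms) arriving at an afferent synapse `syn`
#'   (a [synapse_params()]); optional
#' @param v0 initial potential; default the resting potential
#' @param tms_drive see [membrane_derivative()]
#' @param spike_threshold,refractory spike detection: upward crossing (mV) with
#'   dead time (ms)
#' @return list with `time`, `v`, `gTMS`, `spikes` (ms)
#' @export
hh_simulate <- function(params, duration, dt = 0.01, ku = 0,
                        coupling = tms_coupling(), i_inj = 0,
                        syn_times = numeric(), syn = NULL, v0 = NULL,
                        tms_drive = c("rectified", "signed"),
                        spike_threshold = 0, refractory = 2) {
  tms_drive <- match.arg(tms_drive)
  .validate_membrane(params)
  nsteps <- round(duration / dt)
  if (length(ku) == 1) ku <- rep(ku, 2 * nsteps + 1)
  if (length(ku) != 2 * nsteps + 1)
    stop("ku must be sampled on the half-step grid (length 2 * nsteps + 1)")
  if (tms_drive == "rectified") ku <- pmax(ku, 0)
  if (is.null(v0)) v0 <- hh_rest(params)
  sh <- .shifts(params)
  ss <- hh_steady_gating(v0, sh)
  x <- c(v0, ss["m"], ss["h"], ss["n"], 0, 0) # v, m, h, n, gTMS, syn gate
  stau <- if (is.null(syn)) 1 else syn$tau
  svs <- if (is.null(syn)) 0 else syn$vsyn
  f <- function(x, u) {
    v <- x[1]; m <- x[2]; h <- x[3]; nn <- x[4]; g <- x[5]; s <- x[6]
    r <- hh_rates(v, sh)
    ion <- (params$gNa * m^3 * h + g) * (v - params$vNa) +
      params$gK * nn^4 * (v - params$vK) + params$gL * (v - params$vL)
    c((-(ion) - s * (v - svs) + i_inj) / params$c,
      r$am * (1 - m) - r$bm * m,
      r$ah * (1 - h) - r$bh * h,
      r$an * (1 - nn) - r$bn * nn,
      (u - g) / coupling$tau,
      -s / stau)
  }
  vtr <- numeric(nsteps + 1); gtr <- numeric(nsteps + 1)
  vtr[1] <- x[1]; gtr[1] <- x[5]
  spikes <- numeric(0); last <- -Inf
  syn_times <- sort(syn_times); sp <- 1
  for (i in seq_len(nsteps)) {
    t <- (i - 1) * dt
    while (sp <= length(syn_times) && syn_times[sp] < t + dt) {
      if (syn_times[sp] >= t) x[6] <- x[6] + syn$weight
      sp <- sp + 1
    }
    u0 <- ku[2 * i - 1]; uh <- ku[2 * i]; u1 <- ku[2 * i + 1]
    k1 <- f(x, u0)
    k2 <- f(x + dt / 2 * k1, uh)
    k3 <- f(x + dt / 2 * k2, uh)
    k4 <- f(x + dt * k3, u1)
    vold <- x[1]
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    x[2:4] <- pmin(pmax(x[2:4], 0), 1)
    x[5] <- max(x[5], 0)
    if (!is.finite(x[1]) || abs(x[1]) > 200)
      stop(sprintf("numerical blow-up at t = %.4f ms", t + dt))
    if (vold < spike_threshold && x[1] >= spike_threshold &&
        (t + dt) - last >= refractory) {
      tspk <- t + dt * (spike_threshold - vold) / (x[1] - vold)
      spikes <- c(spikes, tspk)
      last <- tspk
    }
    vtr[i + 1] <- x[1]; gtr[i + 1] <- x[5]
  }
  list(time = seq(0, by = dt, length.out = nsteps + 1),
       v = vtr, gTMS = gtr, spikes = spikes)
}


#' Calibrated membrane sets for the TMS-facing lumbar interneurons
#'
#' The differential TMS sensitivity of the lumbar interneurons rests on two
#' calibrated parameter sets:
#'
#' * `"inhibitory"` (Node 2 and Node 6): a low-threshold, fast-recruited cell
#'   obtained by scaling the classical channel densities down (default 0.03),
#'   leaving a potassium conductance far below that of any excitatory node.
#'   A single pulse of the standard TMS drive elicits a short burst that
#'   decays back to rest well before the next 1 Hz pulse.
#' * `"excitatory"` (Nodes 1 and 3): a high-threshold slow integrator with a
#'   high input resistance (gL = 0.02 mS/cm^2 anchored at -65 mV), sparse
#'   sodium/potassium channels (gNa = 20, gK = 6 mS/cm^2) recruited only well
#'   above rest (m/h shifted +16 mV, n shifted +25 mV), and a shallow
#'   after-spike reset (vK = -70 mV). A single TMS pulse depolarises it by
#'   roughly 15 mV -- clearly subthreshold -- while the accumulated
#'   conductance of a 30 Hz train (whose mean drive is thirty-fold larger)
#'   carries it across threshold, where the pulses entrain roughly one spike
#'   per stimulus.
#'
#' @param class `"excitatory"` or `"inhibitory"`
#' @return a [membrane_params()] object
#' @export
interneuron_params <- function(class = c("excitatory", "inhibitory")) {
  class <- match.arg(class)
  if (class == "inhibitory") return(membrane_params("inhibitory"))
  membrane_params("excitatory", density = 1,
                  c = 0.8, gNa = 20, gK = 6, gL = 0.02,
                  vK = -70, vL = -65,
                  vshift_m = 16, vshift_h = 16, vshift_n = 25)
}
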