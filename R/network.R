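# Circuit construction, lesion and plasticity overlays, the pelvic-nerve
# cable, pass-through relays, and the network simulation wrapper.
#
# Node ids follow the circuit diagram convention:
#   1, 3  excitatory lumbar interneurons (TMS targets)
#   2     inhibitory lumbar interneuron (TMS target)
#   4     sympathetic preganglionic / hypogastric efferent (detrusor relaxation)
#   5     pelvic-nerve bladder afferent, modelled as a multi-compartment cable
#         (compartments "5.1" ... "5.(N-1)" with the distal compartment "5")
#   6     lumbar inhibitory interneuron keeping the spinal voiding reflex latent
#   7     lumbar interneuron of the spinal (infantile) voiding reflex
#   8     parasympathetic preganglionic neuron (detrusor contraction; the same
#         population is labelled "Node 10" in some figures)
#   9     somatic motor neuron of the Nucleus of Onuf (external sphincter)
#   PSC, PMC_exc, PMC_inh  pontine storage / micturition centres
#   PAG   periaqueductal grey, a rate-threshold gate on ascending afferents
#   asc_psc  first-order relay carrying afferent drive to the PSC

#' Lesion specification
#' @param level `"none"`, `"upper_T10"` (suprasacral transection: every edge
#'   crossing the T10 plane is silenced) or `"lower_conus"` (conus injury:
#'   Nodes 8 and 9 are made inactive and unresponsive to synaptic input).
#' @export
lesion_spec <- function(level = c("none", "upper_T10", "lower_conus")) {
  level <- match.arg(level)
  structure(list(level = level), class = "lesion_spec")
}

#' Post-injury synaptic plasticity overlay
#'
#' Multipliers applied to the four connection groups that reorganise after a
#' spinal cord injury: the inhibitory 6->7 connection, the afferent limb 5->7
#' of the spinal voiding reflex, the inhibitory 2->4 connection, and the
#' excitatory sympathetic path from the afferent to Node 4 (weakened).
#'
#' @param w67,w57,w24 strengthening multipliers (>= 1 under the post-injury
#'   preset)
#' @param w54 attenuation multiplier for the 5->4 excitatory path (<= 1 under
#'   the post-injury preset)
#' @param preset `"healthy"` (all 1) or `"sci"` (2, 2, 2, 0.5)
#' @export
plasticity_spec <- function(w67 = 1, w57 = 1, w24 = 1, w54 = 1,
                            preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("healthy", "sci"))
    if (preset == "sci") {
      w67 <- 2; w57 <- 2; w24 <- 2; w54 <- 0.5
    } else {
      w67 <- w57 <- w24 <- w54 <- 1
    }
  }
  if (any(c(w67, w57, w24, w54) <= 0)) stop("plasticity multipliers must be > 0")
  active <- !(w67 == 1 && w57 == 1 && w24 == 1 && w54 == 1)
  if (active && (w67 < 1 || w57 < 1 || w24 < 1 || w54 > 1))
    stop("post-injury plasticity strengthens 6->7, 5->7, 2->4 and weakens 5->4")
  structure(list(w67 = w67, w57 = w57, w24 = w24, w54 = w54),
            class = "plasticity_spec")
}

#' Pelvic-nerve cable specification
#'
#' The bladder afferent is a chain of 5-20 identically parameterised axonal
#' compartments with ohmic axial coupling; a spike injected proximally
#' regenerates compartment by compartment, which supplies the conduction
#' delay between the bladder and its rostral receptive sites.
#'
#' @param n_compartments integer in `[5, 20]`
#' @param g_axial axial coupling conductance between neighbouring compartments
#'   (mS/cm^2)
#' @param membrane per-compartment [membrane_params()]
#' @param input_weight synaptic weight of the afferent injection into the
#'   proximal compartment
#' @export
cable_spec <- function(n_compartments = 10, g_axial = 0.25,
                       membrane = membrane_params("excitatory"),
                       input_weight = 0.5) {
  if (n_compartments < 5 || n_compartments > 20)
    stop("n_compartments must lie in [5, 20]")
  if (g_axial <= 0) stop("axial conductance must be > 0")
  structure(list(n_compartments = as.integer(n_compartments),
                 g_axial = g_axial, membrane = membrane,
                 input_weight = input_weight),
            class = "cable_spec")
}

#' Default synaptic weights of the circuit
#'
#' Named list of the coupling strengths (mS/cm^2 conductance increments per
#' presynaptic spike, or drive conductances for relay/gate edges) and synaptic
#' time constants (ms) used by [default_topology()]. The values are the
#' package calibration under which the healthy storage and voiding behaviours,
#' the post-injury dyssynergia/incontinence patterns and the TMS frequency
#' contrast all hold; scripts/calibrate.R re-derives the critical ones.
#' Override individual entries and pass the list to [default_topology()] or a
#' scenario's `weights` override.
#'
#' @return named list of weights
#' @export
default_weights <- function() {
  list(
    aff      = 0.5,   # bladder afferent -> proximal cable compartment
    w_5_4    = 0.20,  # sympathetic storage reflex (plasticity group "p54")
    w_5_9    = 0.20,  # spinal sphincter storage reflex
    w_5_7    = 0.030, # afferent limb of the spinal voiding reflex ("p57")
    w_6_7    = 1.0,   # latent-reflex inhibition ("p67")
    w_3_6    = 0.02,
    w_3_9    = 1.5,
    w_7_8    = 0.20,
    w_1_8    = 0.20,
    w_2_4    = 1.5,   # inhibitory, strengthened after SCI ("p24")
    w_2_9    = 0.8,
    w_psc    = 0.25,  # ascending relay -> PSC continuous drive
    w_psc_3  = 0.10,
    w_pmc_1  = 0.10,
    w_pmc_2  = 0.02,
    w_pmci_psc = 3.0, # PMC -> PSC reciprocal inhibition
    w_pag    = 0.15,  # PAG gate -> PMC drive conductance
    tau_exc  = 3,     # excitatory synaptic decay (ms)
    tau_inh  = 15     # inhibitory synaptic decay (ms)
  )
}

.node_row <- function(id, kind, role, membrane = NULL, relay_tau = 10,
                      tms_target = FALSE, pag_threshold = 35, i_inj = 0) {
  if (is.null(membrane)) membrane <- membrane_params("excitatory")
  data.frame(id = id, kind = kind, role = role,
             class = membrane$excitability_class,
             c = membrane$c, gNa = membrane$gNa, gK = membrane$gK,
             gL = membrane$gL, vNa = membrane$vNa, vK = membrane$vK,
             vL = membrane$vL,
             vshift_m = membrane$vshift_m %||% 0,
             vshift_h = membrane$vshift_h %||% 0,
             vshift_n = membrane$vshift_n %||% 0,
             relay_tau = relay_tau,
             tms_target = tms_target, tms_k = 1, tms_tau = 30,
             pag_threshold = pag_threshold, i_inj = i_inj,
             stringsAsFactors = FALSE)
}

.edge_row <- function(pre, post, weight, vsyn = 0, tau = 3, type = "spike",
                      crosses = "none", group = "") {
  data.frame(pre = pre, post = post, weight = weight, vsyn = vsyn, tau = tau,
             type = type, crosses = crosses, group = group,
             stringsAsFactors = FALSE)
}

#' Default micturition circuit topology
#'
#' Builds the node and edge tables of the storage/voiding circuit: the spinal
#' reflex arcs (afferent cable to sympathetic Node 4, sphincter Node 9, and the
#' latent voiding-reflex interneuron Node 7), the brainstem loop (ascending
#' relay to PSC and PAG, the PAG rate-threshold gate on the pontine micturition
#' centre, reciprocal PMC/PSC inhibition), the descending pathways relayed by
#' the TMS-responsive lumbar interneurons 1-3, and the latent-reflex inhibition
#' via Node 6.
#'
#' @param weights named list as produced by [default_weights()]
#' @param cable a [cable_spec()] for the pelvic afferent
#' @param pag_threshold afferent rate (Hz) above which the PAG gates the PMC on
#' @return list with elements `nodes`, `edges`, `cable`
#' @export
default_topology <- function(weights = default_weights(),
                             cable = cable_spec(), pag_threshold = 35) {
  w <- weights
  std <- membrane_params("excitatory")
  exc_tms <- interneuron_params("excitatory")
  inh <- interneuron_params("inhibitory")

  n <- cable$n_compartments
  cable_ids <- c(paste0("5.", seq_len(n - 1)), "5")
  nodes <- do.call(rbind, c(
    lapply(cable_ids, function(id)
      .node_row(id, "hh", "pelvic afferent cable compartment", cable$membrane)),
    list(
      .node_row("1", "hh", "excitatory lumbar interneuron (TMS)", exc_tms,
                tms_target = TRUE),
      .node_row("2", "hh", "inhibitory lumbar interneuron (TMS)", inh,
                tms_target = TRUE),
      .node_row("3", "hh", "excitatory lumbar interneuron (TMS)", exc_tms,
                tms_target = TRUE),
      .node_row("4", "hh", "sympathetic preganglionic / hypogastric efferent", std),
      .node_row("6", "hh", "inhibitory interneuron gating the voiding reflex", inh),
      .node_row("7", "hh", "spinal voiding-reflex interneuron (afferent-rate integrator)",
                exc_tms),
      .node_row("8", "hh", "parasympathetic preganglionic (detrusor)", std),
      .node_row("9", "hh", "Onuf somatic motor neuron (sphincter)", std),
      .node_row("PSC", "hh", "pontine storage centre", std),
      .node_row("PMC_exc", "hh", "pontine micturition centre, excitatory", std),
      .node_row("PMC_inh", "hh", "pontine micturition centre, inhibitory", std),
      .node_row("asc_psc", "relay", "ascending afferent-rate relay to PSC",
                relay_tau = 100),
      .node_row("PAG", "pag", "periaqueductal grey rate-threshold gate",
                relay_tau = 100, pag_threshold = pag_threshold)
    )))

  ax <- do.call(rbind, lapply(seq_len(n - 1), function(i)
    .edge_row(cable_ids[i], cable_ids[i + 1], cable$g_axial, type = "axial")))

  edges <- rbind(
    .edge_row("afferent", cable_ids[1], cable$input_weight),
    ax,
    # spinal reflex arcs
    .edge_row("5", "4", w$w_5_4, tau = w$tau_exc, group = "p54"),
    .edge_row("5", "9", w$w_5_9, tau = w$tau_exc),
    .edge_row("5", "7", w$w_5_7, tau = 8, group = "p57"),
    # ascending pathways (cross the T10 plane)
    .edge_row("5", "asc_psc", 1, crosses = "above_T10"),
    .edge_row("5", "PAG", 1, crosses = "above_T10"),
    # brainstem
    .edge_row("asc_psc", "PSC", w$w_psc, type = "drive"),
    .edge_row("PAG", "PMC_exc", w$w_pag, type = "drive"),
    .edge_row("PAG", "PMC_inh", w$w_pag, type = "drive"),
    .edge_row("PMC_inh", "PSC", w$w_pmci_psc, vsyn = -80, tau = w$tau_inh),
    # descending pathways (cross the T10 plane)
    .edge_row("PSC", "3", w$w_psc_3, tau = w$tau_exc, crosses = "above_T10"),
    .edge_row("PMC_exc", "1", w$w_pmc_1, tau = w$tau_exc, crosses = "above_T10"),
    .edge_row("PMC_exc", "2", w$w_pmc_2, tau = w$tau_exc, crosses = "above_T10"),
    # lumbar interneuronal network
    .edge_row("3", "6", w$w_3_6, tau = w$tau_exc),
    .edge_row("3", "9", w$w_3_9, tau = w$tau_exc),
    .edge_row("6", "7", w$w_6_7, vsyn = -80, tau = w$tau_inh, group = "p67"),
    .edge_row("7", "8", w$w_7_8, tau = w$tau_exc),
    .edge_row("1", "8", w$w_1_8, tau = w$tau_exc),
    .edge_row("2", "4", w$w_2_4, vsyn = -80, tau = w$tau_inh, group = "p24"),
    .edge_row("2", "9", w$w_2_9, vsyn = -80, tau = w$tau_inh)
  )
  list(nodes = nodes, edges = edges, cable = cable)
}

#' Assemble a simulable network
#'
#' Applies the lesion and plasticity overlays to a topology. An upper (T10)
#' lesion zeroes the weight of every edge crossing the lesion plane; a conus
#' lesion clamps Nodes 8 and 9 at rest and makes them unresponsive to synaptic
#' input. Plasticity multipliers act on the tagged edge groups.
#'
#' @param topology as returned by [default_topology()]
#' @param lesion a [lesion_spec()]
#' @param plasticity a [plasticity_spec()]
#' @param hc_permit logical: do higher centres permit voiding? Gates the PAG.
#' @return object of class `micturition_network`
#' @export
build_network <- function(topology = default_topology(),
                          lesion = lesion_spec("none"),
                          plasticity = plasticity_spec(),
                          hc_permit = TRUE) {
  nodes <- topology$nodes
  edges <- topology$edges
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  known <- c(nodes$id, "afferent")
  for (col in c("pre", "post")) {
    bad <- setdiff(edges[[col]], known)
    if (length(bad))
      stop("edge references unknown node id(s): ", paste(bad, collapse = ", "))
  }
  nodes$clamped <- FALSE
  if (lesion$level == "upper_T10") {
    hit <- edges$crosses == "above_T10"
    if (!any(hit)) warning("upper_T10 lesion matched no edges")
    edges$weight[hit] <- 0
  } else if (lesion$level == "lower_conus") {
    hit <- nodes$id %in% c("8", "9")
    if (!any(hit)) warning("lower_conus lesion matched no nodes")
    nodes$clamped[hit] <- TRUE
  }
  mult <- c(p67 = plasticity$w67, p57 = plasticity$w57,
            p24 = plasticity$w24, p54 = plasticity$w54)
  for (g in names(mult)) {
    edges$weight[edges$group == g] <- edges$weight[edges$group == g] * mult[[g]]
  }
  structure(list(nodes = nodes, edges = edges, cable = topology$cable,
                 lesion = lesion, plasticity = plasticity,
                 hc_permit = hc_permit),
            class = "micturition_network")
}

#' @export
print.micturition_network <- function(x, ...) {
  cat(sprintf("<micturition_network> %d nodes, %d edges; lesion: %s\n",
              nrow(x$nodes), nrow(x$edges), x$lesion$level))
  invisible(x)
}

#' First-order relay filter
#'
#' Low-pass of a sampled input signal with unity steady-state gain, the
#' behaviour of the unnumbered pass-through nodes: a constant input is passed
#' unchanged in steady state, a step reaches 63.2% of its asymptote after one
#' time constant, and the impulse response integrates to one.
#'
#' @param x input samples
#' @param dt sampling step (ms)
#' @param tau relay time constant (ms)
#' @return filtered signal of the same length
#' @export
relay_filter <- function(x, dt, tau) {
  if (tau <= 0) stop("relay tau must be > 0")
  a <- exp(-dt / tau)
  y <- numeric(length(x))
  prev <- 0
  for (i in seq_along(x)) {
    prev <- a * prev + (1 - a) * x[i]
    y[i] <- prev
  }
  y
}

# map the network + stimuli onto the compiled engine's argument lists
.compile_and_run <- function(network, aff_times, tms = NULL, duration,
                             dt = 0.01, record_dt = 0.1,
                             tms_drive = c("rectified", "signed"),
                             hc_permit = network$hc_permit) {
  tms_drive <- match.arg(tms_drive)
  if (duration <= 0 || dt <= 0) stop("duration and dt must be > 0")
  nodes <- network$nodes
  edges <- network$edges
  nsteps <- round(duration / dt)
  record_every <- max(1L, round(record_dt / dt))

  kind_code <- c(hh = 0L, relay = 1L, pag = 2L)[nodes$kind]
  idx <- seq_len(nrow(nodes)); names(idx) <- nodes$id

  # resting potential per distinct parameter set
  key <- paste(nodes$gNa, nodes$gK, nodes$gL, nodes$vNa, nodes$vK, nodes$vL,
               nodes$vshift_m, nodes$vshift_h, nodes$vshift_n)
  v0 <- numeric(nrow(nodes))
  for (k in unique(key[nodes$kind == "hh"])) {
    sel <- which(key == k & nodes$kind == "hh")
    p <- as.list(nodes[sel[1], c("c", "gNa", "gK", "gL", "vNa", "vK", "vL",
                                 "vshift_m", "vshift_h", "vshift_n")])
    v0[sel] <- hh_rest(structure(p, class = "membrane_params"))
  }

  tms_col <- integer(nrow(nodes))
  ku <- matrix(0, nrow = 1, ncol = 1)
  if (!is.null(tms) && tms$n_pulses > 0) {
    unknown <- setdiff(tms$targets, nodes$id)
    if (length(unknown))
      stop("TMS target(s) not in network: ", paste(unknown, collapse = ", "))
    ok <- nodes$tms_target[idx[tms$targets]]
    if (!all(ok))
      stop("TMS may only target the lumbar interneurons (Nodes 1, 2, 3); got: ",
           paste(tms$targets[!ok], collapse = ", "))
    ku <- make_tms_train(tms, duration, dt / 2)
    for (j in seq_along(tms$targets)) {
      i <- idx[tms$targets[j]]
      tms_col[i] <- j
      ku[, j] <- ku[, j] * nodes$tms_k[i]
    }
  }

  nl <- list(kind = kind_code, clamped = as.integer(nodes$clamped),
             tms_col = tms_col, pag_permit = as.integer(rep(hc_permit, nrow(nodes))),
             c = nodes$c, gNa = nodes$gNa, gK = nodes$gK, gL = nodes$gL,
             vNa = nodes$vNa, vK = nodes$vK, vL = nodes$vL,
             vshift_m = nodes$vshift_m, vshift_h = nodes$vshift_h,
             vshift_n = nodes$vshift_n,
             relay_tau = nodes$relay_tau, tms_tau = nodes$tms_tau,
             i_inj = if (is.null(nodes$i_inj)) rep(0, nrow(nodes)) else nodes$i_inj,
             v0 = v0,
             pag_threshold = nodes$pag_threshold)
  pre_i <- ifelse(edges$pre == "afferent", 0L, idx[edges$pre])
  el <- list(pre = as.integer(pre_i), post = as.integer(idx[edges$post]),
             type = c(spike = 0L, drive = 1L, axial = 2L)[edges$type],
             weight = edges$weight, vsyn = edges$vsyn, tau = edges$tau)

  out <- .sim_network_cpp(nl, el, as.numeric(sort(aff_times)), ku, dt, nsteps,
                          0, 2, record_every, tms_drive == "rectified")
  colnames(out$v) <- nodes$id
  names(out$spikes) <- nodes$id
  out
}

#' Simulate the micturition network
#'
#' Advances every Hodgkin-Huxley node, cable compartment, relay and synaptic
#' gate on a shared clock with fixed-step RK4. Deterministic: identical
#' configuration, step size and seed reproduce identical spike times.
#'
#' @param network a [build_network()] result
#' @param afferent an [afferent_schedule()], or a numeric vector of afferent
#'   spike times (ms), or `NULL` for no bladder drive
#' @param tms a [tms_train()] or `NULL`; targets must be lumbar interneurons
#' @param duration simulated time (ms)
#' @param dt integration step (ms); the default resolves the 210 us TMS pulse
#' @param record_dt sampling interval of the stored voltage traces (ms);
#'   spikes are always detected at full resolution
#' @param seed integer seed (only consumed by a Poisson afferent schedule)
#' @param tms_drive `"rectified"` (default) clips negative EMF lobes before
#'   the conductance equation; `"signed"` passes them and floors the
#'   conductance at zero
#' @return object of class `micturition_sim`: list with `time` (ms), `v`
#'   (matrix, one column per node, mV), `spikes` (named list of spike times),
#'   and `meta` (scenario metadata)
#' @export
simulate_network <- function(network, afferent = NULL, tms = NULL, duration,
                             dt = 0.01, record_dt = 0.1, seed = NULL,
                             tms_drive = c("rectified", "signed")) {
  tms_drive <- match.arg(tms_drive)
  aff_times <- numeric(0)
  if (inherits(afferent, "afferent_schedule")) {
    aff_times <- schedule_to_spike_train(afferent, duration, seed = seed)
  } else if (is.numeric(afferent)) {
    aff_times <- afferent
  } else if (!is.null(afferent)) {
    stop("afferent must be an afferent_schedule, numeric spike times, or NULL")
  }
  out <- .compile_and_run(network, aff_times, tms, duration, dt, record_dt,
                          tms_drive)
  structure(list(
    time = out$time, v = out$v, spikes = out$spikes,
    meta = list(duration = duration, dt = dt, record_dt = record_dt,
                lesion = network$lesion$level,
                plasticity = unclass(network$plasticity),
                hc_permit = network$hc_permit,
                tms = if (is.null(tms)) NULL else unclass(tms),
                afferent = if (inherits(afferent, "afferent_schedule"))
                  unclass(afferent) else afferent,
                seed = seed, tms_drive = tms_drive)),
    class = "micturition_sim")
}

#' @export
print.micturition_sim <- function(x, ...) {
  ns <- vapply(x$spikes, length, 1L)
  cat(sprintf("<micturition_sim> %.0f ms, dt = %g ms, lesion: %s\n",
              x$meta$duration, x$meta$dt, x$meta$lesion))
  on <- ns[ns > 0]
  if (length(on))
    cat("  spikes:", paste(sprintf("%s=%d", names(on), on), collapse = " "), "\n")
  invisible(x)
}

#' Conduct a spike train along the pelvic-nerve cable
#'
#' Injects the proximal train into an isolated cable and returns the distal
#' spike times. At physiological rates conduction is one-to-one and each spike
#' is shifted by the cable's total conduction delay, which grows with the
#' number of compartments at fixed per-compartment parameters.
#'
#' @param cable a [cable_spec()]
#' @param spikes sorted proximal spike times (ms)
#' @param duration simulated time (ms); default covers the input plus 50 ms
#' @param dt integration step (ms)
#' @return distal spike times; attribute `dropped` gives the number of input
#'   spikes that failed to conduct (a warning is raised when positive)
#' @export
cable_propagate <- function(cable, spikes, duration = NULL, dt = 0.01) {
  if (is.unsorted(spikes)) stop("spike train must be sorted")
  if (is.null(duration)) duration <- (if (length(spikes)) max(spikes) else 0) + 50
  n <- cable$n_compartments
  ids <- c(paste0("5.", seq_len(n - 1)), "5")
  nodes <- do.call(rbind, lapply(ids, function(id)
    .node_row(id, "hh", "cable compartment", cable$membrane)))
  ax <- do.call(rbind, lapply(seq_len(n - 1), function(i)
    .edge_row(ids[i], ids[i + 1], cable$g_axial, type = "axial")))
  edges <- rbind(.edge_row("afferent", ids[1], cable$input_weight), ax)
  net <- build_network(list(nodes = nodes, edges = edges, cable = cable))
  out <- .compile_and_run(net, spikes, NULL, duration, dt)
  distal <- out$spikes[["5"]]
  dropped <- length(spikes) - length(distal)
  if (dropped > 0)
    warning(sprintf("%d of %d spikes failed to conduct", dropped, length(spikes)))
  structure(distal, dropped = max(dropped, 0))
}
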