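# Turn-key reproductions of the study conditions: healthy storage, healthy
# voiding, dyssynergia after an upper (T10) injury, incontinence after a conus
# injury, TMS after an upper injury, and the single-node TMS sensitivity runs.

.scenario_names <- c("healthy_storage", "healthy_voiding", "sci_upper",
                     "sci_lower", "sci_upper_tms")

#' Configuration bundle for a named scenario
#'
#' Returns the full configuration (lesion, plasticity, higher-centre permit,
#' afferent schedule, TMS train, duration, solver settings) for one of the
#' five study scenarios. `overrides` is a named list patched over the
#' defaults, so any run is reproducible from the emitted snapshot.
#'
#' Defaults: storage drives the bladder afferent in three steps,
#' 10 / 25 / 45 Hz at 0 / 1000 / 2000 ms over 3 s with the higher centres
#' withholding voiding; voiding holds a full-bladder 45 Hz drive for 2 s with
#' voiding permitted; both injury scenarios use the post-injury plasticity
#' overlay and a full-bladder 40 Hz drive; the TMS scenario defaults to 1 Hz
#' biphasic pulses at t = 0 and 1000 ms.
#'
#' @param name one of `"healthy_storage"`, `"healthy_voiding"`, `"sci_upper"`,
#'   `"sci_lower"`, `"sci_upper_tms"`
#' @param overrides named list; recognised keys include `duration`, `dt`,
#'   `afferent` (an [afferent_schedule()]), `tms` (a [tms_train()]),
#'   `tms_frequency`, `tms_shape`, `n_pulses`, `hc_permit`, `lesion`,
#'   `plasticity`, `weights`, `pag_threshold`, `seed`
#' @return a list of class `scenario_config`
#' @export
scenario_config <- function(name = .scenario_names, overrides = list()) {
  name <- match.arg(name)
  cfg <- list(
    name = name,
    duration = switch(name, healthy_storage = , sci_lower = 3000, 2000),
    dt = 0.01,
    record_dt = 0.1,
    weights = default_weights(),
    pag_threshold = 35,
    lesion = switch(name,
                    sci_upper = , sci_upper_tms = "upper_T10",
                    sci_lower = "lower_conus",
                    "none"),
    plasticity = if (name %in% c("sci_upper", "sci_lower", "sci_upper_tms"))
      "sci" else "healthy",
    hc_permit = name == "healthy_voiding",
    afferent = switch(name,
      healthy_storage = , sci_lower =
        afferent_schedule(c(0, 1000, 2000), c(10, 25, 45)),
      healthy_voiding = afferent_schedule(0, 45),
      afferent_schedule(0, 40)),
    tms = NULL,
    seed = NULL
  )
  if (name == "sci_upper_tms") {
    freq <- overrides$tms_frequency %||% 1
    shape <- overrides$tms_shape %||% "biphasic"
    npls <- overrides$n_pulses %||% if (freq >= 30) 30 else 2
    cfg$duration <- if (freq >= 30) 1000 else 2000
    cfg$tms <- tms_train(tms_pulse(shape), frequency = freq, n_pulses = npls)
  }
  known <- c(names(cfg), "tms_frequency", "tms_shape", "n_pulses")
  bad <- setdiff(names(overrides), known)
  if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "))
  cfg[intersect(names(overrides), names(cfg))] <-
    overrides[intersect(names(overrides), names(cfg))]
  if (name != "sci_upper_tms" && !is.null(cfg$tms))
    stop("a TMS train is only valid in the sci_upper_tms scenario")
  if (name == "sci_upper_tms" && cfg$lesion == "none")
    stop("sci_upper_tms requires an upper_T10 lesion")
  structure(cfg, class = "scenario_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a named scenario
#'
#' Builds the matching network / lesion / plasticity / stimulus bundle,
#' simulates it, and attaches a [metric_report()]. The configuration snapshot
#' is stored in the result, and re-running a snapshot reproduces the spike
#' times exactly.
#'
#' @param name scenario name (see [scenario_config()]), or a ready
#'   `scenario_config`
#' @param overrides named list patched over the scenario defaults
#' @return a `micturition_sim` with elements `report` (a `metric_report`) and
#'   `config` (the snapshot) added
#' @export
run_scenario <- function(name, overrides = list()) {
  cfg <- if (inherits(name, "scenario_config")) name
         else scenario_config(name, overrides)
  topo <- default_topology(weights = cfg$weights,
                           pag_threshold = cfg$pag_threshold)
  net <- build_network(topo,
                       lesion = lesion_spec(cfg$lesion),
                       plasticity = plasticity_spec(preset = cfg$plasticity),
                       hc_permit = cfg$hc_permit)
  sim <- simulate_network(net, afferent = cfg$afferent, tms = cfg$tms,
                          duration = cfg$duration, dt = cfg$dt,
                          record_dt = cfg$record_dt, seed = cfg$seed)
  windows <- if (inherits(cfg$afferent, "afferent_schedule") &&
                 length(cfg$afferent$start) > 1) {
    st <- cfg$afferent$start
    en <- c(st[-1], cfg$duration)
    w <- lapply(seq_along(st), function(i) c(st[i], en[i]))
    names(w) <- paste0("step", seq_along(st))
    w
  } else {
    list(full = c(0, cfg$duration))
  }
  sim$report <- metric_report(sim, windows = windows)
  sim$config <- cfg
  sim
}

#' Response of one isolated interneuron to a TMS train
#'
#' Simulates a single lumbar interneuron of the given excitability class under
#' a TMS pulse train and summarises its spiking: total count, spikes per
#' pulse, burst structure, and how long spiking persists beyond the train.
#'
#' @param class `"excitatory"` or `"inhibitory"`
#' @param shape `"biphasic"` or `"monophasic"`
#' @param frequency pulse rate (Hz); 1 and 30 are the study presets
#' @param n_pulses pulses in the train; default 2 at 1 Hz (t = 0 and 1000 ms)
#'   and 10 at higher rates
#' @param duration simulated time (ms); default covers the train plus 500 ms
#' @param dt integration step (ms)
#' @param peak_ku,tau EMF peak drive (mS/cm^2) and conductance closing time
#'   constant (ms)
#' @return list with `spikes`, `n_spikes`, `spikes_per_pulse`, `bursts`,
#'   `bursts_per_pulse`, `persistence` (ms past the last pulse onset + width),
#'   `train_end` and the simulation object
#' @export
single_node_tms_response <- function(class = c("excitatory", "inhibitory"),
                                     shape = c("biphasic", "monophasic"),
                                     frequency = 1, n_pulses = NULL,
                                     duration = NULL, dt = 0.01,
                                     peak_ku = 4, tau = 30) {
  class <- match.arg(class)
  shape <- match.arg(shape)
  if (is.null(n_pulses)) n_pulses <- if (frequency < 10) 2 else 10
  mem <- interneuron_params(class)
  train_end <- (n_pulses - 1) * 1000 / frequency + 0.21
  if (is.null(duration)) duration <- n_pulses * 1000 / frequency + 500
  nodes <- .node_row("n1", "hh", paste(class, "lumbar interneuron"), mem,
                     tms_target = TRUE)
  nodes$tms_tau <- tau
  net <- build_network(list(nodes = nodes,
                            edges = .edge_row("n1", "n1", 0)[0, ],
                            cable = NULL))
  train <- tms_train(tms_pulse(shape, peak_ku = peak_ku),
                     frequency = frequency, n_pulses = n_pulses,
                     targets = "n1")
  # targets checked against the tms_target flag, not the lumbar ids, for
  # single-node probes
  sim <- simulate_network(net, tms = train, duration = duration, dt = dt)
  spk <- sim$spikes[["n1"]]
  bursts <- burst_stats(spk)
  list(spikes = spk, n_spikes = length(spk),
       spikes_per_pulse = length(spk) / max(n_pulses, 1),
       bursts = bursts,
       bursts_per_pulse = nrow(bursts) / max(n_pulses, 1),
       persistence = post_train_persistence(spk, train_end),
       train_end = train_end, sim = sim)
}

#' Contrast low- and high-frequency TMS after an upper injury
#'
#' Runs the upper-injury scenario under TMS at each requested frequency and
#' reports the coordinated-voiding metrics: voiding events per pulse and their
#' latency/duration, plus sphincter (Node 9) and sympathetic (Node 4) rates.
#' `frequency = 0` denotes the no-TMS reference and reduces exactly to the
#' plain upper-injury scenario.
#'
#' @param frequencies numeric vector of pulse rates (Hz; 0 = no TMS)
#' @param shape pulse shape
#' @param overrides extra scenario overrides
#' @return named list (one element per frequency) of lists with `events`,
#'   `events_per_pulse`, `latencies`, `rates` and the scenario result
#' @export
tms_frequency_contrast <- function(frequencies = c(1, 30),
                                   shape = "biphasic", overrides = list()) {
  out <- list()
  for (f in frequencies) {
    if (f == 0) {
      res <- run_scenario("sci_upper", overrides)
      pulses <- numeric(0)
    } else {
      res <- run_scenario("sci_upper_tms",
                          modifyList(overrides,
                                     list(tms_frequency = f, tms_shape = shape)))
      tr <- res$config$tms
      pulses <- tr$onset + (seq_len(tr$n_pulses) - 1) * 1000 / tr$frequency
    }
    ev <- voiding_event_detect(res$spikes[["8"]], res$spikes[["9"]],
                               res$spikes[["4"]], c(0, res$meta$duration))
    lat <- if (nrow(ev) && length(pulses)) {
      vapply(ev$onset, function(o) {
        prior <- pulses[pulses <= o]
        if (length(prior)) o - max(prior) else NA_real_
      }, 1)
    } else numeric(0)
    out[[as.character(f)]] <- list(
      frequency = f, events = ev,
      events_per_pulse = if (length(pulses)) nrow(ev) / length(pulses) else NA,
      latencies = lat, pulses = pulses,
      rates = res$report$rates, result = res)
  }
  out
}
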