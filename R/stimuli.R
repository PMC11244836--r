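# TMS coil pulses, their induced EMF waveforms, pulse trains, and
# bladder-afferent drive schedules.

#' A single TMS coil pulse
#'
#' The EMF induced by the coil is the time derivative of the coil current, so
#' a biphasic coil pulse (one full sine cycle of coil current) induces a
#' tri-phasic EMF (+, -, + lobes), while a monophasic pulse (fast quarter-sine
#' rise, slow smooth return) induces a biphasic EMF whose positive lobe carries
#' half the area of the biphasic pulse's positive lobes at equal peak. Both
#' waveforms return the coil current to baseline, so the EMF integrates to
#' zero over the pulse.
#'
#' @param shape `"biphasic"` or `"monophasic"`
#' @param width_us total pulse width in microseconds
#' @param peak_ku peak of the EMF drive `k * u` (mS/cm^2)
#' @export
tms_pulse <- function(shape = c("biphasic", "monophasic"), width_us = 210,
                      peak_ku = 4) {
  shape <- match.arg(shape)
  if (width_us <= 0) stop("pulse width must be > 0")
  if (peak_ku < 0) stop("peak_ku must be >= 0")
  structure(list(shape = shape, width_us = width_us, peak_ku = peak_ku),
            class = "tms_pulse")
}

#' EMF waveform of a TMS pulse
#'
#' Evaluates the induced EMF drive `k * u` on a time grid. The waveform is
#' scaled so its maximum equals `peak_ku` and is identically zero outside the
#' pulse support `[0, width]`.
#'
#' Biphasic: `u(t) = peak * cos(2 pi t / T)` (three lobes, +, -, +).
#' Monophasic: quarter-cosine positive lobe on `[0, T/4]` followed by a shallow
#' sine return lobe of amplitude `peak / 3` on `[T/4, T]`; the lobe areas
#' cancel exactly.
#'
#' @param pulse a [tms_pulse()]
#' @param t time grid (ms), starting at the pulse onset; its resolution must be
#'   at most `width / 20`
#' @return numeric vector of EMF drive values (mS/cm^2)
#' @export
emf_waveform <- function(pulse, t) {
  Tms <- pulse$width_us / 1000
  if (length(t) > 1 && max(diff(t)) > Tms / 20 + 1e-12)
    stop("time grid too coarse for the EMF waveform: need resolution <= width / 20")
  u <- numeric(length(t))
  inside <- t >= 0 & t <= Tms
  if (pulse$shape == "biphasic") {
    u[inside] <- pulse$peak_ku * cos(2 * pi * t[inside] / Tms)
  } else {
    rise <- inside & t <= Tms / 4
    fall <- inside & t > Tms / 4
    u[rise] <- pulse$peak_ku * cos(2 * pi * t[rise] / Tms)
    u[fall] <- -pulse$peak_ku / 3 * sin(pi * (t[fall] - Tms / 4) / (3 * Tms / 4))
  }
  u
}

#' A TMS pulse train
#'
#' @param pulse a [tms_pulse()]
#' @param frequency pulse repetition rate (Hz); 1 and 30 are the presets used
#'   throughout
#' @param n_pulses number of pulses
#' @param onset time of the first pulse (ms)
#' @param targets node ids receiving the train; only the lumbar interneurons
#'   `"1"`, `"2"`, `"3"` are valid targets
#' @export
tms_train <- function(pulse = tms_pulse(), frequency, n_pulses, onset = 0,
                      targets = c("1", "2", "3")) {
  if (frequency <= 0) stop("frequency must be > 0")
  ipi <- 1000 / frequency
  if (ipi <= pulse$width_us / 1000)
    stop("inter-pulse interval must exceed the pulse width")
  if (n_pulses < 0) stop("n_pulses must be >= 0")
  structure(list(pulse = pulse, frequency = frequency, n_pulses = n_pulses,
                 onset = onset, targets = as.character(targets)),
            class = "tms_train")
}

#' Sample a TMS train's EMF drive on a time grid
#'
#' The same waveform is delivered to every target (the induced field is common
#' to the stimulated region; per-node gain differences belong in the coupling
#' gain of each node).
#'
#' @param train a [tms_train()]
#' @param duration simulation length (ms); the train must fit inside it
#' @param dt grid step (ms)
#' @return matrix with `length(seq(0, duration, dt))` rows and one column per
#'   target, column names the target ids
#' @export
make_tms_train <- function(train, duration, dt) {
  if (train$onset + train$n_pulses * 1000 / train$frequency > duration + 1e-9)
    stop("TMS train does not fit inside the simulation duration")
  t <- seq(0, duration, by = dt)
  u <- numeric(length(t))
  if (train$n_pulses > 0) {
    starts <- train$onset + (seq_len(train$n_pulses) - 1) * 1000 / train$frequency
    for (s in starts) u <- u + emf_waveform(train$pulse, t - s)
  }
  m <- matrix(u, nrow = length(t), ncol = length(train$targets))
  colnames(m) <- train$targets
  m
}

#' Piecewise-constant bladder-afferent firing-rate schedule
#'
#' @param start step onset times (ms), strictly increasing, first at 0
#' @param rate firing rate of each step (Hz), `>= 0`
#' @param kind `"regular"` (deterministic, the default) or `"poisson"`
#' @export
afferent_schedule <- function(start, rate, kind = c("regular", "poisson")) {
  kind <- match.arg(kind)
  if (length(start) != length(rate)) stop("start and rate must have equal length")
  if (length(start) == 0) stop("schedule must contain at least one step")
  if (any(diff(start) <= 0)) stop("step start times must be strictly increasing")
  if (any(rate < 0)) stop("rates must be >= 0")
  structure(list(start = start, rate = rate, kind = kind),
            class = "afferent_schedule")
}

#' Convert a rate schedule to a spike train
#'
#' Within each step of the schedule spikes are regular with inter-spike
#' interval `1000 / rate` ms, starting at the step onset; step boundaries are
#' respected. The optional Poisson mode draws exponential intervals and is the
#' only stochastic element in the package.
#'
#' @param schedule an [afferent_schedule()]
#' @param duration total length (ms)
#' @param seed integer seed, used only for `kind = "poisson"`
#' @return sorted spike times (ms)
#' @export
schedule_to_spike_train <- function(schedule, duration, seed = NULL) {
  if (duration <= 0) stop("duration must be > 0")
  ends <- c(schedule$start[-1], duration)
  spikes <- numeric(0)
  if (schedule$kind == "poisson" && !is.null(seed)) set.seed(seed)
  for (i in seq_along(schedule$start)) {
    t0 <- schedule$start[i]; t1 <- min(ends[i], duration); r <- schedule$rate[i]
    if (r <= 0 || t1 <= t0) next
    if (schedule$kind == "regular") {
      isi <- 1000 / r
      s <- seq(t0, t1, by = isi)
      spikes <- c(spikes, s[s < t1 - 1e-9])
    } else {
      t <- t0 + rexp(1, r / 1000)
      while (t < t1) {
        spikes <- c(spikes, t)
        t <- t + rexp(1, r / 1000)
      }
    }
  }
  sort(spikes)
}
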