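# Spike detection and the behavioural metrics that turn voltage traces into
# physiological statements: firing rates, burst statistics, post-train
# persistence, dyssynergia coactivation, and voiding-event detection.
# All metrics operate on plain spike-time vectors / traces, so they can be
# computed from the CSV exports alone.

#' Detect spikes in a voltage trace
#'
#' One spike per upward threshold crossing, with a refractory dead time.
#'
#' @param trace voltage samples (mV) on a uniform grid
#' @param time sample times (ms), same length as `trace`
#' @param threshold crossing level (mV)
#' @param refractory dead time after a detected spike (ms)
#' @return sorted spike times (ms), linearly interpolated at the crossing
#' @export
detect_spikes <- function(trace, time, threshold = 0, refractory = 2) {
  if (length(trace) != length(time)) stop("trace and time must have equal length")
  if (length(time) > 2) {
    dtv <- diff(time)
    if (max(dtv) - min(dtv) > 1e-6 * max(dtv)) stop("time grid must be uniform")
  }
  up <- which(trace[-length(trace)] < threshold & trace[-1] >= threshold)
  if (!length(up)) return(numeric(0))
  tc <- time[up] + (time[up + 1] - time[up]) *
    (threshold - trace[up]) / (trace[up + 1] - trace[up])
  keep <- logical(length(tc))
  last <- -Inf
  for (i in seq_along(tc)) {
    if (tc[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- tc[i]
    }
  }
  tc[keep]
}

#' Mean firing rate in a window
#' @param spikes spike times (ms)
#' @param window `c(t0, t1)` in ms, `t1 > t0`
#' @return rate in Hz
#' @export
firing_rate <- function(spikes, window) {
  if (window[2] <= window[1]) stop("window must satisfy t1 > t0")
  n <- sum(spikes >= window[1] & spikes < window[2])
  1000 * n / (window[2] - window[1])
}

#' Burst statistics of a spike train
#'
#' Bursts are maximal runs of spikes whose consecutive inter-spike intervals
#' do not exceed `isi_gap`; an isolated spike is a one-spike burst.
#'
#' @param spikes sorted spike times (ms)
#' @param isi_gap maximal within-burst inter-spike interval (ms)
#' @return data.frame with columns `onset`, `offset`, `n_spikes`, `duration`
#'   (ms) and `rate` (within-burst rate in Hz, `(n-1)/duration`; `NA` for
#'   single-spike bursts)
#' @export
burst_stats <- function(spikes, isi_gap = 20) {
  if (isi_gap <= 0) stop("isi_gap must be > 0")
  if (!length(spikes))
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      n_spikes = integer(0), duration = numeric(0),
                      rate = numeric(0)))
  spikes <- sort(spikes)
  brk <- c(0, which(diff(spikes) > isi_gap), length(spikes))
  out <- lapply(seq_len(length(brk) - 1), function(i) {
    s <- spikes[(brk[i] + 1):brk[i + 1]]
    data.frame(onset = s[1], offset = s[length(s)], n_spikes = length(s),
               duration = s[length(s)] - s[1],
               rate = if (length(s) > 1) 1000 * (length(s) - 1) /
                 (s[length(s)] - s[1]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Coactivation index of two spike trains
#'
#' The window is divided into bins; the index is the number of bins in which
#' both trains fire divided by the number of bins in which either fires
#' (Jaccard over active bins). Zero when either train is empty. Symmetric and
#' invariant to a common time shift of both trains and the window.
#'
#' @param a,b spike-time vectors (ms)
#' @param window `c(t0, t1)` shared analysis window (ms)
#' @param bin bin width (ms)
#' @return value in `[0, 1]`
#' @export
coactivation_index <- function(a, b, window, bin = 100) {
  if (bin <= 0) stop("bin must be > 0")
  if (!length(a) || !length(b)) return(0)
  edges <- seq(window[1], window[2], by = bin)
  if (edges[length(edges)] < window[2]) edges <- c(edges, window[2])
  cut_a <- table(cut(a[a >= window[1] & a < window[2]], edges)) > 0
  cut_b <- table(cut(b[b >= window[1] & b < window[2]], edges)) > 0
  either <- sum(cut_a | cut_b)
  if (either == 0) return(0)
  sum(cut_a & cut_b) / either
}

#' Detect coordinated voiding events
#'
#' A voiding event is an interval in which the detrusor drive (parasympathetic
#' preganglionic train) is burst-active while both the external-sphincter
#' motor train and the sympathetic train are paused -- i.e. detrusor
#' contraction coordinated with sphincter relaxation and withdrawal of
#' sympathetic detrusor inhibition.
#'
#' A train is "paused" wherever the local inter-spike gap (window edges count
#' as boundaries) exceeds `gap_factor` times its own median inter-spike
#' interval, which makes the criterion scale-free across efferent rates. A
#' train with fewer than two spikes in the window is treated as paused
#' throughout.
#'
#' @param detrusor,sphincter,sympathetic spike-time vectors (ms)
#' @param window `c(t0, t1)` shared window (ms)
#' @param bin event-timing resolution (ms)
#' @param gap_factor pause threshold as a multiple of the train's median ISI
#' @param burst_gap maximal within-burst ISI for the detrusor train (ms)
#' @return data.frame with `onset`, `offset`, `duration` (ms), one row per event
#' @export
voiding_event_detect <- function(detrusor, sphincter, sympathetic, window,
                                 bin = 20, gap_factor = 1.8, burst_gap = 20) {
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0))
  if (!length(detrusor)) return(empty)
  edges <- seq(window[1], window[2], by = bin)
  if (length(edges) < 2) return(empty)
  nb <- length(edges) - 1
  paused <- function(s) {
    s <- s[s >= window[1] & s <= window[2]]
    if (length(s) < 2) return(rep(TRUE, nb))
    thr <- gap_factor * stats::median(diff(s))
    aug <- c(window[1], s, window[2])
    gaps <- diff(aug)
    open <- which(gaps > thr)
    out <- rep(FALSE, nb)
    for (g in open) {
      a <- aug[g]; b <- aug[g + 1]
      out <- out | (edges[-length(edges)] >= a & edges[-1] <= b)
    }
    out
  }
  sph_pause <- paused(sphincter)
  sym_pause <- paused(sympathetic)
  bursts <- burst_stats(detrusor, isi_gap = burst_gap)
  det_active <- vapply(seq_len(nb), function(i) {
    any(bursts$onset < edges[i + 1] & bursts$offset + burst_gap > edges[i])
  }, logical(1))
  act <- det_active & sph_pause & sym_pause
  if (!any(act)) return(empty)
  r <- rle(act)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1
  ev <- data.frame(onset = edges[starts[r$values]],
                   offset = edges[stops[r$values] + 1])
  ev$duration <- ev$offset - ev$onset
  ev
}

#' Post-train spiking persistence
#'
#' How long spiking outlasts the end of a stimulus train: the time from
#' `train_end` to the last spike, floored at zero.
#'
#' @param spikes spike times (ms)
#' @param train_end end of the stimulus train (ms)
#' @return persistence in ms
#' @export
post_train_persistence <- function(spikes, train_end) {
  after <- spikes[spikes > train_end]
  if (!length(after)) return(0)
  max(after) - train_end
}

#' Summary metric report for a simulation
#'
#' @param result a `micturition_sim`
#' @param windows named list of `c(t0, t1)` analysis windows (ms); default one
#'   window spanning the run
#' @param nodes node ids to summarise; default the efferent trio 4, 8, 9
#' @param bin coactivation bin (ms)
#' @param burst_gap burst ISI gap (ms)
#' @return object of class `metric_report`: per-node rates by window, burst
#'   tables, pairwise coactivation of Nodes 4/8/9, and voiding events
#' @export
metric_report <- function(result, windows = NULL, nodes = c("4", "8", "9"),
                          bin = 100, burst_gap = 20) {
  dur <- result$meta$duration
  if (is.null(windows)) windows <- list(full = c(0, dur))
  rates <- sapply(windows, function(w)
    vapply(nodes, function(id) firing_rate(result$spikes[[id]], w), 1))
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = length(nodes),
                                           dimnames = list(nodes, names(windows)))
  bursts <- lapply(result$spikes[nodes], burst_stats, isi_gap = burst_gap)
  co <- list()
  have <- intersect(c("4", "8", "9"), names(result$spikes))
  for (i in seq_along(have)) for (j in seq_along(have)) if (i < j) {
    co[[paste(have[i], have[j], sep = "-")]] <-
      coactivation_index(result$spikes[[have[i]]], result$spikes[[have[j]]],
                         c(0, dur), bin = bin)
  }
  events <- if (all(c("8", "9", "4") %in% names(result$spikes))) {
    voiding_event_detect(result$spikes[["8"]], result$spikes[["9"]],
                         result$spikes[["4"]], c(0, dur))
  } else NULL
  structure(list(rates = rates, bursts = bursts, coactivation = co,
                 voiding_events = events, windows = windows),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\nmean rates (Hz):\n")
  print(round(x$rates, 1))
  if (length(x$coactivation)) {
    cat("coactivation:",
        paste(sprintf("%s=%.2f", names(x$coactivation),
                      unlist(x$coactivation)), collapse = " "), "\n")
  }
  if (!is.null(x$voiding_events))
    cat(sprintf("voiding events: %d\n", nrow(x$voiding_events)))
  invisible(x)
}
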