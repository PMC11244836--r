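# Configuration loading, result export in plain-text formats, and the
# deterministic fixture generator used by the analysis-layer tests.
#
# CSV dialect: comma separated, header row, '.' decimal, UTF-8; a leading
# '#' comment line states the units (times in ms, voltages in mV).

#' Load a scenario configuration file
#'
#' Reads a JSON or YAML scenario description, validates it and fills defaults.
#' Recognised top-level keys: `name` (a scenario preset) and any override
#' accepted by [scenario_config()]; `afferent` may be given as a list with
#' `start` and `rate` vectors, `tms` as a list with `shape`, `frequency`,
#' `n_pulses`, `onset`.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`
#' @return a `scenario_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$name)) stop("config key 'name' is required")
  ov <- raw[setdiff(names(raw), "name")]
  if (!is.null(ov$afferent)) {
    a <- ov$afferent
    if (is.null(a$start) || is.null(a$rate))
      stop("config key 'afferent' requires 'start' and 'rate'")
    ov$afferent <- afferent_schedule(unlist(a$start), unlist(a$rate),
                                     kind = a$kind %||% "regular")
  }
  if (!is.null(ov$tms)) {
    tm <- ov$tms
    ov$tms <- tms_train(tms_pulse(tm$shape %||% "biphasic",
                                  width_us = tm$width_us %||% 210,
                                  peak_ku = tm$peak_ku %||% 4),
                        frequency = tm$frequency,
                        n_pulses = tm$n_pulses,
                        onset = tm$onset %||% 0,
                        targets = tm$targets %||% c("1", "2", "3"))
  }
  scenario_config(raw$name, ov)
}

#' Write a scenario configuration snapshot
#' @param config a `scenario_config`
#' @param path output path (`.yaml` or `.json`)
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$weights <- NULL # reproducible from the package defaults
  if (inherits(x$afferent, "afferent_schedule")) x$afferent <- unclass(x$afferent)
  if (inherits(x$tms, "tms_train")) {
    x$tms <- c(unclass(x$tms$pulse),
               x$tms[c("frequency", "n_pulses", "onset", "targets")])
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

.write_commented_csv <- function(df, path, comment) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  write.csv(df, con, row.names = FALSE)
}

.read_commented_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
           colClasses = NA)
}

#' Export a simulation result to a directory
#'
#' Writes tidy voltage traces (`traces.csv`: time, node, voltage), spike times
#' (`spikes.csv`: node, spike_time_ms), metrics (`metrics.json`, when a report
#' is attached), a configuration snapshot (`config.yaml`, when present) and a
#' `manifest.json` listing the files with their MD5 checksums.
#'
#' @param result a `micturition_sim`
#' @param dir output directory, created if missing
#' @return invisibly, the manifest as a data.frame
#' @export
write_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  tr <- data.frame(
    time = rep(result$time, times = ncol(result$v)),
    node = rep(colnames(result$v), each = nrow(result$v)),
    voltage = as.vector(result$v))
  p <- file.path(dir, "traces.csv")
  .write_commented_csv(tr, p, "time in ms, voltage in mV")
  files <- c(files, p)

  ns <- vapply(result$spikes, length, 1L)
  sp <- data.frame(node = rep(names(result$spikes), ns),
                   spike_time_ms = unlist(result$spikes, use.names = FALSE))
  if (!nrow(sp)) sp <- data.frame(node = character(0), spike_time_ms = numeric(0))
  p <- file.path(dir, "spikes.csv")
  .write_commented_csv(sp, p, "spike times in ms")
  files <- c(files, p)

  if (!is.null(result$report)) {
    p <- file.path(dir, "metrics.json")
    rep <- result$report
    jsonlite::write_json(
      list(rates_hz = as.data.frame(rep$rates),
           coactivation = rep$coactivation,
           voiding_events = rep$voiding_events),
      p, auto_unbox = TRUE, digits = NA, dataframe = "columns")
    files <- c(files, p)
  }
  if (!is.null(result$config)) {
    p <- file.path(dir, "config.yaml")
    write_config(result$config, p)
    files <- c(files, p)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         bytes = unname(file.size(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read spike times exported by [write_result()]
#' @param path path to a `spikes.csv`
#' @return named list of spike-time vectors
#' @export
read_spikes <- function(path) {
  df <- .read_commented_csv(path)
  if (!nrow(df)) return(list())
  split(df$spike_time_ms, df$node)
}

#' Generate deterministic test fixtures with known ground truth
#'
#' Produces plain-text fixtures for the analysis layer, each with a sidecar
#' JSON recording the ground truth encoded in the fixture.
#'
#' * `"spike_train"`: a regular train (`params$rate` Hz over
#'   `params$duration` ms); sidecar records the spike count and rate.
#' * `"trace"`: a synthetic voltage trace at rest with `params$n_bumps`
#'   super-threshold spike-like bumps; sidecar records their times.
#' * `"scenario_bundle"`: a miniature healthy-storage export (traces, spikes,
#'   metrics) produced by an actual short simulation.
#'
#' @param kind fixture kind
#' @param params named list (see above); sensible defaults are filled
#' @param seed integer; fixtures are deterministic given the seed
#' @param dir output directory
#' @return named list of file paths
#' @export
generate_fixture <- function(kind = c("spike_train", "trace", "scenario_bundle"),
                             params = list(), seed = 1, dir = tempdir()) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  if (kind == "spike_train") {
    rate <- params$rate %||% 40
    duration <- params$duration %||% 1000
    spikes <- schedule_to_spike_train(afferent_schedule(0, rate), duration)
    p <- file.path(dir, "fixture_spikes.csv")
    .write_commented_csv(data.frame(node = "fix", spike_time_ms = spikes), p,
                         "spike times in ms")
    side <- file.path(dir, "fixture_spikes.json")
    jsonlite::write_json(list(kind = kind, rate_hz = rate,
                              duration_ms = duration, n_spikes = length(spikes)),
                         side, auto_unbox = TRUE, digits = NA)
    return(list(data = p, sidecar = side))
  }
  if (kind == "trace") {
    n_bumps <- params$n_bumps %||% 3
    spacing <- params$spacing %||% 50
    dt <- params$dt %||% 0.1
    duration <- params$duration %||% (n_bumps * spacing + 100)
    t <- seq(0, duration, by = dt)
    v <- rep(-65, length(t))
    centers <- spacing * seq_len(n_bumps)
    for (ct in centers) v <- v + 95 * exp(-((t - ct)^2) / (2 * 0.5^2))
    p <- file.path(dir, "fixture_trace.csv")
    .write_commented_csv(data.frame(time = t, node = "fix", voltage = v), p,
                         "time in ms, voltage in mV")
    side <- file.path(dir, "fixture_trace.json")
    jsonlite::write_json(list(kind = kind, n_bumps = n_bumps,
                              centers_ms = centers), side,
                         auto_unbox = TRUE, digits = NA)
    return(list(data = p, sidecar = side))
  }
  # scenario_bundle
  res <- run_scenario("healthy_storage",
                      overrides = list(
                        duration = params$duration %||% 300,
                        afferent = afferent_schedule(0, params$rate %||% 10)))
  write_result(res, dir)
  side <- file.path(dir, "fixture_bundle.json")
  jsonlite::write_json(list(kind = kind,
                            n_spikes = vapply(res$spikes, length, 1L)),
                       side, auto_unbox = TRUE, digits = NA)
  list(dir = dir, sidecar = side)
}
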