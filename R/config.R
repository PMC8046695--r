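#' Default simulation configuration
#'
#' All model constants in one serialisable list: the RS neuron parameters,
#' the STDP kernel (A+ = 1.03, A- = -0.51, tau+ = 14 ms, tau- = 34 ms,
#' 64 ms window), the synapse constants (tau_SCD = 15 ms, tau_SWD = 35 h,
#' ipsilateral decay 1.5x faster, weight bounds [0, 1], additive scale `eta`,
#' current gain `g_scale`), the noise drive (uniform on [0.6, 1.7] x i_th),
#' and the time-scale preset.
#'
#' The `demo` preset divides the weight-decay constant (and the preset stage
#' durations, see [cimt_protocol()]) by `factor` (default 100) while leaving
#' every millisecond-scale constant untouched, so the full multi-day
#' phenomenology plays out in minutes of simulated time with all rate ratios
#' preserved; `paper` keeps the 35 h decay constant and day-scale stages.
#'
#' @param scale `"demo"` or `"paper"`.
#' @param factor Time-compression factor of the demo preset.
#' @return Nested configuration list of class `run_config`.
#' @export
default_config <- function(scale = c("demo", "paper"), factor = 100) {
  scale <- match.arg(scale)
  eff <- if (scale == "demo") factor else 1
  structure(list(
    neuron = list(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 30),
    kernel = list(a_plus = 1.03, a_minus = -0.51, tau_plus_ms = 14,
                  tau_minus_ms = 34, window_ms = 64),
    synapse = list(tau_scd_ms = 15, tau_swd_ms = 35 * 3600 * 1000 / eff,
                   decay_ratio_ipsi = 1.5, g_min = 0, g_max = 1,
                   eta = 5e-5, g_scale = 50),
    drive = list(i_th = 5.81, lo_frac = 0.6, hi_frac = 1.7),
    scale = list(preset = scale, factor = factor),
    replicates = 1L),
    class = "run_config")
}

config_schema <- function() {
  d <- unclass(default_config())
  lapply(d, function(x) if (is.list(x)) names(x) else NULL)
}

#' Load and validate a YAML configuration
#'
#' Reads a (possibly partial) YAML config, fills every missing field from
#' [default_config()], and validates: unknown keys are rejected, and the
#' synaptic current decay constant must be far smaller than the weight decay
#' constant (the model's separation-of-time-scales requirement).
#'
#' @param path Path to a YAML file; an empty or missing-key file yields the
#'   full default configuration.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- unclass(default_config(
    scale = if (!is.null(user$scale$preset)) user$scale$preset else "demo",
    factor = if (!is.null(user$scale$factor)) user$scale$factor else 100))
  schema <- config_schema()
  bad <- setdiff(names(user), names(schema))
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  for (sec in names(user)) {
    if (is.list(schema[[sec]]) || is.character(schema[[sec]])) {
      badk <- setdiff(names(user[[sec]]), schema[[sec]])
      if (length(badk)) {
        stop("unknown keys in section '", sec, "': ",
             paste(badk, collapse = ", "))
      }
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  validate_config(structure(cfg, class = "run_config"))
}

#' Validate a configuration
#'
#' @param cfg A `run_config` list.
#' @return The config, invisibly, after checks.
#' @export
validate_config <- function(cfg) {
  syn <- cfg$synapse
  if (!(syn$tau_scd_ms < syn$tau_swd_ms / 100)) {
    stop("tau_scd_ms must be orders of magnitude smaller than tau_swd_ms; ",
         "got ", syn$tau_scd_ms, " ms vs ", syn$tau_swd_ms, " ms")
  }
  stopifnot(syn$g_min < syn$g_max, syn$eta >= 0, syn$g_scale >= 0,
            syn$decay_ratio_ipsi >= 1,
            cfg$drive$lo_frac > 0,
            cfg$drive$lo_frac < cfg$drive$hi_frac,
            cfg$drive$i_th > 0,
            cfg$neuron$a > 0, cfg$neuron$d > 0,
            cfg$kernel$a_plus > 0, cfg$kernel$a_minus < 0,
            cfg$kernel$window_ms > 0)
  invisible(cfg)
}

#' Write the output bundle of a run
#'
#' Writes, into `dir`: `trajectory.csv` (time, stage, weights),
#' `spikes.csv` (neuron_id, time_ms event list, when spikes were recorded),
#' `summary.json` (final weights, stage boundaries, per-stage spike counts
#' and dominance labels where applicable), `config.yaml` (full config echo
#' including the seed), and `manifest.json` listing every file with its MD5
#' checksum.  A run is reproducible from the config echo alone.
#'
#' @param run A `subnetwork_run` from [simulate_network()].
#' @param dir Output directory (created if needed).
#' @param extra Optional named list merged into the summary.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(run, dir, extra = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$trajectory, file.path(dir, "trajectory.csv"),
                   row.names = FALSE)
  files <- "trajectory.csv"
  if (!is.null(run$spikes)) {
    ev <- data.frame(
      neuron_id = rep(names(run$spikes),
                      vapply(run$spikes, length, 0L)),
      time_ms = unlist(run$spikes, use.names = FALSE))
    utils::write.csv(ev, file.path(dir, "spikes.csv"), row.names = FALSE)
    files <- c(files, "spikes.csv")
  }
  summary <- c(list(
    topology = run$topology$type,
    seed = run$seed,
    g_final = as.list(run$g_final),
    stages = run$stage_bounds,
    spike_counts = as.data.frame(run$spike_counts)), extra)
  if (run$topology$type == "cst_2x2") {
    summary$dominance_final <- as.list(dominance(unname(run$g_final)))
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, "summary.json")
  cfg <- unclass(run$config)
  cfg$seed <- run$seed
  cfg$record_every_ms <- run$record_every_ms
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  files <- c(files, "config.yaml")
  manifest <- list(
    package = "synapcomp",
    version = as.character(utils::packageVersion("synapcomp")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(dir, f))))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
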