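#' Complete run configuration
#'
#' Bundles neuron, mapping and stimulus settings with run controls into a
#' single validated object. Validation is fail-fast: an inconsistent
#' configuration errors before any simulation starts, naming the offending
#' key.
#'
#' @param neuron A [lif_params()].
#' @param mapping A [mapping_config()].
#' @param stimulus A [stim_bias()] or [stim_spikes()].
#' @param duration Run duration (ms).
#' @param V0 Initial condition (mV); `NULL` means the neuron's resting
#'   potential.
#' @param seed Integer seed recorded for reproducibility.
#' @param out_dir Output directory for `cmd_*` commands.
#' @param log_level `"quiet"` or `"info"`.
#' @return An object of class `"run_config"`.
#' @examples
#' run_config()
#' @export
run_config <- function(neuron = lif_params(),
                       mapping = mapping_config(),
                       stimulus = stim_bias(200),
                       duration = 500, V0 = NULL, seed = 1L,
                       out_dir = tempdir(),
                       log_level = c("info", "quiet")) {
  if (!inherits(neuron, "lif_params"))
    stop("config key 'neuron' must be a lif_params object")
  if (!inherits(mapping, "mapping_config"))
    stop("config key 'mapping' must be a mapping_config object")
  if (!inherits(stimulus, "lif_stimulus"))
    stop("config key 'stimulus' must be a stimulus object")
  if (!is.numeric(duration) || duration < mapping$dt)
    stop("config key 'duration' must be >= the mapping timestep")
  if (!is.null(V0) && (!is.numeric(V0) || !is.finite(V0)))
    stop("config key 'V0' must be a finite voltage or NULL")
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("config key 'seed' must be a single integer")
  log_level <- match.arg(log_level)
  ## fail fast: the mapping must be applicable to this neuron/stimulus
  map_lif_to_loihi(neuron, stimulus, mapping, duration)
  structure(
    list(neuron = neuron, mapping = mapping, stimulus = stimulus,
         duration = duration, V0 = V0, seed = as.integer(seed),
         out_dir = out_dir, log_level = log_level),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  print(x$neuron)
  print(x$mapping)
  print(x$stimulus)
  cat(sprintf("  duration = %g ms, seed = %d, out = %s\n",
              x$duration, x$seed, x$out_dir))
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Recognized sections and keys:
#' `mapping:` `Vs`, `dt`, `precision_bits`, `rounding`;
#' `neuron:` `C_pF`, `tau_ms`, `EL_mV`, `Vr_mV`, `theta_mV`;
#' `stimulus:` `mode` (`bias`/`spikes`), `Ie_pA`, `spikes_csv`
#' (`"table1"` for the frozen fixture), `weight_mV`;
#' `run:` `duration_ms`, `V0_mV`, `seed`, `out_dir`.
#' Missing keys fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  getd <- function(section, key, default) {
    v <- raw[[section]][[key]]
    if (is.null(v)) default else v
  }
  mapping <- mapping_config(
    Vs = getd("mapping", "Vs", calibrated_vs()),
    dt = getd("mapping", "dt", 1),
    precision_bits = getd("mapping", "precision_bits", 12),
    rounding = getd("mapping", "rounding", "truncate"))
  neuron <- lif_params(
    C = getd("neuron", "C_pF", 170),
    tau_v = getd("neuron", "tau_ms", 22.2),
    EL = getd("neuron", "EL_mV", -70),
    Vr = getd("neuron", "Vr_mV", -70),
    theta = getd("neuron", "theta_mV", -50))
  mode <- getd("stimulus", "mode", "bias")
  stimulus <- if (identical(mode, "bias")) {
    stim_bias(getd("stimulus", "Ie_pA", 200))
  } else {
    src <- getd("stimulus", "spikes_csv", "table1")
    trains <- if (identical(src, "table1")) stimulus_table1()
      else read_spike_csv(src)
    stim_spikes(trains, weight = getd("stimulus", "weight_mV", 0.5))
  }
  run_config(neuron = neuron, mapping = mapping, stimulus = stimulus,
             duration = getd("run", "duration_ms", 500),
             V0 = raw[["run"]][["V0_mV"]],
             seed = getd("run", "seed", 1L),
             out_dir = getd("run", "out_dir", tempdir()))
}

log_info <- function(config, fmt, ...) {
  if (identical(config$log_level, "info"))
    message(sprintf(fmt, ...))
}

#' Write a reproducibility manifest
#'
#' Records the effective configuration, seed and package version as JSON;
#' for the deterministic paths this is sufficient to reproduce the outputs
#' bit for bit.
#'
#' @param config A [run_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  stim <- config$stimulus
  stim_desc <- if (stim$mode == "bias")
    list(mode = "bias", Ie_pA = stim$Ie)
  else
    list(mode = "spikes", n_sources = stim$trains$n_sources,
         n_spikes = nrow(stim$trains$spikes),
         weight_mV = stim$weight, kernel = stim$kernel)
  manifest <- list(
    package = "lifmap",
    version = as.character(utils::packageVersion("lifmap")),
    seed = config$seed,
    neuron = config$neuron[c("C", "tau_v", "EL", "Vr", "theta")],
    mapping = unclass(config$mapping),
    stimulus = stim_desc,
    duration_ms = config$duration,
    V0_mV = if (is.null(config$V0)) config$neuron$EL else config$V0
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run both backends and write their traces
#'
#' Simulates the configured neuron on the reference backend and on the
#' integer emulator, writing the reference trace, the raw integer trace,
#' the emulator trace mapped back to mV, a JSON cost report, and a
#' manifest into `config$out_dir`. The effective mapping (Vs, decay, bias
#' encoding) is echoed to the log.
#'
#' @param config A [run_config()].
#' @param delta_v_override Optional integer decay overriding the mapped
#'   value.
#' @return Invisibly, a list with the file paths and the [cost_report()].
#' @export
cmd_simulate <- function(config, delta_v_override = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  mp <- map_lif_to_loihi(config$neuron, config$stimulus, config$mapping,
                         config$duration)
  if (!is.null(delta_v_override)) {
    mp$config <- loihi_config(delta_v = delta_v_override,
                              bias_mantissa = mp$config$bias_mantissa,
                              bias_exponent = mp$config$bias_exponent,
                              theta_int = mp$config$theta_int,
                              weight_int = mp$config$weight_int)
  }
  log_info(config,
           "mapping: Vs = %g mV/unit, delta_v = %d, bias = %d x 2^%d",
           config$mapping$Vs, mp$config$delta_v,
           mp$config$bias_mantissa, mp$config$bias_exponent)
  ref <- simulate_reference(config$neuron, config$stimulus,
                            dt = config$mapping$dt,
                            duration = config$duration, V0 = config$V0)
  emu_int <- simulate_emulator(mp$config, u = mp$u,
                               n_steps = mp$n_steps)
  emu <- as_lif_trace(emu_int, config$neuron$Vr, config$mapping)
  report <- cost_report(ref, emu)

  paths <- list(
    reference = file.path(config$out_dir, "trace_reference.csv"),
    emulator_int = file.path(config$out_dir, "trace_emulator_int.csv"),
    emulator_mv = file.path(config$out_dir, "trace_emulator_mv.csv"),
    report_json = file.path(config$out_dir, "cost_report.json"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  write_trace_csv(ref, paths$reference)
  int_as_trace <- lif_trace(dt = config$mapping$dt,
                            duration = emu_int$steps * config$mapping$dt,
                            values = emu_int$values,
                            spike_times = emu_int$spike_steps *
                              config$mapping$dt)
  write_trace_csv(int_as_trace, paths$emulator_int)
  write_trace_csv(emu, paths$emulator_mv)
  write_cost_report(report, paths$report_json)
  write_manifest(config, paths$manifest)
  log_info(config, "wrote %d file(s) to %s", length(paths),
           config$out_dir)
  invisible(c(paths, list(report = report)))
}

#' Validate the configured neuron across backends
#'
#' Runs both backends and returns the [cost_report()]; also writes it as
#' JSON to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return The [cost_report()].
#' @export
cmd_validate <- function(config) {
  res <- cmd_simulate(config)
  res$report
}

#' Run a sensitivity or precision scan from a configuration
#'
#' @param config A [run_config()].
#' @param mode `"oat"`, `"tat"` or `"precision"`.
#' @param param For OAT: one of `"C"`, `"tau_v"`, `"EL"`. For TAT: two of
#'   them.
#' @param preset Grid preset family: `"spike"` or `"bias"`; defaults to
#'   the configured stimulus mode.
#' @param direction `"reference"` or `"emulator"`.
#' @param what For `mode = "precision"`: `"bias"` (mantissa/exponent
#'   table) or `"decay"` (decay sweep, +/- `half_width` around the mapped
#'   value).
#' @param half_width Half width of the decay sweep (default 30).
#' @param grid,grid_b Optional explicit [param_grid()]s overriding the
#'   presets.
#' @return Invisibly, a list with the scan object and the files written
#'   (long-format CSV plus JSON summary).
#' @export
cmd_scan <- function(config, mode = c("oat", "tat", "precision"),
                     param = "EL", preset = NULL,
                     direction = c("reference", "emulator"),
                     what = c("bias", "decay"), half_width = 30,
                     grid = NULL, grid_b = NULL) {
  stopifnot(inherits(config, "run_config"))
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(preset))
    preset <- if (config$stimulus$mode == "bias") "bias" else "spike"

  if (mode == "precision") {
    what <- match.arg(what)
    if (what == "bias") {
      mp <- map_lif_to_loihi(config$neuron, config$stimulus,
                             config$mapping, config$duration)
      tab <- bias_precision_table(mp$bias$reconstructed)
      path <- file.path(config$out_dir, "bias_precision.csv")
      write.csv(tab, path, row.names = FALSE, quote = FALSE)
      log_info(config, "wrote %s", path)
      return(invisible(list(table = tab, csv = path)))
    }
    mp <- map_lif_to_loihi(config$neuron, config$stimulus,
                           config$mapping, config$duration)
    ref <- simulate_reference(config$neuron, config$stimulus,
                              dt = config$mapping$dt,
                              duration = config$duration,
                              V0 = config$V0)
    sweep <- decay_sweep(mp$config, mp$config$delta_v, half_width, ref,
                         config$mapping, u = mp$u,
                         Vr = config$neuron$Vr)
    csv <- file.path(config$out_dir, "decay_sweep.csv")
    js <- file.path(config$out_dir, "decay_sweep.json")
    write_scan_csv(sweep, csv)
    write_scan_summary(sweep, js)
    log_info(config, "wrote %s and %s", csv, js)
    return(invisible(list(scan = sweep, csv = csv, json = js)))
  }

  if (mode == "oat") {
    if (length(param) != 1L) stop("OAT scans take a single 'param'")
    g <- if (is.null(grid)) preset_grid(param, preset) else grid
    scan <- oat_scan(config$neuron, config$stimulus, config$mapping, g,
                     direction = direction, duration = config$duration)
  } else {
    if (length(param) != 2L) stop("TAT scans take two parameters")
    ga <- if (is.null(grid)) preset_grid(param[1], preset) else grid
    gb <- if (is.null(grid_b)) preset_grid(param[2], preset) else grid_b
    scan <- tat_scan(config$neuron, config$stimulus, config$mapping,
                     ga, gb, direction = direction,
                     duration = config$duration)
  }
  stem <- paste(c(mode, param, direction), collapse = "_")
  csv <- file.path(config$out_dir, paste0(stem, ".csv"))
  js <- file.path(config$out_dir, paste0(stem, ".json"))
  write_scan_csv(scan, csv)
  write_scan_summary(scan, js)
  log_info(config, "wrote %s and %s", csv, js)
  invisible(list(scan = scan, csv = csv, json = js))
}
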