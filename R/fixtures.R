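# Deterministic run bundles (waveform CSV + config JSON) used by the tests,
# the CLI examples, and as synthetic stand-ins for the study's unpublished
# raw traces.

FIXTURE_NAMES <- c("tga_default", "control_default", "steady_flow", "zero_flow")

#' Generate a named deterministic run fixture
#'
#' Writes a waveform CSV and a network-config JSON for one of the bundled
#' scenarios and returns the in-memory objects. `tga_default` is the bench
#' preset driven at 5.48 L/min, `control_default` the same network at
#' 5.25 L/min, `steady_flow` a constant inflow at the TGA mean, and
#' `zero_flow` an all-zero inflow. Regenerating with the same name and seed
#' reproduces byte-identical files.
#'
#' @param name One of `"tga_default"`, `"control_default"`,
#'   `"steady_flow"`, `"zero_flow"`.
#' @param seed Non-negative integer recorded with the fixture and used for
#'   any stochastic component (the bundled scenarios are noise-free, so it
#'   only guarantees reproducibility of downstream noisy resampling).
#' @param dir Directory to write into.
#' @param dt Solver grid spacing for the waveform, s.
#' @return A list with `name`, `seed`, `config`, `pump` (NULL for the
#'   constant scenarios), `waveform`, and `paths` (`waveform`, `config`).
#' @export
make_fixture <- function(name, seed = 1L, dir = tempdir(), dt = 1e-4) {
  name <- match.arg(name, FIXTURE_NAMES)
  if (!is.numeric(seed) || length(seed) != 1 || seed < 0 || seed != round(seed)) {
    abort("`seed` must be a non-negative integer", class = "mockloop_invalid_params")
  }
  config <- default_network()
  period <- 0.8
  n <- as.integer(round(period / dt))
  pump <- NULL
  if (name %in% c("tga_default", "control_default")) {
    co <- if (name == "tga_default") 5.48 else 5.25
    pump <- pump_settings(cardiac_output = convert_flow(co, "L/min", "m3/s"))
    waveform <- generate_pump_waveform(pump, n_samples = n)
  } else if (name == "steady_flow") {
    q <- convert_flow(5.48, "L/min", "m3/s")
    waveform <- flow_waveform((0:(n - 1)) * dt, rep(q, n), period = period)
  } else {
    waveform <- flow_waveform((0:(n - 1)) * dt, rep(0, n), period = period)
  }
  paths <- list(
    waveform = file.path(dir, paste0(name, "_waveform.csv")),
    config = file.path(dir, paste0(name, "_config.json"))
  )
  write_waveform_csv(waveform, paths$waveform)
  write_lpn_config(config, paths$config)
  list(
    name = name, seed = as.integer(seed), config = config, pump = pump,
    waveform = waveform, paths = paths
  )
}

#' Write a report object to JSON
#'
#' Serialises a `comparison_report`, a simulation summary, or any plain
#' list of tibbles/vectors to pretty-printed JSON at full precision.
#'
#' @param report The object to serialise.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    unclass_deep(report), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows",
    na = "null"
  )
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) {
    return(as.data.frame(lapply(x, unlist)))
  }
  if (is.list(x)) {
    return(lapply(unclass(x), unclass_deep))
  }
  x
}

#' Load a full run configuration
#'
#' A run config JSON ties a network, pump settings, and solver settings
#' together: keys `network` (inline network document or a path to one),
#' `pump` (`cardiac_output_lmin`, `period_s`, `systolic_fraction`,
#' `backflow_fraction`), `solver` (`dt_s`, `max_cycles`,
#' `periodicity_tol_pa`, `initial_pressure_mmhg`), and `seed`. All keys are
#' optional except `network`; omitted settings take package defaults.
#'
#' @param path Path to the run-config JSON.
#' @return A list with `config` ([lpn_config()]), `pump`
#'   ([pump_settings()]), `solver` ([solver_settings()]), `seed`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Run config not found: %s", path), class = "mockloop_io_error")
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$network)) {
    abort("Run config is missing key(s): network",
      class = "mockloop_config_error"
    )
  }
  config <- if (is.character(doc$network)) {
    netpath <- doc$network
    if (!file.exists(netpath)) {
      netpath <- file.path(dirname(path), doc$network)
    }
    read_lpn_config(netpath)
  } else {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(doc$network, tmp, auto_unbox = TRUE, digits = NA)
    read_lpn_config(tmp)
  }
  p <- doc$pump
  pump <- pump_settings(
    cardiac_output = convert_flow(p$cardiac_output_lmin %||% 5.48, "L/min", "m3/s"),
    period = p$period_s %||% 0.8,
    systolic_fraction = p$systolic_fraction %||% 0.5,
    backflow_fraction = p$backflow_fraction %||% 0
  )
  s <- doc$solver
  solver <- solver_settings(
    dt = s$dt_s %||% 1e-4,
    max_cycles = s$max_cycles %||% 50,
    periodicity_tol = s$periodicity_tol_pa %||% (0.1 * PA_PER_MMHG),
    initial_pressure = convert_pressure(
      s$initial_pressure_mmhg %||% 80, "mmHg", "Pa"
    )
  )
  seed <- doc$seed %||% 0L
  if (!is.numeric(seed) || seed < 0 || seed != round(seed)) {
    abort("Run config `seed` must be a non-negative integer",
      class = "mockloop_config_error"
    )
  }
  list(config = config, pump = pump, solver = solver, seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
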