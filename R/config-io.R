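# JSON serialisation of the network configuration: SI element constants,
# atrial pressure in mmHg (a bench gauge reading), inlet diameter in m.

#' Write a network configuration to JSON
#'
#' @param config An [lpn_config()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_lpn_config()]
#' @export
write_lpn_config <- function(config, path) {
  stopifnot(inherits(config, "lpn_config"))
  doc <- list(
    branches = purrr::pmap(
      config$branches,
      function(label, a, b, r2, c) list(label = label, a = a, b = b, r2 = r2, c = c)
    ),
    terminal = list(r_t = config$terminal$r_t, c_t = config$terminal$c_t),
    p_atrium_mmHg = convert_pressure(config$p_atrium, "Pa", "mmHg"),
    fluid = list(rho = config$fluid$density, mu = config$fluid$viscosity),
    r_internal = as.list(config$r_internal),
    inlet_diameter_m = config$inlet_diameter
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a network configuration from JSON
#'
#' Validates the document structure and all physical invariants; a missing
#' top-level key is reported by name.
#'
#' @param path Path to a JSON file written by [write_lpn_config()] (or
#'   hand-edited in the same schema).
#' @return An [lpn_config()] object.
#' @export
read_lpn_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "mockloop_io_error")
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  required <- c(
    "branches", "terminal", "p_atrium_mmHg", "fluid",
    "r_internal", "inlet_diameter_m"
  )
  missing <- setdiff(required, names(doc))
  if (length(missing) > 0) {
    abort(
      sprintf("Config is missing key(s): %s", paste(missing, collapse = ", ")),
      class = "mockloop_config_error"
    )
  }
  branches <- purrr::map_dfr(doc$branches, function(b) {
    need <- setdiff(c("label", "a", "b", "r2", "c"), names(b))
    if (length(need) > 0) {
      abort(
        sprintf("Branch entry is missing key(s): %s", paste(need, collapse = ", ")),
        class = "mockloop_config_error"
      )
    }
    branch_params(b$label, b$a, b$b, b$r2, b$c)
  })
  lpn_config(
    branches = branches,
    terminal = terminal_params(doc$terminal$r_t, doc$terminal$c_t),
    p_atrium = convert_pressure(doc$p_atrium_mmHg, "mmHg", "Pa"),
    fluid = fluid_properties(doc$fluid$rho, doc$fluid$mu),
    r_internal = unlist(doc$r_internal),
    inlet_diameter = doc$inlet_diameter_m
  )
}
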