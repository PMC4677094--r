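# Unit conversion lives at the I/O boundary only; everything internal is SI
# (Pa, m^3/s, s).

PA_PER_MMHG <- 133.322
M3S_PER_LMIN <- 1 / 60000

#' Convert pressures between pascal and millimetres of mercury
#'
#' Internally the package works strictly in SI units; `convert_pressure()`
#' and [convert_flow()] are the only places where clinical units appear.
#' The conversion factor is 1 mmHg = 133.322 Pa.
#'
#' @param value Numeric vector of pressures.
#' @param from,to Unit names, one of `"Pa"` or `"mmHg"`.
#' @return Numeric vector in the target unit.
#' @examples
#' convert_pressure(8, "mmHg", "Pa") # atrial reservoir head, 1066.58 Pa
#' @export
convert_pressure <- function(value, from, to) {
  factors <- c(Pa = 1, mmHg = PA_PER_MMHG)
  check_unit(from, names(factors))
  check_unit(to, names(factors))
  value * factors[[from]] / factors[[to]]
}

#' Convert volumetric flows between SI and litres per minute
#'
#' @param value Numeric vector of flows.
#' @param from,to Unit names, one of `"m3/s"` or `"L/min"`.
#' @return Numeric vector in the target unit.
#' @examples
#' convert_flow(5.48, "L/min", "m3/s")
#' @export
convert_flow <- function(value, from, to) {
  factors <- c("m3/s" = 1, "L/min" = M3S_PER_LMIN)
  check_unit(from, names(factors))
  check_unit(to, names(factors))
  value * factors[[from]] / factors[[to]]
}

check_unit <- function(unit, known) {
  if (!(is.character(unit) && length(unit) == 1 && unit %in% known)) {
    abort(
      sprintf(
        "Unknown unit %s; expected one of: %s",
        deparse(unit), paste(known, collapse = ", ")
      ),
      class = "mockloop_unit_error"
    )
  }
  invisible(unit)
}
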