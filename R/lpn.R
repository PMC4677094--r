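# Lumped-parameter network: element laws and the bench-calibrated preset.
#
# Each downstream branch j is a non-linear tap resistance (dP = a*Q^2 + b*Q,
# from needle-valve calibration), a linear tube resistance r2, and a
# Windkessel compliance c. A common terminal section (r_t, c_t) returns all
# outlets to a constant-pressure atrial reservoir.

BRANCH_LABELS <- c("innominate", "carotid", "subclavian", "descending_aorta")

#' Fluid properties of the working fluid
#'
#' The bench loop and the simulations use water: incompressible, Newtonian,
#' density 1000 kg/m^3, dynamic viscosity 1 cP (1e-3 Pa s).
#'
#' @param density Mass density in kg/m^3; must be positive.
#' @param viscosity Dynamic viscosity in Pa s; must be positive.
#' @return A named list with class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1000, viscosity = 1e-3) {
  stopifnot(is.numeric(density), length(density) == 1, is.finite(density))
  stopifnot(is.numeric(viscosity), length(viscosity) == 1, is.finite(viscosity))
  if (density <= 0 || viscosity <= 0) {
    abort("Fluid density and viscosity must be strictly positive",
      class = "mockloop_invalid_params"
    )
  }
  structure(list(density = density, viscosity = viscosity),
    class = "fluid_properties"
  )
}

#' Parameters of one downstream branch
#'
#' Builds a one-row tibble holding the element constants of a branch:
#' the quadratic (`a`, Pa s^2/m^6) and linear (`b`, Pa s/m^3, may be
#' negative) coefficients of the tap law dP = a Q^2 + b Q, the linear tube
#' resistance `r2` (Pa s/m^3), and the compliance `c` (m^3/Pa). The series
#' pressure-flow law a Q^2 + (b + r2) Q must be strictly increasing for
#' forward flow, which requires `b + r2 > 0`.
#'
#' @param label One of `"innominate"`, `"carotid"`, `"subclavian"`,
#'   `"descending_aorta"`.
#' @param a,b,c,r2 Element constants in SI units (see above).
#' @return A one-row tibble with columns `label`, `a`, `b`, `r2`, `c`.
#' @export
branch_params <- function(label, a, b, r2, c) {
  label <- match.arg(label, BRANCH_LABELS)
  a <- as.numeric(a)
  b <- as.numeric(b)
  r2 <- as.numeric(r2)
  c <- as.numeric(c)
  vals <- c(a = a, b = b, r2 = r2, c = c)
  if (!all(is.finite(vals))) {
    abort("Branch parameters must be finite numbers",
      class = "mockloop_invalid_params"
    )
  }
  if (a <= 0 || r2 <= 0 || c <= 0) {
    abort(sprintf("Branch '%s': a, r2 and c must be strictly positive", label),
      class = "mockloop_invalid_params"
    )
  }
  if (b + r2 <= 0) {
    abort(
      sprintf(
        "Branch '%s': b + r2 must be positive so the series dP-Q law is monotone",
        label
      ),
      class = "mockloop_invalid_params"
    )
  }
  tibble(label = label, a = a, b = b, r2 = r2, c = c)
}

#' Terminal (common-section) parameters
#'
#' The terminal section lumps the final tubing that returns all outlets to
#' the atrial reservoir: a linear resistance `r_t` and a small compliance
#' `c_t`.
#'
#' @param r_t Terminal resistance in Pa s/m^3; positive.
#' @param c_t Terminal compliance in m^3/Pa; positive.
#' @return A named list with class `terminal_params`.
#' @export
terminal_params <- function(r_t, c_t) {
  r_t <- as.numeric(r_t)
  c_t <- as.numeric(c_t)
  if (!all(is.finite(c(r_t, c_t))) || r_t <= 0 || c_t <= 0) {
    abort("Terminal r_t and c_t must be strictly positive",
      class = "mockloop_invalid_params"
    )
  }
  structure(list(r_t = r_t, c_t = c_t), class = "terminal_params")
}

#' Assemble a full lumped-parameter network configuration
#'
#' @param branches A four-row tibble of branch parameters (rbind of
#'   [branch_params()] rows), one per unique label.
#' @param terminal A [terminal_params()] object.
#' @param p_atrium Constant atrial reservoir pressure in Pa; non-negative.
#' @param fluid A [fluid_properties()] object.
#' @param r_internal Junction internal resistance per branch, Pa s/m^3
#'   (scalar recycled or length 4, named or in branch order); all positive.
#'   Represents the small viscous loss of the aortic flow domain between the
#'   inlet and each outlet.
#' @param inlet_diameter Inlet tube diameter in m; positive.
#' @return A list with class `lpn_config`.
#' @export
lpn_config <- function(branches, terminal, p_atrium, fluid,
                       r_internal = 1e6, inlet_diameter = 0.012) {
  branches <- as_tibble(branches)
  if (nrow(branches) != 4 || !setequal(branches$label, BRANCH_LABELS) ||
    anyDuplicated(branches$label)) {
    abort("`branches` must contain exactly the four uniquely labelled branches",
      class = "mockloop_invalid_params"
    )
  }
  # canonical branch order throughout the package
  branches <- branches[match(BRANCH_LABELS, branches$label), ]
  for (i in seq_len(4)) {
    branch_params(
      branches$label[i], branches$a[i], branches$b[i],
      branches$r2[i], branches$c[i]
    )
  }
  if (!inherits(terminal, "terminal_params")) {
    terminal <- terminal_params(terminal$r_t, terminal$c_t)
  }
  if (!inherits(fluid, "fluid_properties")) {
    fluid <- fluid_properties(fluid$density, fluid$viscosity)
  }
  p_atrium <- as.numeric(p_atrium)
  if (length(p_atrium) != 1 || !is.finite(p_atrium) || p_atrium < 0) {
    abort("`p_atrium` must be a non-negative pressure in Pa",
      class = "mockloop_invalid_params"
    )
  }
  if (length(r_internal) == 1) r_internal <- rep(r_internal, 4)
  if (!is.null(names(r_internal))) {
    r_internal <- r_internal[BRANCH_LABELS]
  }
  r_internal <- unname(as.numeric(r_internal))
  if (length(r_internal) != 4 || !all(is.finite(r_internal)) ||
    any(r_internal <= 0)) {
    abort("`r_internal` must be four strictly positive resistances",
      class = "mockloop_invalid_params"
    )
  }
  names(r_internal) <- BRANCH_LABELS
  inlet_diameter <- as.numeric(inlet_diameter)
  if (!is.finite(inlet_diameter) || inlet_diameter <= 0) {
    abort("`inlet_diameter` must be positive", class = "mockloop_invalid_params")
  }
  structure(
    list(
      branches = branches, terminal = terminal, p_atrium = p_atrium,
      fluid = fluid, r_internal = r_internal,
      inlet_diameter = inlet_diameter
    ),
    class = "lpn_config"
  )
}

#' The bench-calibrated network preset
#'
#' Returns the lumped-parameter network tuned to replicate the physical
#' mock circulatory loop: tap laws, tube resistances and compliances for the
#' innominate, carotid, subclavian and descending-aorta branches, the
#' common terminal section, an 8 mmHg atrial reservoir, water as the
#' working fluid, and a 12.0 mm cylindrical inlet.
#'
#' @param r_internal Junction internal resistance(s), Pa s/m^3; see
#'   [lpn_config()]. Default 1e6 per branch (about 0.4 mmHg drop at
#'   descending-aorta flow).
#' @return An `lpn_config` object.
#' @examples
#' net <- default_network()
#' net$branches
#' convert_pressure(net$p_atrium, "Pa", "mmHg")
#' @export
default_network <- function(r_internal = 1e6) {
  branches <- dplyr::bind_rows(
    branch_params("innominate", a = 1e13, b = -8e6, r2 = 5e7, c = 1.88e-9),
    branch_params("carotid", a = 2e13, b = -5e6, r2 = 1e8, c = 1.98e-9),
    branch_params("subclavian", a = 1e13, b = -8e6, r2 = 1e7, c = 3.06e-9),
    branch_params("descending_aorta", a = 8e11, b = -1e7, r2 = 2.5e7, c = 1.48e-9)
  )
  lpn_config(
    branches = branches,
    terminal = terminal_params(r_t = 8e7, c_t = 0.36e-11),
    p_atrium = convert_pressure(8, "mmHg", "Pa"),
    fluid = fluid_properties(),
    r_internal = r_internal,
    inlet_diameter = 0.012
  )
}

#' @export
print.lpn_config <- function(x, ...) {
  cat("<lpn_config>\n")
  cat(sprintf(
    "  atrial pressure: %.2f Pa (%.2f mmHg)\n",
    x$p_atrium, convert_pressure(x$p_atrium, "Pa", "mmHg")
  ))
  cat(sprintf(
    "  terminal: r_t = %.3g Pa s/m^3, c_t = %.3g m^3/Pa\n",
    x$terminal$r_t, x$terminal$c_t
  ))
  cat(sprintf(
    "  fluid: rho = %g kg/m^3, mu = %g Pa s; inlet diameter %g m\n",
    x$fluid$density, x$fluid$viscosity, x$inlet_diameter
  ))
  cat("  branches:\n")
  print(x$branches)
  invisible(x)
}

#' Pressure drop across a non-linear tap resistance
#'
#' Evaluates the calibrated tap law dP = a Q^2 + b Q for forward flow.
#' The quadratic fit comes from forward-flow calibration, so the law is
#' extended antisymmetrically to negative flow (`f(-q) = -f(q)`), keeping it
#' odd and monotone in series with the tube resistance.
#'
#' @param branch A one-row branch tibble (a row of `config$branches`), or
#'   any list with numeric `a` and `b`.
#' @param q Volumetric flow in m^3/s (vectorised).
#' @return Pressure drop in Pa.
#' @export
nonlinear_drop <- function(branch, q) {
  sign(q) * (branch$a[[1]] * q^2 + branch$b[[1]] * abs(q))
}

#' Invert the series branch pressure-flow law
#'
#' The branch seen from its compliance node to the common node is the tap in
#' series with the tube: dP = a Q^2 + (b + r2) Q. For `dp >= 0` this has a
#' unique non-negative root
#' `Q = (-(b + r2) + sqrt((b + r2)^2 + 4 a dp)) / (2 a)`; negative drops use
#' the antisymmetric extension. Round-tripping through the forward law is
#' the identity.
#'
#' @param branch A one-row branch tibble with `a`, `b`, `r2`.
#' @param dp Pressure drop in Pa (vectorised).
#' @return Volumetric flow in m^3/s, with the sign of `dp`.
#' @export
series_branch_flow <- function(branch, dp) {
  a <- branch$a[[1]]
  beta <- branch$b[[1]] + branch$r2[[1]]
  if (!is.finite(beta) || beta <= 0) {
    abort("series_branch_flow() requires b + r2 > 0 (monotone series law)",
      class = "mockloop_invalid_params"
    )
  }
  sign(dp) * (-beta + sqrt(beta^2 + 4 * a * abs(dp))) / (2 * a)
}

# Forward series law (tap + tube), vectorised over the four branches.
# Used by the integrator; q may be a length-4 vector.
series_drop <- function(branches, q) {
  sign(q) * (branches$a * q^2 + (branches$b + branches$r2) * abs(q))
}

# Inverse series law vectorised over the four branches (dp length 4).
series_flow_all <- function(branches, dp) {
  beta <- branches$b + branches$r2
  sign(dp) * (-beta + sqrt(beta^2 + 4 * branches$a * abs(dp))) / (2 * branches$a)
}
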