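# Derived mechanical quantities on the 0D solution: a Poiseuille wall
# shear stress estimate and the power dissipation index of the junction
# flow domain.

#' Poiseuille estimate of wall shear stress
#'
#' For fully developed laminar flow in a straight tube the wall shear
#' stress is `tau_w = 4 mu q / (pi r^3)`. This is a bulk estimate at a
#' circular cross-section; it cannot capture local three-dimensional
#' hot-spots.
#'
#' @param q Volumetric flow in m^3/s (vectorised); the sign of `q` carries
#'   through.
#' @param radius Tube radius in m; positive.
#' @param viscosity Dynamic viscosity in Pa s.
#' @return Wall shear stress in Pa.
#' @examples
#' wss_poiseuille(convert_flow(5.48, "L/min", "m3/s"), 0.006, 1e-3)
#' @export
wss_poiseuille <- function(q, radius, viscosity) {
  if (!all(is.finite(radius)) || any(radius <= 0)) {
    abort("`radius` must be positive", class = "mockloop_invalid_params")
  }
  4 * viscosity * q / (pi * radius^3)
}

#' Cycle-averaged power dissipation of the junction flow domain
#'
#' Energy-flux bookkeeping over the 0D stand-in for the aortic flow domain
#' (inlet node to the four branch nodes): the cycle mean of
#' `(p_a + 1/2 rho v_in^2) q_in - sum_j (p_j + 1/2 rho v_j^2) q_j`,
#' with velocities `v = q / area`. The junction domain stores no volume, so
#' for the passive network this is non-negative and equals the viscous loss
#' in the internal resistances plus the net kinetic-energy flux.
#'
#' With `include_kinetic = FALSE` the kinetic terms are dropped and the
#' index reduces to the static-pressure work absorbed by the internal
#' resistances, `sum_j mean(r_internal_j q_j^2)`, exactly. Under a strongly
#' pulsatile inflow the kinetic fluxes do not cancel (the junction
#' distributes the flow pulse by internal conductance, not by mean-flow
#' fraction), so the full index can undershoot the viscous loss and even
#' turn negative; at steady flow, with outlet areas proportional to the
#' flow fractions, the kinetic terms cancel and the index equals the
#' element dissipation sum.
#'
#' @param result A converged `mockloop_sim` from [run_to_periodic()].
#' @param outlet_areas Four outlet cross-sectional areas in m^2. Default:
#'   the inlet area scaled by the reference computed flow fractions of the
#'   TGA run, which makes the cycle-mean outlet velocities comparable to
#'   the mean inlet velocity.
#' @param include_kinetic Include the `1/2 rho v^2 q` kinetic flux terms
#'   (default `TRUE`).
#' @return Cycle-averaged dissipated power in W.
#' @export
power_dissipation <- function(result, outlet_areas = NULL,
                              include_kinetic = TRUE) {
  stopifnot(inherits(result, "mockloop_sim"))
  if (!result$converged) {
    abort("power_dissipation() requires a converged periodic result",
      class = "mockloop_not_converged"
    )
  }
  config <- result$config
  area_in <- pi * (config$inlet_diameter / 2)^2
  if (is.null(outlet_areas)) {
    frac <- reference_flow_table()
    frac <- frac$split_pct[frac$anatomy == "tga" & frac$modality == "cfd"] / 100
    outlet_areas <- area_in * frac
  }
  if (length(outlet_areas) != 4 || any(outlet_areas <= 0)) {
    abort("`outlet_areas` must be four positive areas",
      class = "mockloop_invalid_params"
    )
  }
  s <- result$series
  rho <- if (include_kinetic) config$fluid$density else 0
  v_in <- s$q_in_m3s / area_in
  influx <- (s$p_aorta_pa + 0.5 * rho * v_in^2) * s$q_in_m3s
  q_cols <- c("q_i_m3s", "q_c_m3s", "q_s_m3s", "q_d_m3s")
  p_cols <- c("p_i_pa", "p_c_pa", "p_s_pa", "p_d_pa")
  outflux <- rowSums(
    vapply(seq_len(4), function(j) {
      v <- s[[q_cols[j]]] / outlet_areas[j]
      (s[[p_cols[j]]] + 0.5 * rho * v^2) * s[[q_cols[j]]]
    }, numeric(nrow(s)))
  )
  mean(influx - outflux)
}
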