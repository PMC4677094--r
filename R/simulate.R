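# Coupled 0D simulation: a junction node standing in for the aortic flow
# domain distributes the inlet flow over the four branches through small
# internal resistances; each branch charges its Windkessel compliance and
# drains through tap + tube into the common terminal node, which empties
# into the constant-pressure atrial reservoir. The five node-pressure ODEs
# are integrated with fixed-step explicit Euler until consecutive cycles
# agree within a pressure tolerance.

#' Solver settings for the periodic integration
#'
#' @param dt Time step in s (default 1e-4, the step the network was tuned
#'   at).
#' @param max_cycles Maximum number of cardiac cycles to integrate.
#' @param periodicity_tol Maximum node-pressure change between consecutive
#'   cycles, in Pa, for the run to count as periodic (default 13.3 Pa, i.e.
#'   0.1 mmHg).
#' @param initial_pressure Initial pressure of every node in Pa (default
#'   80 mmHg, near the operating point, which keeps the transient short;
#'   the converged cycle does not depend on it).
#' @return A named list with class `solver_settings`.
#' @export
solver_settings <- function(dt = 1e-4, max_cycles = 50,
                            periodicity_tol = 0.1 * PA_PER_MMHG,
                            initial_pressure = 80 * PA_PER_MMHG) {
  ok <- is.finite(dt) && dt > 0 &&
    is.finite(max_cycles) && max_cycles >= 2 &&
    is.finite(periodicity_tol) && periodicity_tol > 0 &&
    is.finite(initial_pressure)
  if (!ok) {
    abort("Invalid solver settings: need dt > 0, max_cycles >= 2, periodicity_tol > 0",
      class = "mockloop_invalid_params"
    )
  }
  structure(
    list(
      dt = dt, max_cycles = as.integer(max_cycles),
      periodicity_tol = periodicity_tol, initial_pressure = initial_pressure
    ),
    class = "solver_settings"
  )
}

#' Instantaneous network state
#'
#' @param p_branch Pressures at the four branch compliance nodes in Pa,
#'   in canonical branch order (innominate, carotid, subclavian,
#'   descending aorta); names are attached if absent.
#' @param p_common Pressure at the terminal node in Pa.
#' @param t Time in s.
#' @return A named list with class `network_state`.
#' @export
network_state <- function(p_branch, p_common, t = 0) {
  p_branch <- as.numeric(p_branch)
  if (length(p_branch) != 4 || !all(is.finite(p_branch)) ||
    !is.finite(p_common)) {
    abort("`p_branch` must be four finite pressures; `p_common` finite",
      class = "mockloop_invalid_params"
    )
  }
  names(p_branch) <- BRANCH_LABELS
  structure(list(p_branch = p_branch, p_common = p_common, t = t),
    class = "network_state"
  )
}

#' Solve the junction node for the instantaneous flow distribution
#'
#' The junction replaces the three-dimensional aortic domain with a single
#' pressure node: each branch draws `q_j = (p_a - p_j) / r_internal_j` and
#' the flows must sum to the inlet flow. With linear internal resistances
#' the solution is closed-form,
#' `p_a = (q_in + sum(p_j / r_j)) / sum(1 / r_j)`.
#'
#' @param config An [lpn_config()].
#' @param state A [network_state()] (only `p_branch` is used).
#' @param q_in Inlet flow in m^3/s.
#' @return A list with `p_aorta` (Pa) and `q_branch` (named, m^3/s);
#'   `sum(q_branch) == q_in` to machine precision.
#' @export
junction_solve <- function(config, state, q_in) {
  g <- 1 / config$r_internal
  if (!all(is.finite(g)) || any(g <= 0)) {
    abort("Singular junction: all internal resistances must be positive",
      class = "mockloop_singular_junction"
    )
  }
  p_a <- (q_in + sum(g * state$p_branch)) / sum(g)
  q <- g * (p_a - state$p_branch)
  list(p_aorta = p_a, q_branch = q)
}

#' One explicit Euler step of the network ODEs
#'
#' Advances the five node pressures by one forward-Euler step:
#' `c_j dp_j/dt = q_j - q_out_j` at each branch node (junction inflow minus
#' series tap+tube outflow) and
#' `c_t dp_c/dt = sum(q_out_j) - (p_c - p_atrium)/r_t` at the terminal node.
#'
#' @param config An [lpn_config()].
#' @param state A [network_state()].
#' @param q_in Inlet flow in m^3/s over the step.
#' @param dt Step size in s.
#' @return The updated [network_state()] at `t + dt`.
#' @export
step_euler <- function(config, state, q_in, dt) {
  jn <- junction_solve(config, state, q_in)
  dp <- state$p_branch - state$p_common
  q_out <- series_flow_all(config$branches, dp)
  p_branch <- state$p_branch + dt / config$branches$c * (jn$q_branch - q_out)
  p_common <- state$p_common + dt / config$terminal$c_t *
    (sum(q_out) - (state$p_common - config$p_atrium) / config$terminal$r_t)
  if (any(abs(c(p_branch, p_common)) > 1e6)) {
    abort("Numerical instability: node pressure exceeded 1e6 Pa",
      class = "mockloop_instability"
    )
  }
  network_state(p_branch, p_common, state$t + dt)
}

# Operating-point branch flows for a given mean inflow: solves
# sum_j q_j(delta) = q_mean for the common total drop (series law plus the
# junction internal resistance). Used only for the stability guard.
operating_flows <- function(config, q_mean) {
  if (!is.finite(q_mean) || q_mean <= 0) {
    return(rep(0, 4))
  }
  br <- config$branches
  beta <- br$b + br$r2 + config$r_internal
  qfun <- function(delta) {
    (-beta + sqrt(beta^2 + 4 * br$a * delta)) / (2 * br$a)
  }
  f <- function(delta) sum(qfun(delta)) - q_mean
  upper <- 10
  while (f(upper) < 0) upper <- upper * 10
  delta <- stats::uniroot(f, c(0, upper), tol = 1e-10)$root
  qfun(delta)
}

# Explicit-Euler stability bound: 2x the fastest local node time constant,
# with series-law conductances linearised at the operating flows.
stability_bound <- function(config, q_mean) {
  q_op <- operating_flows(config, q_mean)
  br <- config$branches
  g_series <- 1 / (2 * br$a * q_op + br$b + br$r2)
  tau_branch <- br$c / (1 / config$r_internal + g_series)
  tau_common <- config$terminal$c_t /
    (sum(g_series) + 1 / config$terminal$r_t)
  2 * min(tau_branch, tau_common)
}

#' Integrate the coupled network to a periodic regime
#'
#' Runs fixed-step explicit Euler cycle after cycle until the maximum
#' node-pressure change between consecutive cycles drops below
#' `settings$periodicity_tol`, or `max_cycles` is reached. The terminal
#' compliance is small, so the terminal node is the stiffest: a stability
#' guard compares `dt` against 0.8 of the explicit stability bound
#' (twice the fastest node time constant, linearised at the cycle-mean
#' operating point) and transparently sub-steps when `dt` is too large.
#'
#' @param config An [lpn_config()].
#' @param waveform A [flow_waveform()]; if its grid spacing differs from
#'   `settings$dt` it is first passed through
#'   [interpolate_to_solver_grid()].
#' @param settings A [solver_settings()].
#' @return A `mockloop_sim` object: `series` (tibble over the final cycle
#'   with node pressures, junction branch flows `q_*` and branch outflows
#'   `qout_*`), `cycles_run`, `converged`, `delta_p` (final cycle-to-cycle
#'   change, Pa), `cycle_metrics`, `n_substeps`, and the inputs. Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @examples
#' \donttest{
#' sim <- simulate_loop()
#' glance(sim)
#' tidy(sim)
#' }
#' @export
run_to_periodic <- function(config, waveform, settings = solver_settings()) {
  stopifnot(inherits(config, "lpn_config"), inherits(waveform, "flow_waveform"))
  dt <- settings$dt
  if (abs(wf_spacing(waveform) - dt) > 1e-12) {
    waveform <- interpolate_to_solver_grid(waveform, dt)
  }
  q_in <- waveform$flow_m3s
  n <- length(q_in)
  times <- waveform$time_s

  bound <- stability_bound(config, mean(q_in))
  n_sub <- if (dt > 0.8 * bound) as.integer(ceiling(dt / (0.8 * bound))) else 1L
  h <- dt / n_sub

  br <- config$branches
  a <- br$a
  beta <- br$b + br$r2
  cc <- br$c
  c_t <- config$terminal$c_t
  r_t <- config$terminal$r_t
  p_atr <- config$p_atrium
  g <- 1 / config$r_internal
  gs <- sum(g)

  p_b <- rep(settings$initial_pressure, 4)
  p_c <- settings$initial_pressure

  prev <- NULL
  metrics <- list()
  converged <- FALSE
  delta <- NA_real_
  cycles <- 0L

  for (cyc in seq_len(settings$max_cycles)) {
    P <- matrix(0, n, 5)
    PA <- numeric(n)
    QJ <- matrix(0, n, 4)
    QO <- matrix(0, n, 4)
    for (i in seq_len(n)) {
      qi <- q_in[i]
      # record the state and instantaneous flows at the start of the step
      pa_ <- (qi + sum(g * p_b)) / gs
      qj_ <- g * (pa_ - p_b)
      dpv <- p_b - p_c
      qo_ <- sign(dpv) * (-beta + sqrt(beta * beta + 4 * a * abs(dpv))) / (2 * a)
      P[i, ] <- c(p_b, p_c)
      PA[i] <- pa_
      QJ[i, ] <- qj_
      QO[i, ] <- qo_
      for (k in seq_len(n_sub)) {
        if (k > 1L) {
          pa_ <- (qi + sum(g * p_b)) / gs
          qj_ <- g * (pa_ - p_b)
          dpv <- p_b - p_c
          qo_ <- sign(dpv) * (-beta + sqrt(beta * beta + 4 * a * abs(dpv))) / (2 * a)
        }
        p_b <- p_b + h / cc * (qj_ - qo_)
        p_c <- p_c + h / c_t * (sum(qo_) - (p_c - p_atr) / r_t)
      }
    }
    if (any(!is.finite(P)) || any(abs(P) > 1e6)) {
      abort("Numerical instability: node pressure exceeded 1e6 Pa",
        class = "mockloop_instability"
      )
    }
    cycles <- cyc
    if (!is.null(prev)) {
      delta <- max(abs(P - prev))
      metrics[[length(metrics) + 1]] <- tibble(cycle = cyc, max_dp_pa = delta)
      if (delta < settings$periodicity_tol) {
        converged <- TRUE
        break
      }
    }
    prev <- P
  }

  if (!converged) {
    warn(sprintf(
      "Periodic regime not reached after %d cycles (last change %.3g Pa)",
      cycles, delta
    ))
  }

  series <- tibble(
    time_s = times,
    q_in_m3s = q_in,
    p_aorta_pa = PA,
    p_i_pa = P[, 1], p_c_pa = P[, 2], p_s_pa = P[, 3], p_d_pa = P[, 4],
    p_common_pa = P[, 5],
    q_i_m3s = QJ[, 1], q_c_m3s = QJ[, 2], q_s_m3s = QJ[, 3], q_d_m3s = QJ[, 4],
    qout_i_m3s = QO[, 1], qout_c_m3s = QO[, 2], qout_s_m3s = QO[, 3],
    qout_d_m3s = QO[, 4]
  )

  structure(
    list(
      series = series,
      cycles_run = cycles,
      converged = converged,
      delta_p = delta,
      cycle_metrics = dplyr::bind_rows(metrics),
      n_substeps = n_sub,
      period = wf_period(waveform),
      config = config,
      settings = settings
    ),
    class = "mockloop_sim"
  )
}

#' Run the default pulsatile simulation in one call
#'
#' Generates the pump waveform on the solver grid and integrates the
#' network to periodicity.
#'
#' @param config An [lpn_config()]; defaults to the bench preset.
#' @param pump A [pump_settings()]; defaults to the TGA run (5.48 L/min).
#' @param settings A [solver_settings()].
#' @return A `mockloop_sim` object; see [run_to_periodic()].
#' @export
simulate_loop <- function(config = default_network(),
                          pump = pump_settings(),
                          settings = solver_settings()) {
  n <- as.integer(round(pump$period / settings$dt))
  w <- generate_pump_waveform(pump, n_samples = n)
  run_to_periodic(config, w, settings)
}

#' @export
print.mockloop_sim <- function(x, ...) {
  g <- glance(x)
  cat("<mockloop_sim>\n")
  cat(sprintf(
    "  %d cycle(s), converged: %s (last cycle-to-cycle change %.3g Pa)\n",
    x$cycles_run, x$converged, x$delta_p
  ))
  cat(sprintf(
    "  aortic pressure: mean %.1f, peak %.1f, min %.1f mmHg\n",
    g$mean_p_aorta_mmhg, g$peak_p_aorta_mmhg, g$min_p_aorta_mmhg
  ))
  cat(sprintf("  cardiac output: %.2f L/min\n", g$co_lmin))
  invisible(x)
}

#' @rdname run_to_periodic
#' @param x A `mockloop_sim` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mockloop_sim <- function(x, ...) {
  q_cols <- c("q_i_m3s", "q_c_m3s", "q_s_m3s", "q_d_m3s")
  means <- vapply(x$series[q_cols], mean, numeric(1))
  q_ref <- mean(x$series$q_in_m3s)
  tibble(
    label = BRANCH_LABELS,
    mean_flow_lmin = convert_flow(unname(means), "m3/s", "L/min"),
    split_pct = 100 * unname(means) / q_ref
  )
}

#' @rdname run_to_periodic
#' @exportS3Method generics::glance
glance.mockloop_sim <- function(x, ...) {
  pa <- x$series$p_aorta_pa
  tibble(
    mean_p_aorta_mmhg = convert_pressure(mean(pa), "Pa", "mmHg"),
    peak_p_aorta_mmhg = convert_pressure(max(pa), "Pa", "mmHg"),
    min_p_aorta_mmhg = convert_pressure(min(pa), "Pa", "mmHg"),
    co_lmin = convert_flow(mean(x$series$q_in_m3s), "m3/s", "L/min"),
    cycles_run = x$cycles_run,
    converged = x$converged
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.mockloop_sim <- function(object, ...) {
  s <- object$series
  df <- dplyr::bind_rows(
    tibble(
      time_s = s$time_s, value = convert_pressure(s$p_aorta_pa, "Pa", "mmHg"),
      panel = "aortic pressure (mmHg)", series = "p_aorta"
    ),
    tibble(
      time_s = s$time_s, value = convert_flow(s$q_in_m3s, "m3/s", "L/min"),
      panel = "flow (L/min)", series = "inlet"
    ),
    purrr::map2_dfr(
      c("q_i_m3s", "q_c_m3s", "q_s_m3s", "q_d_m3s"), BRANCH_LABELS,
      function(col, lab) {
        tibble(
          time_s = s$time_s,
          value = convert_flow(s[[col]], "m3/s", "L/min"),
          panel = "flow (L/min)", series = lab
        )
      }
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
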