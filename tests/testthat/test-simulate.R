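# Shared runs (each file-scope run is a fraction of a second).
net <- default_network()
sim_tga <- simulate_loop(net, pump_settings(), solver_settings())
q_const <- 9.133e-5
steady_w <- flow_waveform((0:7999) * 1e-4, rep(q_const, 8000), period = 0.8)
sim_steady <- run_to_periodic(net, steady_w, solver_settings())

test_that("junction_solve distributes flow exactly and matches a dense solve", {
  st <- network_state(rep(1e4, 4), 9e3)
  # symmetric case: equal pressures and resistances
  jn <- junction_solve(net, st, 8e-5)
  expect_equal(jn$p_aorta, 1e4 + 8e-5 * 1e6 / 4)
  expect_equal(unname(jn$q_branch), rep(2e-5, 4))
  # zero inflow at equal pressures
  jn0 <- junction_solve(net, st, 0)
  expect_equal(jn0$p_aorta, 1e4)
  expect_equal(unname(jn0$q_branch), rep(0, 4))
  # unequal pressures against the dense linear-system oracle
  cfg <- default_network(r_internal = c(5e5, 2e6, 8e5, 1.3e6))
  p <- c(10900, 11350, 10410, 11120)
  oracle <- junction_dense_oracle(unname(cfg$r_internal), p, 7.3e-5)
  jn2 <- junction_solve(cfg, network_state(p, 9e3), 7.3e-5)
  expect_rel_equal(jn2$p_aorta, oracle$p_aorta, 1e-10)
  expect_rel_equal(unname(jn2$q_branch), oracle$q_branch, 1e-10)
  # mass conservation to machine precision
  expect_rel_equal(sum(jn2$q_branch), 7.3e-5, 1e-12)
})

test_that("step_euler fixes the equilibrium and is first order in dt", {
  st <- network_state(rep(net$p_atrium, 4), net$p_atrium)
  out <- step_euler(net, st, 0, 1e-4)
  expect_equal(out$p_branch, st$p_branch)
  expect_equal(out$p_common, st$p_common)
  # the one-step increment scales linearly with dt
  st2 <- network_state(convert_pressure(c(82, 81, 83, 80), "mmHg", "Pa"),
    convert_pressure(63, "mmHg", "Pa"))
  d1 <- unlist(step_euler(net, st2, 9e-5, 1e-5)[c("p_branch", "p_common")]) -
    unlist(st2[c("p_branch", "p_common")])
  d2 <- unlist(step_euler(net, st2, 9e-5, 2e-5)[c("p_branch", "p_common")]) -
    unlist(st2[c("p_branch", "p_common")])
  expect_rel_equal(d2, 2 * d1, 1e-6)
  # runaway pressures are flagged
  expect_error(
    step_euler(net, network_state(rep(5e5, 4), 5e5), 100, 1e-4),
    class = "mockloop_instability"
  )
})

test_that("time-marched steady state matches the algebraic bisection oracle", {
  oracle <- steady_oracle(net, q_const)
  expect_equal(convert_pressure(oracle$p_aorta, "Pa", "mmHg"), 83.9, tolerance = 1e-3)
  s <- sim_steady$series
  expect_true(sim_steady$converged)
  expect_lt(abs(mean(s$p_aorta_pa) - oracle$p_aorta), 0.1 * 133.322)
  q_sim <- colMeans(s[c("q_i_m3s", "q_c_m3s", "q_s_m3s", "q_d_m3s")])
  expect_rel_equal(unname(q_sim), oracle$q_branch, 0.005)
  # pressure ordering at steady forward flow
  expect_true(mean(s$p_aorta_pa) > max(colMeans(s[c("p_i_pa", "p_c_pa", "p_s_pa", "p_d_pa")])))
  expect_true(min(colMeans(s[c("p_i_pa", "p_c_pa", "p_s_pa", "p_d_pa")])) > mean(s$p_common_pa))
  expect_gt(mean(s$p_common_pa), net$p_atrium)
})

test_that("zero inflow relaxes every node to the atrial pressure", {
  zero_w <- flow_waveform((0:7999) * 1e-4, rep(0, 8000), period = 0.8)
  sim0 <- run_to_periodic(net, zero_w, solver_settings())
  expect_true(sim0$converged)
  p_cols <- c("p_aorta_pa", "p_i_pa", "p_c_pa", "p_s_pa", "p_d_pa", "p_common_pa")
  final <- vapply(sim0$series[p_cols], function(x) x[length(x)], numeric(1))
  expect_true(all(abs(final - net$p_atrium) < 0.5 * 133.322))
  q_cols <- c("qout_i_m3s", "qout_c_m3s", "qout_s_m3s", "qout_d_m3s")
  expect_true(all(abs(vapply(sim0$series[q_cols], function(x) x[length(x)], numeric(1))) < 1e-7))
  # stiff near-zero-flow conductances trigger the sub-stepping guard
  expect_gt(sim0$n_substeps, 1)
})

test_that("the pulsatile run conserves mass and stores no net cycle volume", {
  s <- sim_tga$series
  q_sum <- s$q_i_m3s + s$q_c_m3s + s$q_s_m3s + s$q_d_m3s
  expect_rel_equal(q_sum, s$q_in_m3s, 1e-12)
  # net volume into each compliance over the converged cycle
  sv <- mean(s$q_in_m3s) * sim_tga$period
  dt <- 1e-4
  for (j in 1:4) {
    qc <- c("q_i_m3s", "q_c_m3s", "q_s_m3s", "q_d_m3s")[j]
    qo <- c("qout_i_m3s", "qout_c_m3s", "qout_s_m3s", "qout_d_m3s")[j]
    net_vol <- sum(s[[qc]] - s[[qo]]) * dt
    expect_lt(abs(net_vol) / sv, 0.001)
  }
  net_vol_t <- sum(s$qout_i_m3s + s$qout_c_m3s + s$qout_s_m3s + s$qout_d_m3s -
    (s$p_common_pa - net$p_atrium) / net$terminal$r_t) * dt
  expect_lt(abs(net_vol_t) / sv, 0.001)
  # cycle-mean outlet flow equals cycle-mean inflow within 0.1%
  q_out_mean <- mean(s$qout_i_m3s + s$qout_c_m3s + s$qout_s_m3s + s$qout_d_m3s)
  expect_rel_equal(q_out_mean, mean(s$q_in_m3s), 0.001)
})

test_that("halving the time step moves the mean pressure less than 0.05 mmHg", {
  tight <- function(dt) {
    solver_settings(dt = dt, periodicity_tol = 1, max_cycles = 60)
  }
  w1 <- generate_pump_waveform(pump_settings(), n_samples = 8000)
  w2 <- generate_pump_waveform(pump_settings(), n_samples = 16000)
  m1 <- mean(run_to_periodic(net, w1, tight(1e-4))$series$p_aorta_pa)
  m2 <- mean(run_to_periodic(net, w2, tight(5e-5))$series$p_aorta_pa)
  expect_lt(abs(m1 - m2), 0.05 * 133.322)
})

test_that("the converged cycle is independent of the initial condition", {
  low <- solver_settings(initial_pressure = convert_pressure(40, "mmHg", "Pa"),
    periodicity_tol = 1, max_cycles = 80)
  high <- solver_settings(initial_pressure = convert_pressure(120, "mmHg", "Pa"),
    periodicity_tol = 1, max_cycles = 80)
  w <- generate_pump_waveform(pump_settings(), n_samples = 8000)
  s_low <- run_to_periodic(net, w, low)
  s_high <- run_to_periodic(net, w, high)
  expect_true(s_low$converged && s_high$converged)
  expect_lt(
    max(abs(s_low$series$p_aorta_pa - s_high$series$p_aorta_pa)),
    0.05 * 133.322
  )
})

test_that("loading the network harder raises the mean aortic pressure", {
  up <- simulate_loop(net,
    pump_settings(cardiac_output = 1.1 * convert_flow(5.48, "L/min", "m3/s")))
  expect_gt(
    mean(up$series$p_aorta_pa),
    mean(sim_tga$series$p_aorta_pa)
  )
})

test_that("a too-large step engages sub-stepping and agrees with the fine run", {
  sim_coarse <- simulate_loop(net, pump_settings(), solver_settings(dt = 4e-4))
  expect_gt(sim_coarse$n_substeps, 1)
  expect_lt(
    abs(mean(sim_coarse$series$p_aorta_pa) - mean(sim_tga$series$p_aorta_pa)),
    0.5 * 133.322
  )
})

test_that("Poiseuille wall shear stress follows 4 mu q / (pi r^3)", {
  expect_equal(
    wss_poiseuille(9.133e-5, 0.006, 1e-3),
    4 * 1e-3 * 9.133e-5 / (pi * 0.006^3)
  )
  expect_equal(wss_poiseuille(9.133e-5, 0.006, 1e-3), 0.538, tolerance = 1e-3)
  expect_identical(wss_poiseuille(0, 0.01, 1e-3), 0)
  expect_equal(
    wss_poiseuille(2 * 9.133e-5, 0.006, 1e-3),
    2 * wss_poiseuille(9.133e-5, 0.006, 1e-3)
  )
  expect_equal(wss_poiseuille(-1e-5, 0.006, 1e-3), -wss_poiseuille(1e-5, 0.006, 1e-3))
})

test_that("power dissipation bookkeeping closes at steady flow", {
  s <- sim_steady$series
  q_mean <- colMeans(s[c("q_i_m3s", "q_c_m3s", "q_s_m3s", "q_d_m3s")])
  # outlet areas proportional to the actual flow fractions: outlet
  # velocities equal the inlet velocity, so kinetic fluxes cancel exactly
  area_in <- pi * (net$inlet_diameter / 2)^2
  areas <- area_in * unname(q_mean) / q_const
  pd <- power_dissipation(sim_steady, outlet_areas = areas)
  element_sum <- sum(net$r_internal * q_mean^2)
  expect_rel_equal(pd, element_sum, 0.01)
  expect_gt(pd, 0)
  # each internal resistance dissipates R q^2 at steady flow
  expect_rel_equal(element_sum, sum(1e6 * q_mean^2), 1e-12)
  # dropping the kinetic terms reduces to the element sum for any areas
  pd_static <- power_dissipation(sim_tga, include_kinetic = FALSE)
  s2 <- sim_tga$series
  element_sum_tga <- mean(1e6 * (s2$q_i_m3s^2 + s2$q_c_m3s^2 + s2$q_s_m3s^2 + s2$q_d_m3s^2))
  expect_rel_equal(pd_static, element_sum_tga, 1e-10)
  expect_gt(pd_static, 0)
  # zero flow dissipates nothing
  zero_w <- flow_waveform((0:7999) * 1e-4, rep(0, 8000), period = 0.8)
  sim0 <- run_to_periodic(net, zero_w, solver_settings())
  expect_lt(abs(power_dissipation(sim0)), 1e-6)
  # non-converged results are refused
  nc <- sim_tga
  nc$converged <- FALSE
  expect_error(power_dissipation(nc), class = "mockloop_not_converged")
})

test_that("tidy and glance summarise the fitted run", {
  td <- tidy(sim_tga)
  expect_identical(td$label, c("innominate", "carotid", "subclavian", "descending_aorta"))
  expect_rel_equal(sum(td$split_pct), 100, 0.001)
  g <- glance(sim_tga)
  expect_true(g$converged)
  expect_rel_equal(g$co_lmin, 5.48, 1e-6)
  expect_true(g$min_p_aorta_mmhg < g$mean_p_aorta_mmhg &&
    g$mean_p_aorta_mmhg < g$peak_p_aorta_mmhg)
  expect_s3_class(ggplot2::autoplot(sim_tga), "ggplot")
})
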