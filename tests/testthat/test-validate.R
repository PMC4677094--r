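test_that("waveform features recover closed-form summaries", {
  tt <- (0:999) * 1e-3
  const <- data.frame(time_s = tt, v = rep(3.2, 1000))
  f <- waveform_features(const, "v", period = 1)
  expect_equal(f$cycle_mean, 3.2)
  expect_equal(f$peak, 3.2)
  expect_equal(f$minimum, 3.2)
  # half-sine of peak A over half the cycle: mean = A / pi
  A <- 2.5
  hs <- data.frame(time_s = tt, v = ifelse(tt < 0.5, A * sin(2 * pi * tt), 0))
  fh <- waveform_features(hs, "v", period = 1)
  expect_equal(fh$cycle_mean, A / pi, tolerance = 1e-3)
  # sampled instants: four values, peak among the systolic ones
  fs <- waveform_features(hs, "v", sample_at = c(0.1, 0.2, 0.4, 0.6), period = 1)
  expect_equal(nrow(fs$values_at), 4)
  expect_equal(fs$values_at$value[4], 0)
  expect_equal(max(fs$values_at$value), A * sin(2 * pi * 0.2), tolerance = 1e-3)
  expect_true(fs$minimum <= fs$cycle_mean && fs$cycle_mean <= fs$peak)
})

test_that("flow splits normalise by the requested reference", {
  flows <- c(0.86, 0.56, 0.98, 3.02)
  sp <- flow_split(flows)
  expect_equal(sp$split_pct, 100 * flows / sum(flows)) # 15.9, 10.3, 18.1, 55.7
  expect_rel_equal(sum(sp$split_pct), 100, 1e-9)
  expect_equal(flow_split(rep(1.3, 4))$split_pct, rep(25, 4))
  expect_equal(flow_split(c(2, 0, 0, 0), reference = 2)$split_pct, c(100, 0, 0, 0))
  # against the unprinted inlet mean the percentages shrink accordingly
  sp_in <- flow_split(flows, reference = 5.48)
  expect_equal(sp_in$split_pct, 100 * flows / 5.48)
  expect_error(flow_split(flows, reference = 0), class = "mockloop_invalid_params")
})

test_that("percentage errors match the reported pressure comparisons", {
  expect_equal(round(percent_error(84.6, 85.7), 1), 1.3)
  expect_equal(round(percent_error(87.0, 83.2), 1), 4.4)
  expect_identical(percent_error(12.3, 12.3), 0)
  # invariance under common rescaling of both inputs
  expect_equal(percent_error(84.6, 85.7), percent_error(84.6 * 133.322, 85.7 * 133.322))
  expect_error(percent_error(0, 1), class = "mockloop_invalid_params")
})

test_that("the largest split discrepancy is located correctly", {
  ft <- reference_flow_table()
  cmr <- ft[ft$anatomy == "tga" & ft$modality == "cmr", ]
  cfd <- ft[ft$anatomy == "tga" & ft$modality == "cfd", ]
  mx <- max_split_error(cmr$split_pct, cfd$split_pct)
  expect_equal(mx$value, 3.6, tolerance = 1e-9)
  expect_identical(mx$branch, "subclavian")
  # ties resolve to the first branch in canonical order
  same <- max_split_error(c(25, 25, 25, 25), c(25, 25, 25, 25))
  expect_identical(same$value, 0)
  expect_identical(same$branch, "innominate")
  pert <- max_split_error(c(25, 25, 25, 25), c(25, 25, 25 + 0.7, 25))
  expect_equal(pert$value, 0.7)
  expect_identical(pert$branch, "subclavian")
  # unit-rescaling invariance
  expect_equal(
    max_split_error(cmr$split_pct * 2, cfd$split_pct * 2)$value, 2 * 3.6,
    tolerance = 1e-9
  )
})

test_that("r_squared is a squared Pearson correlation with its invariances", {
  x <- seq(1, 5, length.out = 20)
  expect_equal(r_squared(x, 2 * x + 1), 1)
  expect_equal(r_squared(x, -3 * x + 7), 1)
  y <- sin(x)
  expect_equal(r_squared(x, y), r_squared(y, x))
  expect_equal(r_squared(x, y), r_squared(5 * x - 2, 0.1 * y + 4))
  set.seed(101)
  noise <- rnorm(1e4)
  expect_lt(r_squared(rnorm(1e4), noise), 0.1)
  expect_error(r_squared(x, rep(1, 20)), class = "mockloop_degenerate")
  expect_error(r_squared(x, x[1:5]), class = "mockloop_invalid_params")
})

test_that("Bland-Altman statistics match the distributional oracle", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  ba_shift <- bland_altman(x, x - 0.75)
  expect_equal(ba_shift$bias, 0.75)
  expect_equal(ba_shift$loa_high - ba_shift$loa_low, 0)
  # seeded standard-normal differences: limits near +/- 1.96
  set.seed(2024)
  d <- rnorm(1e5)
  ba <- bland_altman(d, rep(0, 1e5))
  expect_equal(ba$loa_low, -1.96, tolerance = 0.02)
  expect_equal(ba$loa_high, 1.96, tolerance = 0.02)
  # swapping arguments flips the bias and keeps the width
  y <- x + c(0.1, -0.2, 0.05, 0.3)
  b1 <- bland_altman(x, y)
  b2 <- bland_altman(y, x)
  expect_equal(b1$bias, -b2$bias)
  expect_equal(b1$loa_high - b1$loa_low, b2$loa_high - b2$loa_low)
  expect_s3_class(ggplot2::autoplot(b1), "ggplot")
})

test_that("a simulation compared with itself reports perfect agreement", {
  sim <- simulate_loop()
  td <- tidy(sim)
  g <- glance(sim)
  self <- list(
    flows_lmin = td$mean_flow_lmin,
    reference_lmin = g$co_lmin,
    pressure_mmhg = list(
      mean = g$mean_p_aorta_mmhg,
      peak = g$peak_p_aorta_mmhg, min = g$min_p_aorta_mmhg
    ),
    series = tibble::tibble(
      time_s = sim$series$time_s,
      innominate = sim$series$q_i_m3s,
      carotid = sim$series$q_c_m3s,
      subclavian = sim$series$q_s_m3s,
      descending_aorta = sim$series$q_d_m3s
    )
  )
  rpt <- build_report(sim, self)
  expect_lt(rpt$max_split$value, 1e-9)
  expect_true(all(abs(rpt$pressure$percent_error) < 1e-9))
  expect_true(all(rpt$agreement$r_squared > 1 - 1e-12))
  expect_true(all(abs(rpt$agreement$bias) < 1e-12))
  expect_identical(
    rpt$sampled$time_s[rpt$sampled$location == "innominate"],
    c(0.1, 0.2, 0.4, 0.6)
  )
  expect_s3_class(glance(rpt), "tbl_df")
})

test_that("the bundled summary tables reproduce the in-study statistics", {
  stats <- study_summary_stats()
  expect_equal(round(stats$pressure$percent_error, 1), c(1.3, 4.4))
  expect_equal(stats$splits$tga$max_split_pp, 3.6, tolerance = 1e-9)
  expect_identical(stats$splits$tga$max_split_branch, "subclavian")
  expect_equal(stats$splits$control$max_split_pp, 2.6, tolerance = 1e-9)
  expect_identical(stats$splits$control$max_split_branch, "descending_aorta")
})
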