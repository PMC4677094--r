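# Pulsatile inlet waveform: a pump-like half-sine ejection profile standing
# in for the (unpublished) bench pump curve, plus emulation of the gated
# phase-contrast MR sampling used to measure the inlet curve and of the
# interpolation onto the ODE solver grid.

#' Construct a periodic flow waveform
#'
#' A flow waveform is a tibble with columns `time_s` and `flow_m3s`
#' covering exactly one cycle on a uniform grid starting at t = 0, plus a
#' `period` attribute. All waveform generators and readers return this
#' structure.
#'
#' @param times Sample instants in s: uniformly spaced, starting at 0,
#'   strictly increasing, covering one period (the last sample is at
#'   `period - spacing`).
#' @param flows Volumetric flow in m^3/s at each instant.
#' @param period Cycle length in s; defaults to `n * spacing`.
#' @return A `flow_waveform` tibble.
#' @export
flow_waveform <- function(times, flows, period = NULL) {
  if (length(times) < 2 || length(times) != length(flows)) {
    abort("`times` and `flows` must be equal-length vectors (n >= 2)",
      class = "mockloop_waveform_error"
    )
  }
  dts <- diff(times)
  spacing <- dts[1]
  if (abs(times[1]) > 1e-12 || any(dts <= 0) ||
    any(abs(dts - spacing) > 1e-9 * spacing)) {
    abort("Waveform time grid must be uniform, increasing, and start at t = 0",
      class = "mockloop_waveform_grid_error"
    )
  }
  if (is.null(period)) period <- length(times) * spacing
  if (!is.finite(period) || period <= 0 || period < times[length(times)]) {
    abort("`period` must be positive and cover all samples",
      class = "mockloop_waveform_error"
    )
  }
  structure(
    tibble(time_s = as.numeric(times), flow_m3s = as.numeric(flows)),
    period = period,
    class = c("flow_waveform", class(tibble()))
  )
}

#' Cycle length of a flow waveform
#' @param w A [flow_waveform()].
#' @return Period in s.
#' @export
wf_period <- function(w) attr(w, "period", exact = TRUE)

wf_spacing <- function(w) w$time_s[2] - w$time_s[1]

#' Pump stroke settings
#'
#' Defaults describe the run used throughout: cycle length 0.8 s with
#' ejection over the first half of the cycle, and a mean flow (cardiac
#' output) of 5.48 L/min, the sum of the computed outlet means for the TGA
#' model. The control run uses the same shape at 5.25 L/min.
#'
#' @param cardiac_output Mean flow over the cycle in m^3/s; positive.
#' @param period Cycle length T in s; positive.
#' @param systolic_fraction Fraction of the cycle with forward ejection,
#'   in (0, 1).
#' @param backflow_fraction Amplitude of a brief negative lobe right after
#'   ejection, relative to peak flow; in \[0, 0.15\].
#' @return A named list with class `pump_settings`.
#' @export
pump_settings <- function(cardiac_output = convert_flow(5.48, "L/min", "m3/s"),
                          period = 0.8,
                          systolic_fraction = 0.5,
                          backflow_fraction = 0) {
  ok <- is.finite(cardiac_output) && cardiac_output > 0 &&
    is.finite(period) && period > 0 &&
    is.finite(systolic_fraction) && systolic_fraction > 0 &&
    systolic_fraction < 1 &&
    is.finite(backflow_fraction) && backflow_fraction >= 0 &&
    backflow_fraction <= 0.15
  if (!ok) {
    abort(
      paste(
        "Invalid pump settings: need cardiac_output > 0, period > 0,",
        "0 < systolic_fraction < 1, 0 <= backflow_fraction <= 0.15"
      ),
      class = "mockloop_invalid_params"
    )
  }
  structure(
    list(
      cardiac_output = cardiac_output, period = period,
      systolic_fraction = systolic_fraction,
      backflow_fraction = backflow_fraction
    ),
    class = "pump_settings"
  )
}

#' Generate a pump-like pulsatile inlet waveform
#'
#' Half-sine forward ejection over `[0, systolic_fraction * T]`, an optional
#' brief negative lobe immediately after ejection (emulating valve-free
#' backflow), and zero flow for the rest of diastole. The peak is set from
#' the closed-form half-sine mean, `Q_peak = CO * pi / (2 * f_s)`, then all
#' samples are rescaled so the discrete cycle mean equals the cardiac output
#' exactly.
#'
#' @param settings A [pump_settings()] object.
#' @param n_samples Number of uniform samples over one cycle; at least 16.
#' @return A [flow_waveform()].
#' @examples
#' w <- generate_pump_waveform(pump_settings(), n_samples = 200)
#' mean(w$flow_m3s) * 60000 # cardiac output in L/min
#' @export
generate_pump_waveform <- function(settings, n_samples = 256) {
  stopifnot(inherits(settings, "pump_settings"))
  if (!is.numeric(n_samples) || n_samples < 16) {
    abort("`n_samples` must be at least 16", class = "mockloop_invalid_params")
  }
  n <- as.integer(n_samples)
  T_ <- settings$period
  fs <- settings$systolic_fraction
  times <- (seq_len(n) - 1) * T_ / n
  q_peak <- settings$cardiac_output * pi / (2 * fs)
  q <- numeric(n)
  sys <- times < fs * T_
  q[sys] <- q_peak * sin(pi * times[sys] / (fs * T_))
  if (settings$backflow_fraction > 0) {
    lobe_len <- 0.2 * fs * T_
    lobe <- !sys & times < fs * T_ + lobe_len
    q[lobe] <- -settings$backflow_fraction * q_peak *
      sin(pi * (times[lobe] - fs * T_) / lobe_len)
  }
  q <- q * settings$cardiac_output / mean(q)
  flow_waveform(times, q, period = T_)
}

#' Emulate gated phase-contrast MR sampling of a waveform
#'
#' Resamples a waveform to the scanner's temporal resolution by phase-bin
#' averaging — the cycle is divided into a whole number of phase bins of
#' width close to `dt_sample` (as in retrospectively gated reconstruction)
#' and native samples are averaged within each bin — then adds seeded
#' Gaussian measurement noise. Deterministic for a given seed.
#'
#' @param w A [flow_waveform()].
#' @param dt_sample Target temporal resolution in s; at least the native
#'   spacing and less than the period. The 2D PC acquisition of the inlet
#'   curve used 29.9 ms.
#' @param noise_sd Standard deviation of additive Gaussian noise, m^3/s.
#' @param seed Integer RNG seed for the noise.
#' @return A [flow_waveform()] on the coarse grid.
#' @export
emulate_pcmr_sampling <- function(w, dt_sample = 0.0299, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(w, "flow_waveform"))
  T_ <- wf_period(w)
  native <- wf_spacing(w)
  if (dt_sample >= T_) {
    abort("`dt_sample` must be smaller than the waveform period",
      class = "mockloop_invalid_params"
    )
  }
  if (dt_sample < native * (1 - 1e-9)) {
    abort("`dt_sample` must be at least the native sample spacing",
      class = "mockloop_invalid_params"
    )
  }
  m <- max(1L, as.integer(round(T_ / dt_sample)))
  width <- T_ / m
  # tolerate floating-point jitter at bin boundaries
  bin <- pmin(m - 1L, floor(w$time_s / width + 1e-9))
  flows <- as.numeric(tapply(w$flow_m3s, factor(bin, levels = 0:(m - 1L)), mean))
  empty <- is.na(flows)
  if (any(empty)) {
    centres <- (which(empty) - 0.5) * width
    flows[empty] <- interp_periodic(w$time_s, w$flow_m3s, T_, centres)
  }
  if (noise_sd > 0) {
    flows <- flows + withr::with_seed(seed, rnorm(m, 0, noise_sd))
  }
  flow_waveform((0:(m - 1L)) * width, flows, period = T_)
}

#' Interpolate a waveform onto the solver time grid
#'
#' Periodic linear interpolation onto a uniform grid of spacing `dt`
#' (default 1e-4 s, the integrator step). The waveform wraps: the value at
#' the period equals the value at t = 0.
#'
#' @param w A [flow_waveform()].
#' @param dt Target grid spacing in s; positive.
#' @return A [flow_waveform()] on the solver grid.
#' @export
interpolate_to_solver_grid <- function(w, dt = 1e-4) {
  stopifnot(inherits(w, "flow_waveform"))
  if (!is.finite(dt) || dt <= 0) {
    abort("`dt` must be positive", class = "mockloop_invalid_params")
  }
  T_ <- wf_period(w)
  n <- max(2L, as.integer(round(T_ / dt)))
  grid <- (0:(n - 1L)) * dt
  out <- approx(
    x = c(w$time_s, T_), y = c(w$flow_m3s, w$flow_m3s[1]),
    xout = grid %% T_, method = "linear", rule = 2
  )$y
  flow_waveform(grid, out, period = n * dt)
}

# Periodic linear interpolation of an arbitrary uniformly sampled series.
interp_periodic <- function(times, values, period, at) {
  approx(
    x = c(times, period), y = c(values, values[1]),
    xout = at %% period, method = "linear", rule = 2
  )$y
}

#' Mean velocity across a circular cross-section
#'
#' @param q Volumetric flow in m^3/s (vectorised).
#' @param diameter Tube diameter in m; positive.
#' @return Cross-sectional mean velocity in m/s.
#' @examples
#' flow_to_velocity(convert_flow(5.48, "L/min", "m3/s"), 0.012)
#' @export
flow_to_velocity <- function(q, diameter) {
  if (!all(is.finite(diameter)) || any(diameter <= 0)) {
    abort("`diameter` must be positive", class = "mockloop_invalid_params")
  }
  q / (pi * (diameter / 2)^2)
}

#' Write a waveform to CSV
#'
#' One cycle, header `time_s,flow_m3s`, full double precision. Writing then
#' reading reproduces the samples exactly.
#'
#' @param w A [flow_waveform()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "flow_waveform"))
  lines <- c(
    "time_s,flow_m3s",
    sprintf("%.17g,%.17g", w$time_s, w$flow_m3s)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a waveform from CSV
#'
#' Validates the header and the uniformity of the time grid; the period is
#' inferred as `n * spacing`.
#'
#' @param path Path to a CSV written by [write_waveform_csv()].
#' @return A [flow_waveform()].
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Waveform file not found: %s", path),
      class = "mockloop_io_error"
    )
  }
  header <- readLines(path, n = 1)
  if (!identical(header, "time_s,flow_m3s")) {
    abort(
      sprintf("Malformed waveform CSV header: expected 'time_s,flow_m3s', got '%s'", header),
      class = "mockloop_csv_header_error"
    )
  }
  df <- utils::read.csv(path, colClasses = "numeric")
  flow_waveform(df$time_s, df$flow_m3s)
}

#' @exportS3Method ggplot2::autoplot
autoplot.flow_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$flow_m3s * 60000)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "inlet flow (L/min)") +
    ggplot2::theme_minimal()
}
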