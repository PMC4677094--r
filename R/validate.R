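# Validation statistics: waveform summaries, flow splits, percentage
# errors, correlation, and Bland-Altman agreement between a measured and a
# simulated haemodynamic data set.

#' Summarise a periodic waveform
#'
#' Cycle mean (time average on the uniform grid), peak, minimum, and the
#' values at requested instants (periodic linear interpolation, instants
#' wrapped into the cycle).
#'
#' @param data A data frame with a time column and a value column; one
#'   cycle on a uniform grid (e.g. a [flow_waveform()] or a
#'   `mockloop_sim$series`).
#' @param value Name of the value column.
#' @param time Name of the time column (default `"time_s"`).
#' @param sample_at Instants (s) at which to report interpolated values;
#'   the study compares at 0.1, 0.2, 0.4 and 0.6 s (early/peak/late
#'   systole, diastole).
#' @param period Cycle length in s; defaults to the waveform's `period`
#'   attribute or `n * spacing`.
#' @return A list with `cycle_mean`, `peak`, `minimum`, and `values_at`
#'   (tibble `time_s`, `value`).
#' @export
waveform_features <- function(data, value, time = "time_s",
                              sample_at = NULL, period = NULL) {
  if (!all(c(time, value) %in% names(data)) || nrow(data) < 2) {
    abort("`data` must contain the time and value columns (n >= 2)",
      class = "mockloop_invalid_params"
    )
  }
  tt <- data[[time]]
  vv <- data[[value]]
  if (is.null(period)) {
    period <- attr(data, "period", exact = TRUE)
    if (is.null(period)) period <- length(tt) * (tt[2] - tt[1])
  }
  values_at <- if (is.null(sample_at)) {
    tibble(time_s = numeric(0), value = numeric(0))
  } else {
    tibble(time_s = sample_at, value = interp_periodic(tt, vv, period, sample_at))
  }
  list(
    cycle_mean = mean(vv),
    peak = max(vv),
    minimum = min(vv),
    values_at = values_at
  )
}

#' Per-branch flow split table
#'
#' Expresses per-branch mean flows as percentages of a reference flow. For
#' simulation output the natural reference is the cycle-mean inlet flow
#' (identical to the outlet sum at periodicity, by mass conservation); for
#' printed summary tables pass the reference explicitly.
#'
#' @param mean_flows Four per-branch mean flows (any single unit).
#' @param reference `"sum"` (default) or a positive flow in the same unit.
#' @param labels Branch labels, defaulting to the canonical order.
#' @return A tibble with `label`, `flow`, `split_pct`; the reference flow
#'   is attached as attribute `reference`.
#' @export
flow_split <- function(mean_flows, reference = "sum",
                       labels = BRANCH_LABELS) {
  mean_flows <- as.numeric(mean_flows)
  if (length(mean_flows) != length(labels) || any(mean_flows < 0)) {
    abort("`mean_flows` must be non-negative, one per label",
      class = "mockloop_invalid_params"
    )
  }
  ref <- if (identical(reference, "sum")) sum(mean_flows) else as.numeric(reference)
  if (!is.finite(ref) || ref <= 0) {
    abort("Reference flow must be positive", class = "mockloop_invalid_params")
  }
  out <- tibble(
    label = labels, flow = mean_flows,
    split_pct = 100 * mean_flows / ref
  )
  attr(out, "reference") <- ref
  out
}

#' Percentage error of a simulated value against a measured one
#'
#' `100 * |simulated - measured| / measured`, the convention used for the
#' measured-vs-computed mean pressure comparison.
#'
#' @param measured,simulated Numeric vectors (recycled); `measured` must be
#'   non-zero.
#' @return Non-negative percentage(s).
#' @examples
#' percent_error(84.6, 85.7) # 1.3 to printed rounding
#' @export
percent_error <- function(measured, simulated) {
  if (any(measured == 0)) {
    abort("`measured` must be non-zero", class = "mockloop_invalid_params")
  }
  100 * abs(simulated - measured) / abs(measured)
}

#' Largest per-branch flow-split discrepancy
#'
#' Maximum absolute componentwise difference between two percentage-split
#' vectors, with the branch where it occurs; ties resolve to the earlier
#' branch in canonical order.
#'
#' @param measured_pct,simulated_pct Four percentage splits.
#' @param labels Branch labels in matching order.
#' @return A list with `value` (percentage points) and `branch`.
#' @export
max_split_error <- function(measured_pct, simulated_pct,
                            labels = BRANCH_LABELS) {
  if (length(measured_pct) != length(simulated_pct) ||
    length(measured_pct) != length(labels)) {
    abort("Split vectors and labels must have equal length",
      class = "mockloop_invalid_params"
    )
  }
  d <- abs(measured_pct - simulated_pct)
  i <- which.max(d) # first maximum: tie-break by branch order
  list(value = d[i], branch = labels[i])
}

#' Squared Pearson correlation
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with non-degenerate
#'   variance.
#' @return R-squared in \[0, 1\].
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must be equal-length with n >= 3",
      class = "mockloop_invalid_params"
    )
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Degenerate variance: R-squared undefined",
      class = "mockloop_degenerate"
    )
  }
  cor(x, y)^2
}

#' Bland-Altman agreement statistics
#'
#' Bias is `mean(x - y)`; limits of agreement are bias +/- 1.96 times the
#' sample standard deviation (n - 1 denominator) of the differences.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), conventionally
#'   measured and simulated.
#' @return A one-row tibble of class `bland_altman` with `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n`; the per-pair means and differences are
#'   attached for [autoplot()].
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must be equal-length with n >= 3",
      class = "mockloop_invalid_params"
    )
  }
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  out <- tibble(
    bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    sd_diff = s, n = length(d)
  )
  attr(out, "pairs") <- tibble(mean = (x + y) / 2, diff = d)
  class(out) <- c("bland_altman", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  pairs <- attr(object, "pairs", exact = TRUE)
  ggplot2::ggplot(pairs, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high),
      linetype = 2
    ) +
    ggplot2::labs(x = "mean of pair", y = "difference") +
    ggplot2::theme_minimal()
}

#' Assemble the measured-vs-simulated comparison report
#'
#' Brings together the comparison statistics: measured and simulated flow
#' splits with per-branch differences and the maximum discrepancy, mean
#' (and, if available, peak/minimum) pressure percentage errors, per-branch
#' R-squared and Bland-Altman agreement when a measured flow time series is
#' supplied, and both sides sampled at the comparison instants.
#'
#' @param sim A `mockloop_sim` from [run_to_periodic()].
#' @param measured A list with elements:
#'   * `flows_lmin`: four per-branch mean flows in L/min (canonical order);
#'   * `pressure_mmhg`: list with `mean` and optionally `peak`, `min`;
#'   * `series` (optional): tibble `time_s` plus one flow column (m^3/s)
#'     per branch label, one cycle, for the agreement statistics;
#'   * `reference_lmin` (optional): reference flow for the measured split
#'     percentages (defaults to the sum of the measured means).
#' @param sample_at Comparison instants in s (default 0.1, 0.2, 0.4, 0.6).
#' @return A `comparison_report` list with tibbles `splits`, `pressure`,
#'   `agreement`, `sampled`, plus `max_split` (`value`, `branch`).
#' @export
build_report <- function(sim, measured, sample_at = c(0.1, 0.2, 0.4, 0.6)) {
  stopifnot(inherits(sim, "mockloop_sim"))
  if (is.null(measured$flows_lmin) || is.null(measured$pressure_mmhg$mean)) {
    abort("`measured` needs `flows_lmin` and `pressure_mmhg$mean`",
      class = "mockloop_invalid_params"
    )
  }
  sim_tidy <- tidy(sim)
  sim_glance <- glance(sim)

  ref_meas <- if (is.null(measured$reference_lmin)) "sum" else measured$reference_lmin
  meas_split <- flow_split(measured$flows_lmin, reference = ref_meas)
  splits <- tibble(
    label = BRANCH_LABELS,
    measured_lmin = meas_split$flow,
    measured_pct = meas_split$split_pct,
    simulated_lmin = sim_tidy$mean_flow_lmin,
    simulated_pct = sim_tidy$split_pct,
    diff_pp = sim_tidy$split_pct - meas_split$split_pct
  )
  max_split <- max_split_error(splits$measured_pct, splits$simulated_pct)

  press <- list(
    tibble(
      quantity = "mean",
      measured_mmhg = measured$pressure_mmhg$mean,
      simulated_mmhg = sim_glance$mean_p_aorta_mmhg
    )
  )
  if (!is.null(measured$pressure_mmhg$peak)) {
    press <- c(press, list(tibble(
      quantity = "peak",
      measured_mmhg = measured$pressure_mmhg$peak,
      simulated_mmhg = sim_glance$peak_p_aorta_mmhg
    )))
  }
  if (!is.null(measured$pressure_mmhg$min)) {
    press <- c(press, list(tibble(
      quantity = "min",
      measured_mmhg = measured$pressure_mmhg$min,
      simulated_mmhg = sim_glance$min_p_aorta_mmhg
    )))
  }
  pressure <- dplyr::bind_rows(press)
  pressure$percent_error <- percent_error(
    pressure$measured_mmhg, pressure$simulated_mmhg
  )

  q_cols <- c(
    innominate = "q_i_m3s", carotid = "q_c_m3s",
    subclavian = "q_s_m3s", descending_aorta = "q_d_m3s"
  )
  agreement <- NULL
  if (!is.null(measured$series)) {
    ms <- measured$series
    agreement <- purrr::map_dfr(BRANCH_LABELS, function(lab) {
      if (!lab %in% names(ms)) {
        return(tibble())
      }
      sim_at <- interp_periodic(
        sim$series$time_s, sim$series[[q_cols[[lab]]]],
        sim$period, ms$time_s
      )
      ba <- bland_altman(ms[[lab]], sim_at)
      tibble(
        location = lab,
        r_squared = r_squared(ms[[lab]], sim_at),
        bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high
      )
    })
  }

  sampled <- purrr::map_dfr(names(q_cols), function(lab) {
    f <- waveform_features(sim$series, q_cols[[lab]],
      sample_at = sample_at, period = sim$period
    )
    tibble(
      location = lab, time_s = f$values_at$time_s,
      simulated_lmin = convert_flow(f$values_at$value, "m3/s", "L/min"),
      measured_lmin = if (!is.null(measured$series) && lab %in% names(measured$series)) {
        convert_flow(
          interp_periodic(
            measured$series$time_s, measured$series[[lab]],
            sim$period, sample_at
          ),
          "m3/s", "L/min"
        )
      } else {
        NA_real_
      }
    )
  })
  p_feat <- waveform_features(sim$series, "p_aorta_pa",
    sample_at = sample_at, period = sim$period
  )
  sampled <- dplyr::bind_rows(
    sampled,
    tibble(
      location = "aortic_pressure", time_s = p_feat$values_at$time_s,
      simulated_lmin = NA_real_,
      measured_lmin = NA_real_,
    ) |>
      dplyr::mutate(simulated_mmhg = convert_pressure(
        p_feat$values_at$value, "Pa", "mmHg"
      ))
  )

  structure(
    list(
      splits = splits, max_split = max_split, pressure = pressure,
      agreement = agreement, sampled = sampled
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat("flow splits (%):\n")
  print(
    dplyr::mutate(x$splits, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 1)))
  )
  cat(sprintf(
    "max split discrepancy: %.1f percentage points at %s\n",
    x$max_split$value, x$max_split$branch
  ))
  cat("pressure (mmHg):\n")
  print(
    dplyr::mutate(x$pressure, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 1)))
  )
  if (!is.null(x$agreement) && nrow(x$agreement) > 0) {
    cat("agreement (flow, m^3/s):\n")
    print(x$agreement)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.comparison_report <- function(x, ...) x$splits

#' @exportS3Method generics::glance
glance.comparison_report <- function(x, ...) {
  tibble(
    max_split_pp = x$max_split$value,
    max_split_branch = x$max_split$branch,
    mean_pressure_pct_error = x$pressure$percent_error[x$pressure$quantity == "mean"],
    min_r_squared = if (!is.null(x$agreement) && nrow(x$agreement) > 0) {
      min(x$agreement$r_squared)
    } else {
      NA_real_
    }
  )
}
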