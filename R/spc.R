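# Attribute control charts for event rates with variable denominators:
# the classic u-chart (3-sigma Poisson limits) and the Laney U' variant,
# which rescales the limits by sigma_z -- a moving-range estimate of the
# dispersion of the period z-scores -- so that between-period
# overdispersion does not flood the chart with false special-cause
# signals.

chart_inputs <- function(counts, denominators = NULL, period_ids = NULL) {
  if (inherits(counts, "rate_series")) {
    series <- counts
    counts <- series$numerator
    denominators <- series$denominator
    if (is.null(period_ids)) period_ids <- series$period_id
  }
  if (is.null(period_ids)) period_ids <- as.character(seq_along(counts))
  stopifnot(
    length(counts) == length(denominators),
    length(counts) == length(period_ids)
  )
  if (any(denominators <= 0)) {
    stop("domain error: denominators must be positive", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("domain error: counts must be non-negative", call. = FALSE)
  }
  list(
    counts = as.numeric(counts),
    denominators = as.numeric(denominators),
    period_ids = as.character(period_ids)
  )
}

new_control_chart <- function(chart_type, center, periods, sigma_z,
                              selection = NULL) {
  chart <- structure(
    list(
      chart_type = chart_type,
      center = center,
      periods = periods,
      sigma_z = sigma_z,
      signals = NULL,
      selection = selection
    ),
    class = "control_chart"
  )
  chart$signals <- detect_signals(chart)
  chart
}

#' @export
print.control_chart <- function(x, ...) {
  cat(sprintf(
    "<control_chart> %s: center %.6g, %d period(s), sigma_z %s, %d signal(s)\n",
    x$chart_type, x$center, nrow(x$periods),
    ifelse(is.na(x$sigma_z), "-", sprintf("%.3f", x$sigma_z)),
    nrow(x$signals)
  ))
  print(x$periods, ...)
  invisible(x)
}

#' u-chart for per-period event rates
#'
#' Center line \eqn{\bar u = \sum c_i / \sum n_i}; per-period 3-sigma
#' limits \eqn{\bar u \pm 3\sqrt{\bar u / n_i}}, lower limit floored at
#' zero. Limits are recomputed for every period's own denominator; no
#' baseline freezing.
#'
#' @param counts Per-period event counts, or a `rate_series` (in which
#'   case `denominators`/`period_ids` are taken from it).
#' @param denominators Per-period exposures (positive).
#' @param period_ids Optional period labels.
#' @return A `control_chart` with `chart_type = "u_chart"`, the per-period
#'   table (`period_id`, `n`, `count`, `u`, `lcl`, `ucl`), and rule-1
#'   signals.
#' @export
#' @examples
#' build_u_chart(c(4, 6, 5), c(1000, 1000, 1000))
build_u_chart <- function(counts, denominators = NULL, period_ids = NULL) {
  inp <- chart_inputs(counts, denominators, period_ids)
  if (length(inp$counts) < 2) {
    stop("insufficient-data error: a u-chart needs at least 2 periods",
      call. = FALSE
    )
  }
  ubar <- sum(inp$counts) / sum(inp$denominators)
  half <- 3 * sqrt(ubar / inp$denominators)
  periods <- tibble::tibble(
    period_id = inp$period_ids,
    n = inp$denominators,
    count = inp$counts,
    u = inp$counts / inp$denominators,
    lcl = pmax(0, ubar - half),
    ucl = ubar + half
  )
  new_control_chart("u_chart", ubar, periods, sigma_z = NA_real_)
}

#' Laney sigma_z: moving-range dispersion of the period z-scores
#'
#' Each period's rate is converted to a z-score on the Poisson scale,
#' \eqn{z_i = (u_i - \bar u) / \sqrt{\bar u / n_i}}, and `sigma_z` is the
#' mean absolute moving range of consecutive z-scores divided by 1.128
#' (the unbiasing constant for moving ranges of span 2). Under pure
#' Poisson variation `sigma_z` is about 1; values well above 1 indicate
#' between-period overdispersion.
#'
#' @inheritParams build_u_chart
#' @return `sigma_z` (non-negative), or `NA` when no events occurred at
#'   all (\eqn{\bar u = 0}, z undefined).
#' @export
laney_sigma_z <- function(counts, denominators = NULL, period_ids = NULL) {
  inp <- chart_inputs(counts, denominators, period_ids)
  if (length(inp$counts) < 3) {
    stop("insufficient-data error: sigma_z needs at least 3 periods",
      call. = FALSE
    )
  }
  ubar <- sum(inp$counts) / sum(inp$denominators)
  if (ubar == 0) {
    return(NA_real_)
  }
  u <- inp$counts / inp$denominators
  z <- (u - ubar) / sqrt(ubar / inp$denominators)
  mean(abs(diff(z))) / 1.128
}

#' Laney U' chart: u-chart limits rescaled by sigma_z
#'
#' Identical to [build_u_chart()] except that the limit half-widths are
#' multiplied by `sigma_z`:
#' \eqn{\bar u \pm 3\,\sigma_z \sqrt{\bar u / n_i}} (lower limit floored
#' at zero). With `sigma_z = 1` the chart coincides with the plain
#' u-chart; with overdispersion the limits widen so that common-cause
#' between-period variation is absorbed instead of flagged.
#'
#' @inheritParams build_u_chart
#' @return A `control_chart` with `chart_type = "laney_u_prime"` and
#'   `sigma_z` recorded.
#' @export
build_laney_chart <- function(counts, denominators = NULL, period_ids = NULL) {
  inp <- chart_inputs(counts, denominators, period_ids)
  sigma_z <- laney_sigma_z(inp$counts, inp$denominators, inp$period_ids)
  if (is.na(sigma_z)) {
    stop("undefined: sigma_z has no value when no events occurred",
      call. = FALSE
    )
  }
  ubar <- sum(inp$counts) / sum(inp$denominators)
  half <- 3 * sigma_z * sqrt(ubar / inp$denominators)
  periods <- tibble::tibble(
    period_id = inp$period_ids,
    n = inp$denominators,
    count = inp$counts,
    u = inp$counts / inp$denominators,
    lcl = pmax(0, ubar - half),
    ucl = ubar + half
  )
  new_control_chart("laney_u_prime", ubar, periods, sigma_z = sigma_z)
}

#' Choose between the u-chart and the Laney U' chart
#'
#' Computes `sigma_z` and returns the Laney chart when it exceeds the
#' overdispersion threshold, the plain u-chart otherwise. The threshold
#' (default 1.3) is an explicit, logged tunable: no fixed published
#' cutoff exists for "overdispersed". Underdispersion (`sigma_z < 1`)
#' still selects the plain u-chart, so limits are never shrunk unless
#' [build_laney_chart()] is called deliberately.
#'
#' @inheritParams build_u_chart
#' @param sigma_z_threshold Overdispersion cutoff on `sigma_z`.
#' @return A `control_chart`; its `selection` element records `sigma_z`,
#'   the threshold, and the decision.
#' @export
select_chart <- function(counts, denominators = NULL, period_ids = NULL,
                         sigma_z_threshold = 1.3) {
  inp <- chart_inputs(counts, denominators, period_ids)
  sigma_z <- if (length(inp$counts) >= 3) {
    laney_sigma_z(inp$counts, inp$denominators, inp$period_ids)
  } else {
    NA_real_
  }
  use_laney <- !is.na(sigma_z) && sigma_z > sigma_z_threshold
  chart <- if (use_laney) {
    build_laney_chart(inp$counts, inp$denominators, inp$period_ids)
  } else {
    build_u_chart(inp$counts, inp$denominators, inp$period_ids)
  }
  chart$selection <- list(
    sigma_z = sigma_z,
    sigma_z_threshold = sigma_z_threshold,
    chart_type = chart$chart_type
  )
  chart
}

#' Detect special-cause signals on a fitted chart
#'
#' `rule_1` (a point outside its control limits) is always evaluated.
#' Two run rules can be switched on: `shift` flags every period that
#' completes 8 consecutive points strictly on one side of the center
#' line (points exactly on the center break the run), and `trend` flags
#' every period that completes 6 consecutive strictly monotone points.
#'
#' @param chart A `control_chart`.
#' @param shift_rule,trend_rule Enable the optional run rules.
#' @return A tibble (`period_id`, `rule_id`) ordered by period position.
#' @export
detect_signals <- function(chart, shift_rule = FALSE, trend_rule = FALSE) {
  stopifnot(inherits(chart, "control_chart"))
  p <- chart$periods
  k <- nrow(p)
  hits <- list()

  out_of_limits <- p$u > p$ucl | p$u < p$lcl
  if (any(out_of_limits)) {
    hits[[length(hits) + 1]] <- tibble::tibble(
      pos = which(out_of_limits), rule_id = "rule_1"
    )
  }

  if (shift_rule && k >= 8) {
    side <- sign(p$u - chart$center) # 0 on the center line breaks runs
    run <- integer(k)
    for (i in seq_len(k)) {
      run[i] <- if (side[i] == 0) {
        0L
      } else if (i > 1 && side[i] == side[i - 1]) {
        run[i - 1] + 1L
      } else {
        1L
      }
    }
    at <- which(run >= 8)
    if (length(at) > 0) {
      hits[[length(hits) + 1]] <- tibble::tibble(pos = at, rule_id = "shift")
    }
  }

  if (trend_rule && k >= 6) {
    step <- sign(diff(p$u)) # strict monotone: ties break the trend
    run <- integer(k)
    for (i in 2:k) {
      run[i] <- if (step[i - 1] == 0) {
        0L
      } else if (i > 2 && step[i - 1] == step[i - 2]) {
        run[i - 1] + 1L
      } else {
        1L
      }
    }
    at <- which(run >= 5) # 5 steps = 6 monotone points
    if (length(at) > 0) {
      hits[[length(hits) + 1]] <- tibble::tibble(pos = at, rule_id = "trend")
    }
  }

  if (length(hits) == 0) {
    return(tibble::tibble(period_id = character(), rule_id = character()))
  }
  all_hits <- dplyr::bind_rows(hits)
  all_hits <- all_hits[order(all_hits$pos, all_hits$rule_id), , drop = FALSE]
  tibble::tibble(
    period_id = p$period_id[all_hits$pos],
    rule_id = all_hits$rule_id
  )
}

#' Export a fitted chart as CSV
#'
#' Columns: `period_id`, `u`, `center`, `lcl`, `ucl`, `sigma_z`,
#' `chart_type`, `signal` (semicolon-joined rule ids, blank when none).
#'
#' @param chart A `control_chart`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chart <- function(chart, path) {
  sig <- vapply(chart$periods$period_id, function(pid) {
    paste(chart$signals$rule_id[chart$signals$period_id == pid], collapse = ";")
  }, character(1))
  df <- tibble::tibble(
    period_id = chart$periods$period_id,
    u = chart$periods$u,
    center = chart$center,
    lcl = chart$periods$lcl,
    ucl = chart$periods$ucl,
    sigma_z = chart$sigma_z,
    chart_type = chart$chart_type,
    signal = unname(sig)
  )
  readr::write_csv(df, path, na = "")
  invisible(path)
}
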