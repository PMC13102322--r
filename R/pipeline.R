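# The three governance outputs, as cumulative pipeline stages:
#   level 1 -- monthly organizational dashboard (hospital-wide rates,
#              near-miss-to-harm ratio, selected control chart, signals)
#   level 2 -- unit-level trend cards (stratified denominators, quarterly
#              aggregation where the stability rule fires)
#   level 3 -- quarterly prioritization brief (Near Miss Index, learning
#              yields, classified trend pattern)
# Each run can write its artifact set (CSV/JSON) to a directory; outputs
# are deterministic, with wall-clock metadata isolated in run_meta.json.

#' Level 1: hospital-wide dashboard
#'
#' Builds the hospital-wide near-miss and harm rate series, the
#' per-period near-miss-to-harm ratio, and the selected control chart
#' for the near-miss rate (u-chart, or Laney U' when `sigma_z` exceeds
#' the threshold). With fewer than 2 periods no chart can be fitted and
#' a gap is recorded instead of an error.
#'
#' @param events,exposures,actions Validated collections ([read_events()]
#'   and friends); `actions` is unused at this level and accepted for
#'   interface symmetry.
#' @param sigma_z_threshold Overdispersion cutoff passed to
#'   [select_chart()].
#' @param shift_rule,trend_rule Enable the optional run rules on the
#'   selected chart.
#' @param out_dir Optional directory; when given, writes
#'   `dashboard.csv`, `charts/level1_near_miss.csv`, `run_log.json`,
#'   `run_meta.json`.
#' @return A list (class `nm_level1`) with `dashboard`, `nm_series`,
#'   `harm_series`, `chart`, `signals`, `gaps`, `run_log`.
#' @export
run_level1 <- function(events, exposures, actions = NULL,
                       sigma_z_threshold = 1.3,
                       shift_rule = FALSE, trend_rule = FALSE,
                       out_dir = NULL) {
  gaps <- character()
  nm_series <- build_rate_series(events, exposures,
    scope = "hospital_wide", event_type = "near_miss"
  )
  harm_series <- build_rate_series(events, exposures,
    scope = "hospital_wide", event_type = "harmful_incident"
  )
  dashboard <- tibble::tibble(
    period_id = nm_series$period_id,
    denominator = nm_series$denominator,
    nm_count = nm_series$numerator,
    harm_count = harm_series$numerator,
    nm_rate = nm_series$rate,
    harm_rate = harm_series$rate,
    nm_to_harm_ratio = nm_to_harm_ratio(
      nm_series$numerator, harm_series$numerator
    )
  )

  chart <- NULL
  signals <- tibble::tibble(period_id = character(), rule_id = character())
  if (nrow(nm_series) >= 2) {
    chart <- select_chart(nm_series, sigma_z_threshold = sigma_z_threshold)
    signals <- detect_signals(chart,
      shift_rule = shift_rule, trend_rule = trend_rule
    )
    chart$signals <- signals
  } else {
    gaps <- c(gaps, "control chart not fitted: fewer than 2 periods")
  }

  run_log <- list(
    level = 1,
    periods = nrow(dashboard),
    sigma_z = if (!is.null(chart)) chart$selection$sigma_z else NA,
    sigma_z_threshold = sigma_z_threshold,
    chart_type = if (!is.null(chart)) chart$chart_type else NA,
    n_signals = nrow(signals),
    gaps = gaps
  )
  out <- structure(
    list(
      level = 1, dashboard = dashboard, nm_series = nm_series,
      harm_series = harm_series, chart = chart, signals = signals,
      gaps = gaps, run_log = run_log
    ),
    class = "nm_level1"
  )
  if (!is.null(out_dir)) write_level1(out, out_dir)
  out
}

write_level1 <- function(x, out_dir) {
  dir.create(file.path(out_dir, "charts"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x$dashboard, file.path(out_dir, "dashboard.csv"), na = "")
  if (!is.null(x$chart)) {
    write_chart(x$chart, file.path(out_dir, "charts", "level1_near_miss.csv"))
  }
  write_run_log(x$run_log, out_dir)
  invisible(out_dir)
}

#' Level 2: unit-level trend cards
#'
#' One rate series and chart per unit/domain that has exposure records,
#' scaled by the domain's own denominator convention (e.g. per 10,000
#' doses in pharmacy). Monthly series whose denominators fall below the
#' stability threshold are aggregated to quarters before charting.
#' Charts are per-unit trend cards, never a cross-unit ranking. Domains
#' with events but no exposure records are skipped with an error entry
#' in `gaps`.
#'
#' @inheritParams run_level1
#' @param stability_threshold Minimum monthly denominator below which a
#'   series is quarterly-aggregated ([aggregate_to_quarters()]).
#' @return A list (class `nm_level2`) with `cards` (named per domain:
#'   `series`, `chart`, `aggregated`), `gaps`, `run_log`.
#' @export
run_level2 <- function(events, exposures, actions = NULL,
                       stability_threshold = 500,
                       sigma_z_threshold = 1.3,
                       out_dir = NULL) {
  gaps <- character()
  domains <- intersect(UNIT_DOMAINS, unique(exposures$unit_domain))
  event_domains <- unique(events$unit_domain)
  for (dom in setdiff(intersect(event_domains, UNIT_DOMAINS), domains)) {
    gaps <- c(gaps, sprintf(
      "domain '%s' has events but no exposure records: skipped", dom
    ))
  }

  cards <- list()
  for (dom in domains) {
    series <- build_rate_series(events, exposures,
      scope = dom, event_type = "near_miss"
    )
    aggregated <- FALSE
    if (identical(attr(series, "period_type"), "month")) {
      agg <- aggregate_to_quarters(series, stability_threshold)
      aggregated <- !identical(attr(agg, "period_type"), "month")
      series <- agg
    }
    chart <- if (nrow(series) >= 2) {
      select_chart(series, sigma_z_threshold = sigma_z_threshold)
    } else {
      gaps <- c(gaps, sprintf(
        "domain '%s': control chart not fitted (fewer than 2 periods)", dom
      ))
      NULL
    }
    cards[[dom]] <- list(series = series, chart = chart, aggregated = aggregated)
  }

  run_log <- list(
    level = 2,
    domains = names(cards),
    aggregated = names(cards)[vapply(cards, `[[`, logical(1), "aggregated")],
    stability_threshold = stability_threshold,
    sigma_z_threshold = sigma_z_threshold,
    gaps = gaps
  )
  out <- structure(
    list(level = 2, cards = cards, gaps = gaps, run_log = run_log),
    class = "nm_level2"
  )
  if (!is.null(out_dir)) write_level2(out, out_dir)
  out
}

write_level2 <- function(x, out_dir) {
  card_dir <- file.path(out_dir, "unit_cards")
  dir.create(card_dir, recursive = TRUE, showWarnings = FALSE)
  for (dom in names(x$cards)) {
    write_rate_series(
      x$cards[[dom]]$series, file.path(card_dir, paste0(dom, ".csv"))
    )
    if (!is.null(x$cards[[dom]]$chart)) {
      write_chart(
        x$cards[[dom]]$chart, file.path(card_dir, paste0(dom, "_chart.csv"))
      )
    }
  }
  write_run_log(x$run_log, out_dir, name = "run_log_level2.json")
  invisible(out_dir)
}

#' Level 3: quarterly prioritization brief
#'
#' Runs levels 1 and 2 first (the levels are a cumulative maturity
#' pathway), then computes the severity-weighted Near Miss Index per
#' quarter and overall, the 90- and 180-day learning yields, and --
#' when at least 4 periods are available -- the trend directions of the
#' near-miss rate, harm rate, and total reporting volume, classified
#' through the interpretation matrix. Missing inputs degrade the brief
#' with explicit entries in `gaps` rather than aborting: without an
#' action log the yields are marked unavailable; with a single quarter
#' the trend classification is skipped.
#'
#' @inheritParams run_level2
#' @param weights Severity weight table ([severity_weights()]).
#' @param as_of Evaluation date for the learning-yield windows.
#' @param epsilon Flatness threshold for [trend_direction()].
#' @return A list (class `nm_level3`) with `level1`, `level2`, `nmi`
#'   (overall), `nmi_by_quarter`, `yield_90`, `yield_180`, `assessment`,
#'   `brief` (plain-list summary), `gaps`, `run_log`.
#' @export
run_level3 <- function(events, exposures, actions = NULL,
                       weights = severity_weights(),
                       as_of = NULL,
                       stability_threshold = 500,
                       sigma_z_threshold = 1.3,
                       epsilon = 0.10,
                       out_dir = NULL) {
  level1 <- run_level1(events, exposures,
    sigma_z_threshold = sigma_z_threshold
  )
  gaps <- level1$gaps
  has_unit_exposures <- any(exposures$unit_domain %in% UNIT_DOMAINS)
  level2 <- NULL
  if (has_unit_exposures) {
    level2 <- run_level2(events, exposures,
      stability_threshold = stability_threshold,
      sigma_z_threshold = sigma_z_threshold
    )
  } else {
    gaps <- c(gaps, "no per-domain exposure records: unit cards skipped")
  }

  nm_unscored <- sum(
    events$event_type == "near_miss" & is.na(events$severity_class)
  )
  if (nm_unscored > 0) {
    gaps <- c(gaps, sprintf(
      "%d near miss(es) lack a severity class and are excluded from the index",
      nm_unscored
    ))
  }
  nmi <- compute_nmi(events, weights = weights)
  quarters <- sort(unique(quarter_of(
    events$event_date[events$event_type == "near_miss"]
  )))
  nmi_by_quarter <- lapply(quarters, function(q) {
    compute_nmi(events, weights = weights, period_id = q)
  })
  names(nmi_by_quarter) <- quarters

  yield_90 <- yield_180 <- NULL
  if (!is.null(actions)) {
    yield_90 <- learning_yield_90(events, actions, as_of = as_of)
    yield_180 <- learning_yield_180(actions, as_of = as_of)
  } else {
    gaps <- c(gaps, "no action log supplied: learning yields unavailable")
  }

  assessment <- NULL
  if (nrow(level1$nm_series) >= 4) {
    reporting_series <- build_rate_series(events, exposures,
      scope = "hospital_wide", event_type = "all"
    )
    spc_signal <- any(level1$signals$rule_id == "rule_1")
    assessment <- classify_pattern(
      nm_trend = trend_direction(level1$nm_series, epsilon = epsilon),
      harm_trend = trend_direction(level1$harm_series, epsilon = epsilon),
      reporting_trend = trend_direction(reporting_series, epsilon = epsilon),
      spc_signal_present = spc_signal
    )
  } else {
    gaps <- c(gaps, "fewer than 4 periods: trend classification skipped")
  }

  brief <- list(
    near_miss_rate = sum(level1$nm_series$numerator) /
      sum(level1$nm_series$denominator) *
      attr(level1$nm_series, "scaling_constant"),
    harm_rate = sum(level1$harm_series$numerator) /
      sum(level1$harm_series$denominator) *
      attr(level1$harm_series, "scaling_constant"),
    nm_to_harm_ratio = nm_to_harm_ratio(
      sum(level1$nm_series$numerator), sum(level1$harm_series$numerator)
    ),
    nmi = nmi$value,
    nmi_by_quarter = lapply(nmi_by_quarter, `[[`, "value"),
    yield_90 = if (!is.null(yield_90)) yield_90$value else NA_real_,
    yield_180 = if (!is.null(yield_180)) yield_180$value else NA_real_,
    pattern = if (!is.null(assessment)) assessment$pattern_id else NA_character_,
    gaps = gaps
  )
  run_log <- list(
    level = 3,
    sigma_z = level1$run_log$sigma_z,
    chart_type = level1$run_log$chart_type,
    precedence_trace = if (!is.null(assessment)) assessment$precedence_trace else NULL,
    weights = stats::setNames(as.integer(weights), names(weights)),
    gaps = gaps
  )
  out <- structure(
    list(
      level = 3, level1 = level1, level2 = level2,
      nmi = nmi, nmi_by_quarter = nmi_by_quarter,
      yield_90 = yield_90, yield_180 = yield_180,
      assessment = assessment, brief = brief,
      gaps = gaps, run_log = run_log
    ),
    class = "nm_level3"
  )
  if (!is.null(out_dir)) write_level3(out, out_dir)
  out
}

write_level3 <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_level1(x$level1, out_dir)
  if (!is.null(x$level2)) write_level2(x$level2, out_dir)
  write_nmi_report(
    unname(x$nmi_by_quarter), file.path(out_dir, "nmi_by_quarter.csv")
  )
  yields <- Filter(Negate(is.null), list(x$yield_90, x$yield_180))
  if (length(yields) > 0) {
    write_learning_report(yields, file.path(out_dir, "learning_yields.csv"))
  }
  brief <- x$brief
  if (!is.null(x$assessment)) {
    brief$assessment <- unclass(x$assessment)
  }
  jsonlite::write_json(brief, file.path(out_dir, "brief.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
  )
  write_run_log(x$run_log, out_dir, name = "run_log_level3.json")
  invisible(out_dir)
}

write_run_log <- function(run_log, out_dir, name = "run_log.json") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(run_log, file.path(out_dir, name),
    auto_unbox = TRUE, pretty = TRUE, na = "null"
  )
  # wall-clock metadata kept out of the deterministic artifacts
  jsonlite::write_json(
    list(written_at = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    file.path(out_dir, "run_meta.json"),
    auto_unbox = TRUE
  )
  invisible(out_dir)
}

#' @export
print.nm_level1 <- function(x, ...) {
  cat(sprintf(
    "<level 1 dashboard> %d period(s); chart: %s; %d signal(s)%s\n",
    nrow(x$dashboard),
    if (is.null(x$chart)) "none" else x$chart$chart_type,
    nrow(x$signals),
    if (length(x$gaps)) paste0("; gaps: ", length(x$gaps)) else ""
  ))
  print(x$dashboard, ...)
  invisible(x)
}

#' @export
print.nm_level2 <- function(x, ...) {
  cat(sprintf(
    "<level 2 trend cards> %d domain(s): %s\n",
    length(x$cards), paste(names(x$cards), collapse = ", ")
  ))
  invisible(x)
}

#' @export
print.nm_level3 <- function(x, ...) {
  b <- x$brief
  cat("<level 3 quarterly brief>\n")
  cat(sprintf(
    "  near-miss rate %.3g, harm rate %.3g per %s %s; ratio %s\n",
    b$near_miss_rate, b$harm_rate,
    format(attr(x$level1$nm_series, "scaling_constant"), big.mark = ","),
    attr(x$level1$nm_series, "denominator_type"),
    ifelse(is.na(b$nm_to_harm_ratio), "undefined",
      sprintf("%.3g:1", b$nm_to_harm_ratio)
    )
  ))
  cat(sprintf("  Near Miss Index %g; yield-90 %s; yield-180 %s\n",
    b$nmi,
    ifelse(is.na(b$yield_90), "unavailable", sprintf("%.2f", b$yield_90)),
    ifelse(is.na(b$yield_180), "unavailable", sprintf("%.2f", b$yield_180))
  ))
  if (!is.na(b$pattern)) cat(sprintf("  pattern: %s\n", b$pattern))
  for (g in x$gaps) cat("  gap:", g, "\n")
  invisible(x)
}
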