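# Standardized rates: events per scaling-constant exposure units, the
# reported near-miss-to-harm ratio, and the small-denominator quarterly
# aggregation rule.

#' Standardized event rate
#'
#' The baseline surveillance rate: events divided by exposure, scaled to a
#' conventional reporting unit (per 1000 patient-days hospital-wide; per
#' 10,000 doses in pharmacy; per 1000 specimens/units/procedures elsewhere).
#'
#' @param count Number of events (non-negative).
#' @param exposure Exposure denominator (positive; e.g. patient-days).
#' @param scaling_constant Reporting scale (default 1000).
#' @return `count / exposure * scaling_constant`.
#' @export
#' @examples
#' near_miss_rate(10, 50000) # 0.2 per 1000 patient-days
near_miss_rate <- function(count, exposure, scaling_constant = 1000) {
  if (any(exposure <= 0)) {
    stop("domain error: exposure must be positive", call. = FALSE)
  }
  if (any(count < 0)) {
    stop("domain error: count must be non-negative", call. = FALSE)
  }
  count / exposure * scaling_constant
}

#' Reported near-miss-to-harm ratio
#'
#' Reported near misses divided by reported harmful incidents, a
#' dimensionless gauge of near-miss underreporting (rendered "x:1" in
#' reports). With zero harm events the ratio is undefined and `NA` is
#' returned rather than infinity.
#'
#' @param near_miss_count,harm_count Non-negative counts.
#' @return Numeric ratio, or `NA` when `harm_count` is zero.
#' @export
#' @examples
#' nm_to_harm_ratio(10, 50) # 0.2
nm_to_harm_ratio <- function(near_miss_count, harm_count) {
  if (any(near_miss_count < 0) || any(harm_count < 0)) {
    stop("domain error: counts must be non-negative", call. = FALSE)
  }
  ifelse(harm_count == 0, NA_real_, near_miss_count / harm_count)
}

new_rate_series <- function(entries, scaling_constant, unit_domain,
                            denominator_type, period_type, event_type) {
  entries <- entries[order(entries$period_id), , drop = FALSE]
  stopifnot(all(entries$denominator > 0))
  stopifnot(isTRUE(all.equal(
    entries$rate,
    entries$numerator / entries$denominator * scaling_constant
  )))
  structure(
    entries,
    class = c("rate_series", class(tibble::tibble())),
    scaling_constant = scaling_constant,
    unit_domain = unit_domain,
    denominator_type = denominator_type,
    period_type = period_type,
    event_type = event_type
  )
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf(
    "<rate_series> %s %s per %s %s, %d period(s) (%s)\n",
    attr(x, "unit_domain"), attr(x, "event_type"),
    format(attr(x, "scaling_constant"), big.mark = ","),
    attr(x, "denominator_type"), nrow(x), attr(x, "period_type")
  ))
  print(tibble::as_tibble(x), ...)
}

#' Build a per-period standardized rate series
#'
#' Counts events per exposure period and standardizes by the matching
#' denominators. Periods with exposure but no events get numerator 0,
#' never omission; an event falling in a period without an exposure
#' record is a missing-denominator error (the denominator is part of the
#' surveillance contract, not optional).
#'
#' Scope `"hospital_wide"` counts events from all units against the
#' hospital-wide exposure records; a unit scope counts only that unit's
#' events against its own denominators.
#'
#' @param events Validated event tibble ([read_events()]).
#' @param exposures Validated exposure tibble ([read_exposures()]).
#' @param scope `"hospital_wide"` or one of the unit/domain codes.
#' @param event_type Which event type to count (`"near_miss"`,
#'   `"harmful_incident"`, `"no_harm_incident"`) or `"all"` for total
#'   reporting volume.
#' @param scaling_constant Override of the scale taken from the exposure
#'   records.
#' @return A `rate_series`: a tibble with columns `period_id`,
#'   `numerator`, `denominator`, `rate`, ordered by period, plus
#'   scale/scope metadata attributes.
#' @export
build_rate_series <- function(events, exposures, scope = "hospital_wide",
                              event_type = "near_miss",
                              scaling_constant = NULL) {
  stopifnot(scope %in% EXPOSURE_SCOPES)
  stopifnot(event_type %in% c(EVENT_TYPES, "all"))

  exp_scope <- exposures[exposures$unit_domain == scope, , drop = FALSE]
  if (nrow(exp_scope) == 0) {
    stop("missing-denominator error: no exposure records for scope '",
      scope, "'",
      call. = FALSE
    )
  }
  kinds <- unique(period_kind(exp_scope$period_id))
  if (length(kinds) != 1) {
    stop("format error: mixed monthly and quarterly exposure periods",
      call. = FALSE
    )
  }
  if (anyDuplicated(exp_scope$period_id)) {
    stop("format error: duplicate exposure period '",
      exp_scope$period_id[duplicated(exp_scope$period_id)][1],
      "' for scope '", scope, "'",
      call. = FALSE
    )
  }
  denom_type <- unique(exp_scope$denominator_type)
  if (length(denom_type) != 1) {
    stop("format error: mixed denominator_type within scope '", scope, "'",
      call. = FALSE
    )
  }
  if (is.null(scaling_constant)) {
    scaling_constant <- unique(exp_scope$scaling_constant)
    if (length(scaling_constant) != 1) {
      stop("format error: mixed scaling_constant within scope '", scope, "'",
        call. = FALSE
      )
    }
  }

  ev <- events
  if (scope != "hospital_wide") ev <- ev[ev$unit_domain == scope, , drop = FALSE]
  if (event_type != "all") ev <- ev[ev$event_type == event_type, , drop = FALSE]
  ev_period <- period_of(ev$event_date, kinds)

  orphan <- setdiff(ev_period, exp_scope$period_id)
  if (length(orphan) > 0) {
    stop(
      "missing-denominator error: events in period(s) without an exposure record: ",
      paste(sort(orphan), collapse = ", "),
      call. = FALSE
    )
  }

  counts <- table(factor(ev_period, levels = exp_scope$period_id))
  entries <- tibble::tibble(
    period_id = exp_scope$period_id,
    numerator = as.numeric(counts),
    denominator = exp_scope$exposure_count
  )
  entries$rate <- entries$numerator / entries$denominator * scaling_constant
  new_rate_series(entries, scaling_constant, scope, denom_type, kinds, event_type)
}

#' Aggregate a monthly rate series to quarters when denominators are small
#'
#' Attribute charts are unstable when per-period denominators are small,
#' so low-volume series are re-binned to calendar quarters. The rule is
#' all-or-nothing for a series: if any monthly denominator falls below
#' `stability_threshold`, every month is summed into its calendar quarter
#' (numerators and denominators conserved exactly); otherwise the series
#' is returned unchanged. The threshold is a tunable convention
#' (default 500 exposure units), not an estimate.
#'
#' @param series A monthly `rate_series`.
#' @param stability_threshold Minimum acceptable monthly denominator.
#' @return A `rate_series`, quarterly if the rule fired.
#' @export
aggregate_to_quarters <- function(series, stability_threshold = 500) {
  stopifnot(inherits(series, "rate_series"))
  if (!identical(attr(series, "period_type"), "month")) {
    stop("format error: aggregate_to_quarters expects a monthly series",
      call. = FALSE
    )
  }
  if (all(series$denominator >= stability_threshold)) {
    return(series)
  }
  scaling <- attr(series, "scaling_constant")
  q <- month_to_quarter(series$period_id)
  agg <- stats::aggregate(
    cbind(numerator, denominator) ~ period_id,
    data = data.frame(
      period_id = q,
      numerator = series$numerator,
      denominator = series$denominator
    ),
    FUN = sum
  )
  entries <- tibble::tibble(
    period_id = agg$period_id,
    numerator = agg$numerator,
    denominator = agg$denominator,
    rate = agg$numerator / agg$denominator * scaling
  )
  new_rate_series(
    entries, scaling, attr(series, "unit_domain"),
    attr(series, "denominator_type"), "quarter", attr(series, "event_type")
  )
}

#' Write a rate series as CSV
#'
#' Columns: `period_id`, `scope`, `numerator`, `denominator`,
#' `scaling_constant`, `rate`.
#'
#' @param series A `rate_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_series <- function(series, path) {
  df <- tibble::tibble(
    period_id = series$period_id,
    scope = attr(series, "unit_domain"),
    numerator = series$numerator,
    denominator = series$denominator,
    scaling_constant = attr(series, "scaling_constant"),
    rate = series$rate
  )
  readr::write_csv(df, path, na = "")
  invisible(path)
}
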