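# Organizational learning yields: how often near misses lead to corrective
# action within 90 days, and how often implemented actions are still in
# place at the 180-day mark. Process metrics of the learning loop -- they
# quantify responsiveness and persistence, not whether the actions reduced
# harm.

ACTION_WINDOW_DAYS <- 90L

new_learning_yield <- function(window_label, numerator, denominator,
                               provisional) {
  structure(
    list(
      window_label = window_label,
      numerator = as.integer(numerator),
      denominator = as.integer(denominator),
      value = if (denominator > 0) numerator / denominator else NA_real_,
      provisional = provisional
    ),
    class = "learning_yield"
  )
}

#' @export
print.learning_yield <- function(x, ...) {
  val <- if (is.na(x$value)) "undefined" else sprintf("%.3f", x$value)
  cat(sprintf(
    "<learning_yield> %s: %d/%d = %s%s\n",
    x$window_label, x$numerator, x$denominator, val,
    if (x$provisional) " [provisional: window not yet closed]" else ""
  ))
  invisible(x)
}

#' 90-day learning yield
#'
#' Proportion of near misses that generated at least one corrective
#' action implemented within 90 days of reporting. The clock starts at
#' the action record's `report_date` (the near miss's reporting date);
#' a near miss with several qualifying actions counts once. The
#' denominator is the number of near misses in scope, so the yield
#' reads "share of near misses acted on in time".
#'
#' If `as_of` precedes the latest report date plus 90 days the window is
#' not yet closed and the result is flagged `provisional` rather than
#' suppressed.
#'
#' @param events Validated event tibble; near misses define the scope.
#' @param actions Validated action tibble ([read_actions()]).
#' @param as_of Evaluation date (default: latest date present in the
#'   data).
#' @return A `learning_yield` (window `"day_90"`); `value` is `NA`
#'   (undefined) when there are no near misses in scope.
#' @export
learning_yield_90 <- function(events, actions, as_of = NULL) {
  nm <- events[events$event_type == "near_miss", , drop = FALSE]
  acts <- actions[actions$event_id %in% nm$event_id &
    !is.na(actions$implemented_date), , drop = FALSE]
  in_window <- as.integer(acts$implemented_date - acts$report_date) <= ACTION_WINDOW_DAYS
  numerator <- length(unique(acts$event_id[in_window]))
  denominator <- nrow(nm)

  if (is.null(as_of)) as_of <- latest_date(events, actions)
  provisional <- denominator > 0 && nrow(actions) > 0 &&
    as.Date(as_of) < max(actions$report_date) + ACTION_WINDOW_DAYS
  new_learning_yield("day_90", numerator, denominator, provisional)
}

#' 180-day learning yield (sustainment rate)
#'
#' Proportion of implemented corrective actions still in place at the
#' 180-day mark, verified by objective evidence (a process audit or
#' post-implementation performance data; `sustainment_evidence`
#' other than `"none"`). The denominator is implemented actions, so the
#' yield reads "share of initial fixes that stuck".
#'
#' @param actions Validated action tibble; the `sustained` flag computed
#'   by [read_actions()] defines the numerator.
#' @param as_of Evaluation date (default: latest date present in the
#'   data); a window closing after `as_of` flags the result provisional.
#' @return A `learning_yield` (window `"day_180"`); `value` is `NA`
#'   (undefined) when no action was implemented.
#' @export
learning_yield_180 <- function(actions, as_of = NULL) {
  implemented <- actions[!is.na(actions$implemented_date), , drop = FALSE]
  numerator <- sum(implemented$sustained)
  denominator <- nrow(implemented)

  if (is.null(as_of)) as_of <- latest_date(NULL, actions)
  provisional <- denominator > 0 &&
    as.Date(as_of) < max(implemented$implemented_date) + SUSTAINMENT_DAYS
  new_learning_yield("day_180", numerator, denominator, provisional)
}

latest_date <- function(events, actions) {
  dates <- c(
    if (!is.null(events)) events$event_date,
    if (!is.null(actions)) {
      c(
        actions$report_date, actions$implemented_date,
        actions$sustainment_verified_date
      )
    }
  )
  dates <- dates[!is.na(dates)]
  if (length(dates) == 0) Sys.Date() else max(as.Date(dates, origin = "1970-01-01"))
}

#' Write a learning-yield report as CSV
#'
#' Columns: `scope`, `window`, `numerator`, `denominator`, `value`,
#' `provisional`.
#'
#' @param yields A `learning_yield` or list of them.
#' @param path Output CSV path.
#' @param scope Scope label recorded in the report.
#' @return `path`, invisibly.
#' @export
write_learning_report <- function(yields, path, scope = "hospital_wide") {
  if (inherits(yields, "learning_yield")) yields <- list(yields)
  rows <- lapply(yields, function(x) {
    tibble::tibble(
      scope = scope, window = x$window_label,
      numerator = x$numerator, denominator = x$denominator,
      value = x$value, provisional = x$provisional
    )
  })
  readr::write_csv(dplyr::bind_rows(rows), path, na = "")
  invisible(path)
}
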