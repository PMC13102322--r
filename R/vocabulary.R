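#' Controlled vocabularies for safety-event records
#'
#' The coded fields of an incident record follow the WHO International
#' Classification for Patient Safety / AHRQ Common Formats conventions:
#' a three-way event type, a reached-patient flag, a four-way detection
#' mode, a unit/domain stratifier, and an optional four-point ordinal
#' severity class describing the worst reasonable outcome had the event
#' not been intercepted.
#'
#' All codes are lower-snake-case strings, exactly as they appear in the
#' interchange CSV files.
#'
#' @format Character vectors of allowed codes.
#' @name vocabulary
NULL

#' @rdname vocabulary
#' @export
EVENT_TYPES <- c("near_miss", "no_harm_incident", "harmful_incident")

#' @rdname vocabulary
#' @export
REACHED_PATIENT <- c("yes", "no")

#' @rdname vocabulary
#' @export
DETECTION_MODES <- c("human", "alarm", "patient", "chance")

#' @rdname vocabulary
#' @export
UNIT_DOMAINS <- c(
  "icu", "operating_room", "emergency_department", "pharmacy",
  "laboratory", "transfusion", "ward", "other"
)

#' @rdname vocabulary
#' @export
EXPOSURE_SCOPES <- c(UNIT_DOMAINS, "hospital_wide")

#' @rdname vocabulary
#' @export
DENOMINATOR_TYPES <- c("patient_days", "doses", "specimens", "units", "procedures")

#' @rdname vocabulary
#' @export
SEVERITY_CLASSES <- c("minor", "moderate", "major", "catastrophic")

#' @rdname vocabulary
#' @export
SUSTAINMENT_EVIDENCE <- c("audit", "performance_data", "none")

#' Default scaling constant for a denominator type
#'
#' Rates are expressed per 10,000 doses in pharmacy and per 1000 exposure
#' units everywhere else (patient-days, specimens, transfusion units,
#' procedures). The value can be overridden record-by-record in the
#' exposure file.
#'
#' @param denominator_type Character vector of denominator type codes.
#' @return Integer vector of scaling constants.
#' @export
#' @examples
#' default_scaling_constant(c("patient_days", "doses"))
default_scaling_constant <- function(denominator_type) {
  stopifnot(all(denominator_type %in% DENOMINATOR_TYPES))
  ifelse(denominator_type == "doses", 10000L, 1000L)
}

# ---- period labels ----------------------------------------------------------
# Periods are "YYYY-MM" (month) or "YYYY-Qn" (quarter); both sort lexically.

period_kind <- function(period_id) {
  kind <- rep(NA_character_, length(period_id))
  kind[grepl("^\\d{4}-(0[1-9]|1[0-2])$", period_id)] <- "month"
  kind[grepl("^\\d{4}-Q[1-4]$", period_id)] <- "quarter"
  kind
}

month_of <- function(date) format(as.Date(date), "%Y-%m")

quarter_of <- function(date) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  sprintf("%s-Q%d", format(date, "%Y"), (m - 1L) %/% 3L + 1L)
}

month_to_quarter <- function(period_id) {
  stopifnot(all(period_kind(period_id) == "month"))
  m <- as.integer(substr(period_id, 6, 7))
  sprintf("%s-Q%d", substr(period_id, 1, 4), (m - 1L) %/% 3L + 1L)
}

#' Assign events to reporting periods
#'
#' @param date Vector of event dates (`Date` or parseable strings).
#' @param kind `"month"` or `"quarter"`.
#' @return Character vector of period labels (`"YYYY-MM"` or `"YYYY-Qn"`).
#' @export
period_of <- function(date, kind = c("month", "quarter")) {
  kind <- match.arg(kind)
  if (kind == "month") month_of(date) else quarter_of(date)
}
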