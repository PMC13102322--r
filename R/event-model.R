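# Reading, validating and writing the three interchange files:
# events.csv, exposures.csv, actions.csv.
#
# Validation is total: every input row is either returned (possibly with a
# coerced field) or appears exactly once in the validation report attached
# to the result. In strict mode any quarantined row aborts the read.

EVENT_COLUMNS <- c(
  "event_id", "event_date", "event_type", "reached_patient",
  "detection_mode", "unit_domain", "severity_class"
)
EXPOSURE_COLUMNS <- c(
  "period_id", "unit_domain", "denominator_type", "exposure_count",
  "scaling_constant"
)
ACTION_COLUMNS <- c(
  "action_id", "event_id", "report_date", "implemented_date",
  "sustainment_verified_date", "sustainment_evidence"
)

# Grace period: a sustainment audit may fall up to 7 days short of the
# nominal 180-day mark and still count as verifying sustainment.
SUSTAINMENT_DAYS <- 180L
SUSTAINMENT_GRACE_DAYS <- 7L

new_validation_report <- function() {
  tibble::tibble(
    row = integer(), id = character(), field = character(),
    problem = character(), action = character()
  )
}

add_problem <- function(report, row, id, field, problem, action) {
  dplyr::bind_rows(report, tibble::tibble(
    row = as.integer(row), id = as.character(id), field = field,
    problem = problem, action = action
  ))
}

parse_date_safe <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

read_csv_frame <- function(path, required) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(
      "format error: missing required column(s): ",
      paste(missing, collapse = ", "), call. = FALSE
    )
  }
  df
}

finish_validation <- function(data, report, strict, what) {
  quarantined <- report[report$action == "quarantined", , drop = FALSE]
  if (strict && nrow(quarantined) > 0) {
    stop(
      "validation error in ", what, " (strict mode): ",
      nrow(quarantined), " row(s) failed, first: row ",
      quarantined$row[1], " [", quarantined$field[1], "] ",
      quarantined$problem[1],
      call. = FALSE
    )
  }
  attr(data, "validation") <- report
  data
}

#' Validation report of a read or validated collection
#'
#' Every offending input row appears exactly once, with the field, the
#' problem, and whether the row was quarantined (dropped) or a single
#' field was coerced (row kept).
#'
#' @param x A collection returned by [read_events()], [read_exposures()],
#'   [read_actions()] or their `validate_*` counterparts.
#' @return A tibble with columns `row`, `id`, `field`, `problem`, `action`.
#' @export
validation_report <- function(x) {
  rep <- attr(x, "validation")
  if (is.null(rep)) new_validation_report() else rep
}

# ---- events -----------------------------------------------------------------

#' Read and validate a safety-event log
#'
#' Reads `events.csv` (columns `event_id`, `event_date`, `event_type`,
#' `reached_patient`, `detection_mode`, `unit_domain`, `severity_class`;
#' severity may be blank) and enforces the record invariants:
#' unique `event_id`, ISO dates, controlled vocabulary codes, and the
#' taxonomy rule that a near miss did not reach the patient while a
#' no-harm incident did. Unknown `unit_domain` codes are coerced to
#' `"other"` with a warning so hospital-wide analysis never loses events
#' to stratification vocabulary; every other violation quarantines the row.
#'
#' @param path Path to the CSV file.
#' @param strict If `TRUE`, any quarantined row aborts with an error instead.
#' @return A tibble of accepted events (`event_date` parsed to `Date`,
#'   `severity_class` `NA` when unscored) carrying the validation report
#'   (see [validation_report()]).
#' @seealso [validate_events()] to validate an in-memory frame.
#' @export
read_events <- function(path, strict = FALSE) {
  validate_events(read_csv_frame(path, EVENT_COLUMNS), strict = strict)
}

#' @rdname read_events
#' @param events A data frame with the `events.csv` columns.
#' @export
validate_events <- function(events, strict = FALSE) {
  missing <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing) > 0) {
    stop(
      "format error: missing required column(s): ",
      paste(missing, collapse = ", "), call. = FALSE
    )
  }
  df <- tibble::as_tibble(events)[, EVENT_COLUMNS]
  for (col in EVENT_COLUMNS) df[[col]] <- as.character(df[[col]])
  report <- new_validation_report()
  n <- nrow(df)
  drop <- rep(FALSE, n)

  bad_id <- is.na(df$event_id)
  dup_id <- duplicated(df$event_id) & !bad_id
  date <- parse_date_safe(df$event_date)
  bad_date <- is.na(date)
  bad_type <- !(df$event_type %in% EVENT_TYPES)
  bad_reached <- !(df$reached_patient %in% REACHED_PATIENT)
  bad_mode <- !(df$detection_mode %in% DETECTION_MODES)
  bad_sev <- !is.na(df$severity_class) & !(df$severity_class %in% SEVERITY_CLASSES)
  # taxonomy rule, only meaningful when both codes parsed
  conflict <- !bad_type & !bad_reached & (
    (df$event_type == "near_miss" & df$reached_patient == "yes") |
      (df$event_type == "no_harm_incident" & df$reached_patient == "no")
  )
  unknown_unit <- !is.na(df$unit_domain) & !(df$unit_domain %in% UNIT_DOMAINS)
  missing_unit <- is.na(df$unit_domain)

  for (i in seq_len(n)) {
    id <- df$event_id[i]
    if (bad_id[i]) {
      report <- add_problem(report, i, NA, "event_id", "missing event_id", "quarantined")
      drop[i] <- TRUE
    } else if (dup_id[i]) {
      report <- add_problem(report, i, id, "event_id", "duplicate event_id", "quarantined")
      drop[i] <- TRUE
    } else if (bad_date[i]) {
      report <- add_problem(report, i, id, "event_date", "unparseable date (expected YYYY-MM-DD)", "quarantined")
      drop[i] <- TRUE
    } else if (bad_type[i]) {
      report <- add_problem(report, i, id, "event_type", paste0("unknown code '", df$event_type[i], "'"), "quarantined")
      drop[i] <- TRUE
    } else if (bad_reached[i]) {
      report <- add_problem(report, i, id, "reached_patient", paste0("unknown code '", df$reached_patient[i], "'"), "quarantined")
      drop[i] <- TRUE
    } else if (bad_mode[i]) {
      report <- add_problem(report, i, id, "detection_mode", paste0("unknown code '", df$detection_mode[i], "'"), "quarantined")
      drop[i] <- TRUE
    } else if (bad_sev[i]) {
      report <- add_problem(report, i, id, "severity_class", paste0("unknown code '", df$severity_class[i], "'"), "quarantined")
      drop[i] <- TRUE
    } else if (conflict[i]) {
      report <- add_problem(
        report, i, id, "event_type",
        paste0("taxonomy conflict: ", df$event_type[i], " with reached_patient=", df$reached_patient[i]),
        "quarantined"
      )
      drop[i] <- TRUE
    } else if (missing_unit[i] || unknown_unit[i]) {
      report <- add_problem(
        report, i, id, "unit_domain",
        paste0("unknown unit_domain '", ifelse(missing_unit[i], "", df$unit_domain[i]), "' mapped to 'other'"),
        "coerced"
      )
      df$unit_domain[i] <- "other"
    }
  }
  if (any(report$action == "coerced")) {
    warning(
      sum(report$action == "coerced"),
      " event(s) with unknown unit_domain mapped to 'other'",
      call. = FALSE
    )
  }

  out <- df[!drop, , drop = FALSE]
  out$event_date <- parse_date_safe(out$event_date)
  finish_validation(out, report, strict, "events")
}

#' Write a safety-event log
#'
#' Inverse of [read_events()]; a write-then-read round trip reproduces
#' any valid collection field for field.
#'
#' @param events Tibble of events as returned by [read_events()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- events[, EVENT_COLUMNS]
  df$event_date <- format(as.Date(df$event_date), "%Y-%m-%d")
  readr::write_csv(df, path, na = "")
  invisible(path)
}

# ---- exposures --------------------------------------------------------------

#' Read and validate an exposure (denominator) log
#'
#' Reads `exposures.csv` (columns `period_id`, `unit_domain`,
#' `denominator_type`, `exposure_count`, `scaling_constant`). Blank
#' scaling constants are filled from the denominator type
#' (10,000 for doses, 1000 otherwise; see [default_scaling_constant()]).
#' Denominators are load-bearing, so violations here are errors rather
#' than quarantines: a non-positive `exposure_count`, an unknown
#' `denominator_type`, or a malformed `period_id` aborts the read.
#'
#' @param path Path to the CSV file.
#' @return A tibble of exposure periods with numeric `exposure_count`
#'   and integer `scaling_constant`.
#' @export
read_exposures <- function(path) {
  validate_exposures(read_csv_frame(path, EXPOSURE_COLUMNS))
}

#' @rdname read_exposures
#' @param exposures A data frame with the `exposures.csv` columns.
#' @export
validate_exposures <- function(exposures) {
  missing <- setdiff(EXPOSURE_COLUMNS, names(exposures))
  if (length(missing) > 0) {
    stop(
      "format error: missing required column(s): ",
      paste(missing, collapse = ", "), call. = FALSE
    )
  }
  df <- tibble::as_tibble(exposures)[, EXPOSURE_COLUMNS]
  df$period_id <- as.character(df$period_id)
  df$unit_domain <- as.character(df$unit_domain)
  df$denominator_type <- as.character(df$denominator_type)

  kind <- period_kind(df$period_id)
  if (anyNA(kind)) {
    stop(
      "format error: malformed period_id (expected YYYY-MM or YYYY-Qn): ",
      paste(unique(df$period_id[is.na(kind)]), collapse = ", "),
      call. = FALSE
    )
  }
  bad_dom <- !(df$unit_domain %in% EXPOSURE_SCOPES)
  if (any(bad_dom)) {
    warning(
      "unknown unit_domain in exposures mapped to 'other': ",
      paste(unique(df$unit_domain[bad_dom]), collapse = ", "),
      call. = FALSE
    )
    df$unit_domain[bad_dom] <- "other"
  }
  if (!all(df$denominator_type %in% DENOMINATOR_TYPES)) {
    stop(
      "validation error: unknown denominator_type: ",
      paste(setdiff(unique(df$denominator_type), DENOMINATOR_TYPES), collapse = ", "),
      call. = FALSE
    )
  }
  count <- suppressWarnings(as.numeric(df$exposure_count))
  if (anyNA(count) || any(count <= 0)) {
    bad <- which(is.na(count) | count <= 0)
    stop(
      "validation error: exposure_count must be a positive number (row ",
      paste(bad, collapse = ", "), ")", call. = FALSE
    )
  }
  df$exposure_count <- count
  scaling <- suppressWarnings(as.integer(df$scaling_constant))
  fill <- is.na(scaling)
  scaling[fill] <- default_scaling_constant(df$denominator_type[fill])
  if (any(scaling <= 0)) {
    stop("validation error: scaling_constant must be positive", call. = FALSE)
  }
  df$scaling_constant <- scaling
  df
}

#' Write an exposure log
#'
#' @param exposures Tibble of exposure periods.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exposures <- function(exposures, path) {
  readr::write_csv(exposures[, EXPOSURE_COLUMNS], path, na = "")
  invisible(path)
}

# ---- actions ----------------------------------------------------------------

#' Read and validate a corrective-action log
#'
#' Reads `actions.csv` (columns `action_id`, `event_id`, `report_date`,
#' `implemented_date`, `sustainment_verified_date`,
#' `sustainment_evidence`). Date ordering is enforced:
#' `implemented_date >= report_date`, and a sustainment verification
#' requires an implementation date at least 173 days earlier
#' (the 180-day mark less a 7-day audit-timing grace). A `sustained`
#' logical column is added: verified in time with evidence from an audit
#' or post-implementation performance data (`sustainment_evidence`
#' other than `"none"`).
#'
#' @param path Path to the CSV file.
#' @param strict If `TRUE`, any quarantined row aborts with an error.
#' @param events Optional event collection; action rows whose `event_id`
#'   does not occur there are reported as dangling.
#' @param dangling `"warn"` (default) or `"error"`: how to treat dangling
#'   `event_id` references when `events` is supplied.
#' @return A tibble of accepted actions with parsed dates and the
#'   `sustained` flag, carrying a validation report.
#' @export
read_actions <- function(path, strict = FALSE, events = NULL,
                         dangling = c("warn", "error")) {
  validate_actions(read_csv_frame(path, ACTION_COLUMNS),
    strict = strict, events = events, dangling = dangling
  )
}

#' @rdname read_actions
#' @param actions A data frame with the `actions.csv` columns.
#' @export
validate_actions <- function(actions, strict = FALSE, events = NULL,
                             dangling = c("warn", "error")) {
  dangling <- match.arg(dangling)
  missing <- setdiff(ACTION_COLUMNS, names(actions))
  if (length(missing) > 0) {
    stop(
      "format error: missing required column(s): ",
      paste(missing, collapse = ", "), call. = FALSE
    )
  }
  df <- tibble::as_tibble(actions)[, ACTION_COLUMNS]
  for (col in ACTION_COLUMNS) df[[col]] <- as.character(df[[col]])
  df$sustainment_evidence[is.na(df$sustainment_evidence)] <- "none"

  report <- new_validation_report()
  n <- nrow(df)
  drop <- rep(FALSE, n)

  report_date <- parse_date_safe(df$report_date)
  implemented <- parse_date_safe(df$implemented_date)
  verified <- parse_date_safe(df$sustainment_verified_date)
  dup <- duplicated(df$action_id) & !is.na(df$action_id)
  min_lag <- SUSTAINMENT_DAYS - SUSTAINMENT_GRACE_DAYS

  for (i in seq_len(n)) {
    id <- df$action_id[i]
    if (is.na(id)) {
      report <- add_problem(report, i, NA, "action_id", "missing action_id", "quarantined")
      drop[i] <- TRUE
    } else if (dup[i]) {
      report <- add_problem(report, i, id, "action_id", "duplicate action_id", "quarantined")
      drop[i] <- TRUE
    } else if (is.na(report_date[i])) {
      report <- add_problem(report, i, id, "report_date", "missing or unparseable date", "quarantined")
      drop[i] <- TRUE
    } else if (!is.na(df$implemented_date[i]) && is.na(implemented[i])) {
      report <- add_problem(report, i, id, "implemented_date", "unparseable date", "quarantined")
      drop[i] <- TRUE
    } else if (!is.na(implemented[i]) && implemented[i] < report_date[i]) {
      report <- add_problem(report, i, id, "implemented_date", "implemented_date earlier than report_date", "quarantined")
      drop[i] <- TRUE
    } else if (!is.na(df$sustainment_verified_date[i]) && is.na(verified[i])) {
      report <- add_problem(report, i, id, "sustainment_verified_date", "unparseable date", "quarantined")
      drop[i] <- TRUE
    } else if (!is.na(verified[i]) && is.na(implemented[i])) {
      report <- add_problem(report, i, id, "sustainment_verified_date", "sustainment verified without an implemented_date", "quarantined")
      drop[i] <- TRUE
    } else if (!is.na(verified[i]) &&
      as.integer(verified[i] - implemented[i]) < min_lag) {
      report <- add_problem(
        report, i, id, "sustainment_verified_date",
        sprintf(
          "verification %d days after implementation; %d required (180-day mark, 7-day grace)",
          as.integer(verified[i] - implemented[i]), min_lag
        ),
        "quarantined"
      )
      drop[i] <- TRUE
    } else if (!(df$sustainment_evidence[i] %in% SUSTAINMENT_EVIDENCE)) {
      report <- add_problem(report, i, id, "sustainment_evidence", paste0("unknown code '", df$sustainment_evidence[i], "'"), "quarantined")
      drop[i] <- TRUE
    }
  }

  out <- df[!drop, , drop = FALSE]
  out$report_date <- report_date[!drop]
  out$implemented_date <- implemented[!drop]
  out$sustainment_verified_date <- verified[!drop]
  out$sustained <- !is.na(out$sustainment_verified_date) &
    out$sustainment_evidence != "none"

  if (!is.null(events) && nrow(out) > 0) {
    missing_ref <- !(out$event_id %in% events$event_id)
    if (any(missing_ref)) {
      msg <- paste0(
        "dangling event_id in actions: ",
        paste(unique(out$event_id[missing_ref]), collapse = ", ")
      )
      if (dangling == "error") stop("validation error: ", msg, call. = FALSE)
      warning(msg, call. = FALSE)
    }
  }
  finish_validation(out, report, strict, "actions")
}

#' Write a corrective-action log
#'
#' @param actions Tibble of actions as returned by [read_actions()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_actions <- function(actions, path) {
  df <- actions[, ACTION_COLUMNS]
  for (col in c("report_date", "implemented_date", "sustainment_verified_date")) {
    df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
      format(as.Date(df[[col]]), "%Y-%m-%d")
    )
  }
  readr::write_csv(df, path, na = "")
  invisible(path)
}
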