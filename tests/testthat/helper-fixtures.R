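# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except through temporary files written by the tests
# themselves.

event_row <- function(event_id = "e1", event_date = "2025-01-10",
                      event_type = "near_miss", reached_patient = "no",
                      detection_mode = "human", unit_domain = "pharmacy",
                      severity_class = "minor") {
  tibble::tibble(
    event_id = event_id, event_date = event_date, event_type = event_type,
    reached_patient = reached_patient, detection_mode = detection_mode,
    unit_domain = unit_domain, severity_class = severity_class
  )
}

exposure_row <- function(period_id = "2025-01", unit_domain = "hospital_wide",
                         denominator_type = "patient_days",
                         exposure_count = 1000,
                         scaling_constant = NA_character_) {
  tibble::tibble(
    period_id = period_id, unit_domain = unit_domain,
    denominator_type = denominator_type,
    exposure_count = as.character(exposure_count),
    scaling_constant = scaling_constant
  )
}

action_row <- function(action_id = "a1", event_id = "e1",
                       report_date = "2025-01-10",
                       implemented_date = "2025-03-01",
                       sustainment_verified_date = NA_character_,
                       sustainment_evidence = "none") {
  tibble::tibble(
    action_id = action_id, event_id = event_id, report_date = report_date,
    implemented_date = implemented_date,
    sustainment_verified_date = sustainment_verified_date,
    sustainment_evidence = sustainment_evidence
  )
}

# random scored near-miss sets for the index oracle tests
random_event_set <- function(n) {
  event_row(
    event_id = sprintf("e%03d", seq_len(n)),
    event_date = format(as.Date("2025-01-01") + sample.int(85, n, replace = TRUE),
      "%Y-%m-%d"
    ),
    event_type = sample(c("near_miss", "harmful_incident"), n,
      replace = TRUE, prob = c(0.7, 0.3)
    ),
    reached_patient = "no",
    detection_mode = sample(DETECTION_MODES, n, replace = TRUE),
    unit_domain = sample(UNIT_DOMAINS, n, replace = TRUE),
    severity_class = sample(c(SEVERITY_CLASSES, NA), n, replace = TRUE)
  ) |>
    (\(df) {
      df$reached_patient[df$event_type == "harmful_incident"] <- "yes"
      validate_events(df)
    })()
}

# scores events one at a time and sums: the brute-force index oracle
nmi_oracle <- function(events, weights = severity_weights()) {
  nm <- events[events$event_type == "near_miss", , drop = FALSE]
  total <- 0L
  for (i in seq_len(nrow(nm))) {
    w <- score_event(nm$severity_class[i], weights)
    if (!is.na(w)) total <- total + w
  }
  total
}

# independent quarter-label oracle (string arithmetic only)
month_to_quarter_oracle <- function(pid) {
  paste0(substr(pid, 1, 4), "-Q", ceiling(as.integer(substr(pid, 6, 7)) / 3))
}

# monthly series with random counts/denominators covering whole quarters
random_monthly_series <- function(n_quarters = 4, max_count = 9) {
  months <- format(seq(as.Date("2024-01-01"),
    by = "month",
    length.out = 3 * n_quarters
  ), "%Y-%m")
  entries <- tibble::tibble(
    period_id = months,
    numerator = sample(0:max_count, length(months), replace = TRUE),
    denominator = sample(50:900, length(months), replace = TRUE)
  )
  entries$rate <- entries$numerator / entries$denominator * 1000
  structure(
    entries,
    class = c("rate_series", class(tibble::tibble())),
    scaling_constant = 1000, unit_domain = "transfusion",
    denominator_type = "units", period_type = "month",
    event_type = "near_miss"
  )
}
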