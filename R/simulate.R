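# Seeded synthetic event/exposure/action logs. Monthly near-miss and harm
# counts are Poisson at the configured true rates; overdispersion is
# injected as a gamma multiplier on the latent monthly rate (gamma-Poisson,
# i.e. negative binomial marginally -- the mechanism the Laney adjustment
# exists to absorb), parameterized as the squared coefficient of variation
# of the latent rate. Severities are multinomial; corrective actions are
# Bernoulli per near miss with implementation uniform in (0, 90] days and
# sustainment audits at day 180+.

#' Simulation configuration
#'
#' Defaults mirror the scale of the demonstration scenario: a hospital
#' accumulating 50,000 patient-days per quarter (16,667 per month), a
#' true near-miss reporting rate of 0.2 and a harm rate of 1.0 per 1000
#' patient-days, a severity mix of 0.5/0.3/0.1/0.1 across
#' minor/moderate/major/catastrophic, a 30% chance that a near miss
#' yields an implemented corrective action within 90 days, and a 2/3
#' sustainment probability for implemented actions.
#'
#' @param months Number of monthly periods to simulate.
#' @param exposure_per_month Patient-days per month (single number), or a
#'   named list/vector mapping unit domains to per-month exposures (each
#'   domain then gets its own event stream and exposure records; the
#'   hospital-wide exposure is their sum when all domains use
#'   patient-days).
#' @param true_nm_rate True near-miss rate per 1000 exposure units.
#' @param true_harm_rate True harmful-incident rate per 1000 exposure units.
#' @param dispersion Squared coefficient of variation of the latent
#'   monthly rate; 0 gives pure Poisson counts, larger values give
#'   gamma-Poisson overdispersion.
#' @param severity_mix Probability vector over the four severity classes
#'   (minor, moderate, major, catastrophic), summing to 1.
#' @param p_action_90 Probability a near miss yields an implemented
#'   corrective action within 90 days.
#' @param p_sustain_180 Probability an implemented action is sustained at
#'   the 180-day mark.
#' @param start Calendar month (`Date` or `"YYYY-MM-DD"`) of the first
#'   period.
#' @param seed Integer RNG seed; the generated logs are a pure function
#'   of the configuration including the seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(months = 24,
                       exposure_per_month = 50000 / 3,
                       true_nm_rate = 0.2,
                       true_harm_rate = 1.0,
                       dispersion = 0,
                       severity_mix = c(0.5, 0.3, 0.1, 0.1),
                       p_action_90 = 0.3,
                       p_sustain_180 = 2 / 3,
                       start = "2020-01-01",
                       seed = 1L) {
  cfg <- list(
    months = as.integer(months),
    exposure_per_month = exposure_per_month,
    true_nm_rate = true_nm_rate,
    true_harm_rate = true_harm_rate,
    dispersion = dispersion,
    severity_mix = as.numeric(severity_mix),
    p_action_90 = p_action_90,
    p_sustain_180 = p_sustain_180,
    start = as.Date(start),
    seed = as.integer(seed)
  )
  if (cfg$months < 1) stop("invalid config: months must be >= 1", call. = FALSE)
  exp_vec <- unlist(cfg$exposure_per_month)
  if (any(exp_vec <= 0)) {
    stop("invalid config: exposure_per_month must be positive", call. = FALSE)
  }
  if (length(exp_vec) > 1 && !all(names(exp_vec) %in% UNIT_DOMAINS)) {
    stop("invalid config: per-domain exposures must be named with unit/domain codes",
      call. = FALSE
    )
  }
  if (cfg$true_nm_rate < 0 || cfg$true_harm_rate < 0 || cfg$dispersion < 0) {
    stop("invalid config: rates and dispersion must be non-negative", call. = FALSE)
  }
  if (length(cfg$severity_mix) != 4 ||
    abs(sum(cfg$severity_mix) - 1) > 1e-9 || any(cfg$severity_mix < 0)) {
    stop("invalid config: severity_mix must be 4 non-negative probabilities summing to 1",
      call. = FALSE
    )
  }
  if (cfg$p_action_90 < 0 || cfg$p_action_90 > 1 ||
    cfg$p_sustain_180 < 0 || cfg$p_sustain_180 > 1) {
    stop("invalid config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

month_starts <- function(start, months) {
  seq(as.Date(format(start, "%Y-%m-01")), by = "month", length.out = months)
}

days_in_month <- function(first_day) {
  as.integer(seq(first_day, by = "month", length.out = 2)[2] - first_day)
}

#' Generate synthetic event, exposure and action logs
#'
#' Fully reproducible from the configuration: monthly near-miss and
#' harm counts are drawn Poisson at `rate/1000 * exposure`, with the
#' monthly mean multiplied by a gamma variate (mean 1, variance
#' `dispersion`) when overdispersion is requested. Event dates are
#' uniform within their month; severities are sampled from
#' `severity_mix` for near misses. Each near miss independently yields
#' an implemented corrective action with probability `p_action_90`
#' (implementation lag uniform on 1..90 days), and each implemented
#' action is sustained with probability `p_sustain_180` (audit at
#' 180 + 0..13 days, with audit or performance-data evidence);
#' non-sustained actions keep evidence `"none"`.
#'
#' @param config A [sim_config()].
#' @return A list with validated tibbles `events`, `exposures`,
#'   `actions` in the interchange schemas.
#' @export
#' @examples
#' sim <- generate(sim_config(months = 6, seed = 7))
#' nrow(sim$events)
generate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  exp_map <- unlist(config$exposure_per_month)
  domains <- if (length(exp_map) > 1) names(exp_map) else "ward"
  if (is.null(names(exp_map))) names(exp_map) <- domains

  starts <- month_starts(config$start, config$months)
  period_ids <- month_of(starts)

  events <- list()
  exposures <- list()
  nm_counter <- 0L
  hi_counter <- 0L

  for (dom in domains) {
    exposure <- exp_map[[dom]]
    lam_nm <- config$true_nm_rate / 1000 * exposure
    lam_hi <- config$true_harm_rate / 1000 * exposure
    mult_nm <- gamma_multiplier(config$months, config$dispersion)
    mult_hi <- gamma_multiplier(config$months, config$dispersion)
    n_nm <- stats::rpois(config$months, lam_nm * mult_nm)
    n_hi <- stats::rpois(config$months, lam_hi * mult_hi)

    for (m in seq_len(config$months)) {
      nm <- draw_events(
        n_nm[m], starts[m], "near_miss", "no", dom,
        config$severity_mix,
        prefix = "nm", offset = nm_counter
      )
      nm_counter <- nm_counter + n_nm[m]
      hi <- draw_events(
        n_hi[m], starts[m], "harmful_incident", "yes", dom,
        severity_mix = NULL, prefix = "hi", offset = hi_counter
      )
      hi_counter <- hi_counter + n_hi[m]
      events[[length(events) + 1]] <- rbind(nm, hi)
    }
    exposures[[length(exposures) + 1]] <- tibble::tibble(
      period_id = period_ids,
      unit_domain = if (length(exp_map) > 1) dom else "hospital_wide",
      denominator_type = "patient_days",
      exposure_count = exposure,
      scaling_constant = NA_character_
    )
  }
  events <- dplyr::bind_rows(events)
  events <- events[order(events$event_date, events$event_id), , drop = FALSE]

  if (length(exp_map) > 1) {
    hw <- tibble::tibble(
      period_id = period_ids,
      unit_domain = "hospital_wide",
      denominator_type = "patient_days",
      exposure_count = sum(exp_map),
      scaling_constant = NA_character_
    )
    exposures[[length(exposures) + 1]] <- hw
  }
  exposures <- dplyr::bind_rows(exposures)

  nm_events <- events[events$event_type == "near_miss", , drop = FALSE]
  n_nm_total <- nrow(nm_events)
  acted <- if (n_nm_total > 0) {
    stats::runif(n_nm_total) < config$p_action_90
  } else {
    logical(0)
  }
  acted_events <- nm_events[acted, , drop = FALSE]
  n_act <- nrow(acted_events)
  if (n_act > 0) {
    lag_impl <- sample.int(ACTION_WINDOW_DAYS, n_act, replace = TRUE)
    sustained <- stats::runif(n_act) < config$p_sustain_180
    lag_audit <- SUSTAINMENT_DAYS + sample.int(14, n_act, replace = TRUE) - 1L
    report_date <- as.Date(acted_events$event_date)
    implemented <- report_date + lag_impl
    verified <- implemented + lag_audit
    actions <- tibble::tibble(
      action_id = sprintf("act-%05d", seq_len(n_act)),
      event_id = acted_events$event_id,
      report_date = format(report_date, "%Y-%m-%d"),
      implemented_date = format(implemented, "%Y-%m-%d"),
      sustainment_verified_date = ifelse(sustained,
        format(verified, "%Y-%m-%d"), NA_character_
      ),
      sustainment_evidence = ifelse(sustained,
        sample(c("audit", "performance_data"), n_act, replace = TRUE),
        "none"
      )
    )
  } else {
    actions <- tibble::tibble(
      action_id = character(), event_id = character(),
      report_date = character(), implemented_date = character(),
      sustainment_verified_date = character(),
      sustainment_evidence = character()
    )
  }

  list(
    events = validate_events(events),
    exposures = validate_exposures(exposures),
    actions = validate_actions(actions)
  )
}

gamma_multiplier <- function(n, dispersion) {
  if (dispersion == 0) {
    return(rep(1, n))
  }
  shape <- 1 / dispersion
  stats::rgamma(n, shape = shape, rate = shape) # mean 1, variance = dispersion
}

draw_events <- function(n, month_start, event_type, reached, domain,
                        severity_mix, prefix, offset) {
  if (n == 0) {
    return(NULL)
  }
  ndays <- days_in_month(month_start)
  dates <- month_start + sample.int(ndays, n, replace = TRUE) - 1L
  severity <- if (!is.null(severity_mix)) {
    sample(SEVERITY_CLASSES, n, replace = TRUE, prob = severity_mix)
  } else {
    NA_character_
  }
  tibble::tibble(
    event_id = sprintf("%s-%06d", prefix, offset + seq_len(n)),
    event_date = format(sort(dates), "%Y-%m-%d"),
    event_type = event_type,
    reached_patient = reached,
    detection_mode = sample(DETECTION_MODES, n,
      replace = TRUE,
      prob = c(0.6, 0.2, 0.1, 0.1)
    ),
    unit_domain = domain,
    severity_class = severity
  )
}

#' The deterministic worked-example quarter
#'
#' A single hypothetical quarter with 50,000 patient-days, 50 reported
#' harmful incidents and 10 reported near misses (near-miss rate 0.2 and
#' harm rate 1.0 per 1000 patient-days; near-miss-to-harm ratio 0.2:1).
#' The near misses carry severities 5 minor, 3 moderate, 1 major,
#' 1 catastrophic (severity-weighted index 19 under the default
#' weights), assigned positionally so the fixture is fully
#' deterministic. Three corrective actions are implemented within
#' 90 days of reporting and two are sustained at the 180-day mark
#' (learning yields 3/10 and 2/3). No randomness is involved.
#'
#' @return A list with validated tibbles `events`, `exposures`,
#'   `actions`.
#' @export
#' @examples
#' fx <- worked_example()
#' nrow(fx$events) # 60
worked_example <- function() {
  nm_severity <- rep(SEVERITY_CLASSES, times = c(5, 3, 1, 1))
  nm_dates <- format(as.Date("2025-01-06") + 7 * (0:9), "%Y-%m-%d")
  nm <- tibble::tibble(
    event_id = sprintf("nm-%02d", 1:10),
    event_date = nm_dates,
    event_type = "near_miss",
    reached_patient = "no",
    detection_mode = rep(c("human", "alarm", "human", "patient", "chance"), 2),
    unit_domain = rep(
      c("pharmacy", "icu", "ward", "laboratory", "emergency_department"), 2
    ),
    severity_class = nm_severity
  )
  hi_dates <- format(as.Date("2025-01-02") + ((0:49) * 88) %% 89, "%Y-%m-%d")
  hi <- tibble::tibble(
    event_id = sprintf("hi-%02d", 1:50),
    event_date = sort(hi_dates),
    event_type = "harmful_incident",
    reached_patient = "yes",
    detection_mode = rep(c("human", "human", "alarm", "patient", "human"), 10),
    unit_domain = rep(
      c("ward", "icu", "operating_room", "pharmacy", "emergency_department"), 10
    ),
    severity_class = NA_character_
  )
  exposures <- tibble::tibble(
    period_id = "2025-Q1",
    unit_domain = "hospital_wide",
    denominator_type = "patient_days",
    exposure_count = "50000",
    scaling_constant = NA_character_
  )
  # three actions implemented within 90 days of reporting; the first two
  # verified sustained past the 180-day mark, the third never sustained
  actions <- tibble::tibble(
    action_id = c("act-01", "act-02", "act-03"),
    event_id = c("nm-01", "nm-02", "nm-06"),
    report_date = c("2025-01-06", "2025-01-13", "2025-02-10"),
    implemented_date = c("2025-02-20", "2025-03-10", "2025-04-15"),
    sustainment_verified_date = c("2025-08-25", "2025-09-10", NA),
    sustainment_evidence = c("audit", "performance_data", "none")
  )
  list(
    events = validate_events(rbind(nm, hi)),
    exposures = validate_exposures(exposures),
    actions = validate_actions(actions)
  )
}

#' Write generated logs as the three interchange CSV files
#'
#' @param data A list with `events`, `exposures`, `actions` (as from
#'   [generate()] or [worked_example()]).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_logs <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_events(data$events, file.path(dir, "events.csv"))
  write_exposures(data$exposures, file.path(dir, "exposures.csv"))
  write_actions(data$actions, file.path(dir, "actions.csv"))
  invisible(dir)
}
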