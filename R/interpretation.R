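# The leadership interpretation matrix: a deterministic rule engine that
# maps joint trend directions of near misses, harm, and overall reporting
# volume (plus the presence of special-cause SPC signals) to one of five
# named reporting patterns, each with its diagnostic checks, hedged
# interpretation, and recommended leadership action.

TREND_LEVELS <- c("increasing", "decreasing", "flat")

PATTERN_IDS <- c(
  "interception_improved", "detection_improved", "culture_plus_strain",
  "disengagement_risk", "equilibrium", "unclassified"
)

# Row templates: observed trend, diagnostic checks, possible
# interpretation, leadership action -- emitted verbatim by the engine.
PATTERN_ROWS <- list(
  interception_improved = list(
    observed = "Increasing near misses while harm decreases or remains flat",
    diagnostics = "Stability of denominators and SPC signals",
    interpretation = "Interception and reporting culture have improved",
    action = "Reinforce effective defenses and promote open reporting"
  ),
  detection_improved = list(
    observed = "Increasing near misses while overall reporting remains stable",
    diagnostics = "Clustering in specific domains and detection processes in those areas",
    interpretation = "Detection has improved in selected domains",
    action = "Investigate process precursors and address system vulnerabilities"
  ),
  culture_plus_strain = list(
    observed = "Both near misses and overall reports increase",
    diagnostics = "Harm rates, exposure changes, system vulnerabilities, and SPC variation",
    interpretation = "Reporting culture is improving, but system stress may be rising",
    action = "Review high-consequence clusters using the Near Miss Index, apply corrective actions, and monitor sustainment"
  ),
  disengagement_risk = list(
    observed = "Both near misses and harm decrease",
    diagnostics = "Culture survey trends, reporting volume, and staff engagement data",
    interpretation = "Reporting fatigue or disengagement rather than true safety improvement",
    action = "Conduct targeted culture assessment, reinforce nonpunitive reporting, and verify harm data completeness"
  ),
  equilibrium = list(
    observed = "Both near misses and harm remain flat (no SPC signals)",
    diagnostics = "Denominator stability, process changes, and culture survey trends",
    interpretation = "The system is at equilibrium, or surveillance sensitivity has plateaued",
    action = "Conduct periodic review of detection processes and consider proactive audits to test reporting sensitivity"
  )
)

#' Classify a trend direction from a rate series
#'
#' Default method: the least-squares slope of the rate on the period
#' index. The series is declared `"flat"` when the total fitted change
#' over the window, `|slope| * length`, is below `epsilon` times the
#' series mean (default 10% -- changes smaller than a tenth of the
#' running level are noise for governance purposes); otherwise the sign
#' of the slope decides. The `"spc_runs"` method instead labels the
#' trend by the chart run rules: a shift or trend signal in the window
#' sets the direction of its run, otherwise flat.
#'
#' @param series A `rate_series`, or a numeric vector of per-period
#'   rates (ordered).
#' @param epsilon Relative flatness threshold (default 0.10).
#' @param method `"slope"` (default) or `"spc_runs"`.
#' @return `"increasing"`, `"decreasing"` or `"flat"`.
#' @export
#' @examples
#' trend_direction(c(1, 2, 3, 4)) # "increasing"
trend_direction <- function(series, epsilon = 0.10,
                            method = c("slope", "spc_runs")) {
  method <- match.arg(method)
  x <- if (inherits(series, "rate_series")) series$rate else as.numeric(series)
  n <- length(x)
  if (n < 4) {
    stop("insufficient-data error: trend classification needs at least 4 periods",
      call. = FALSE
    )
  }
  if (method == "spc_runs") {
    chart <- build_u_chart(x, rep(1, n), as.character(seq_len(n)))
    sig <- detect_signals(chart, shift_rule = TRUE, trend_rule = TRUE)
    sig <- sig[sig$rule_id %in% c("shift", "trend"), , drop = FALSE]
    if (nrow(sig) == 0) {
      return("flat")
    }
    last_pos <- max(match(sig$period_id, chart$periods$period_id))
    # direction of the run that fired last
    return(if (x[last_pos] > mean(x)) "increasing" else "decreasing")
  }
  idx <- seq_len(n)
  slope <- stats::cov(idx, x) / stats::var(idx)
  center <- mean(x)
  if (abs(slope) * n < epsilon * center || slope == 0) {
    return("flat")
  }
  if (slope > 0) "increasing" else "decreasing"
}

#' Classify the joint reporting pattern for leadership review
#'
#' A pure function of four inputs: the trend directions of the near-miss
#' rate, the harm rate, and the overall reporting volume, plus whether
#' any special-cause (rule-1) signal is present on the hospital-wide
#' near-miss chart in the window. Rows are checked in a fixed
#' precedence order -- the riskiest misread (disengagement masquerading
#' as improvement) first:
#'
#' 1. near misses and harm both decreasing -> `disengagement_risk`
#' 2. near misses and harm both flat, no SPC signal -> `equilibrium`
#' 3. near misses and overall reporting both increasing -> `culture_plus_strain`
#' 4. near misses increasing, harm decreasing or flat -> `interception_improved`
#' 5. near misses increasing, reporting flat -> `detection_improved`
#'
#' Any other combination is `unclassified` with the full diagnostic
#' checklist attached; in particular a simultaneous rise in near misses
#' and harm that no row claims carries an "investigate harm rise"
#' diagnostic rather than an invented interpretation.
#'
#' @param nm_trend,harm_trend,reporting_trend One of `"increasing"`,
#'   `"decreasing"`, `"flat"`.
#' @param spc_signal_present Logical: any rule-1 signal on the
#'   hospital-wide near-miss chart within the assessment window.
#' @param extra_diagnostics Optional character vector of user-supplied
#'   context checks (culture survey scores, exposure audits) appended to
#'   the diagnostics list; the engine never fabricates them.
#' @return A `trend_assessment`: list with `pattern_id`, `inputs`,
#'   `diagnostics`, `interpretation_text`, `action_text`, and the
#'   `precedence_trace` of rules tested.
#' @export
#' @examples
#' classify_pattern("increasing", "decreasing", "flat", FALSE)
classify_pattern <- function(nm_trend, harm_trend, reporting_trend,
                             spc_signal_present = FALSE,
                             extra_diagnostics = character()) {
  stopifnot(
    nm_trend %in% TREND_LEVELS, harm_trend %in% TREND_LEVELS,
    reporting_trend %in% TREND_LEVELS, is.logical(spc_signal_present)
  )
  trace <- character()
  test <- function(label, cond) {
    trace[[length(trace) + 1]] <<- sprintf(
      "%s: %s", label, if (cond) "match" else "no match"
    )
    cond
  }

  pattern_id <-
    if (test(
      "disengagement_risk (nm and harm both decreasing)",
      nm_trend == "decreasing" && harm_trend == "decreasing"
    )) {
      "disengagement_risk"
    } else if (test(
      "equilibrium (nm and harm both flat, no SPC signal)",
      nm_trend == "flat" && harm_trend == "flat" && !spc_signal_present
    )) {
      "equilibrium"
    } else if (test(
      "culture_plus_strain (nm and reporting both increasing)",
      nm_trend == "increasing" && reporting_trend == "increasing"
    )) {
      "culture_plus_strain"
    } else if (test(
      "interception_improved (nm increasing, harm not increasing)",
      nm_trend == "increasing" && harm_trend %in% c("decreasing", "flat")
    )) {
      "interception_improved"
    } else if (test(
      "detection_improved (nm increasing, reporting flat)",
      nm_trend == "increasing" && reporting_trend == "flat"
    )) {
      "detection_improved"
    } else {
      "unclassified"
    }

  if (pattern_id == "unclassified") {
    diagnostics <- unname(vapply(PATTERN_ROWS, `[[`, character(1), "diagnostics"))
    if (nm_trend == "increasing" && harm_trend == "increasing") {
      diagnostics <- c(diagnostics, "investigate harm rise")
    }
    interpretation <- "Pattern outside the interpretation matrix; review diagnostics jointly"
    action <- "Escalate for case-by-case review with the full diagnostic checklist"
  } else {
    row <- PATTERN_ROWS[[pattern_id]]
    diagnostics <- row$diagnostics
    interpretation <- row$interpretation
    action <- row$action
  }

  structure(
    list(
      pattern_id = pattern_id,
      inputs = list(
        nm_trend = nm_trend, harm_trend = harm_trend,
        reporting_trend = reporting_trend,
        spc_signal_present = spc_signal_present
      ),
      diagnostics = c(diagnostics, extra_diagnostics),
      interpretation_text = interpretation,
      action_text = action,
      precedence_trace = trace
    ),
    class = "trend_assessment"
  )
}

#' @export
print.trend_assessment <- function(x, ...) {
  cat(sprintf(
    "<trend_assessment> %s\n  inputs: nm=%s harm=%s reporting=%s spc_signal=%s\n  interpretation: %s\n  action: %s\n",
    x$pattern_id, x$inputs$nm_trend, x$inputs$harm_trend,
    x$inputs$reporting_trend, x$inputs$spc_signal_present,
    x$interpretation_text, x$action_text
  ))
  invisible(x)
}

#' Serialize a trend assessment to JSON
#'
#' @param assessment A `trend_assessment`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_assessment <- function(assessment, path) {
  jsonlite::write_json(
    unclass(assessment), path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
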