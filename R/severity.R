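# Severity weighting on the four-point ordinal consequence scale
# (worst reasonable outcome had the event not been intercepted) and the
# severity-weighted Near Miss Index.

#' Severity weight table
#'
#' Weights for the four ordinal consequence classes, strictly increasing
#' from minor to catastrophic. The default table is
#' minor = 1, moderate = 2, major = 3, catastrophic = 5 — the reduction
#' of the IHI Severity Assessment Code matrix to its consequence axis.
#'
#' @param minor,moderate,major,catastrophic Positive integer weights,
#'   strictly increasing in that order.
#' @return A named integer vector of class `severity_weights`.
#' @export
#' @examples
#' severity_weights()
#' severity_weights(1, 3, 6, 10)
severity_weights <- function(minor = 1L, moderate = 2L, major = 3L,
                             catastrophic = 5L) {
  w <- c(
    minor = as.integer(minor), moderate = as.integer(moderate),
    major = as.integer(major), catastrophic = as.integer(catastrophic)
  )
  if (anyNA(w) || any(w <= 0)) {
    stop("severity weights must be positive integers", call. = FALSE)
  }
  if (any(diff(w) <= 0)) {
    stop("severity weights must be strictly increasing minor < moderate < major < catastrophic",
      call. = FALSE
    )
  }
  structure(w, class = c("severity_weights", "integer"))
}

#' Score an event's severity
#'
#' Looks up the event's severity class in a weight table. Events without
#' a severity class return `NA` (an unscored marker, never zero) so that
#' unscored events can be reported separately instead of silently
#' deflating an index.
#'
#' @param event A one-or-more-row event tibble (with a `severity_class`
#'   column) or a character vector of severity classes.
#' @param weights A [severity_weights()] table.
#' @return Integer weight(s); `NA` where unscored.
#' @export
#' @examples
#' score_event("catastrophic") # 5
score_event <- function(event, weights = severity_weights()) {
  stopifnot(inherits(weights, "severity_weights"))
  sev <- if (is.data.frame(event)) event$severity_class else as.character(event)
  bad <- !is.na(sev) & !(sev %in% SEVERITY_CLASSES)
  if (any(bad)) {
    stop("unknown severity_class: ", paste(unique(sev[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  unname(weights[sev])
}

#' Severity-weighted Near Miss Index
#'
#' The Near Miss Index (NMI) is the severity-weighted sum over scored
#' events in scope: \eqn{\mathrm{NMI} = \sum_{class} w_{class} \times
#' n_{class}}. By default the scope is near misses only; events lacking
#' a severity class are excluded from the sum and reported in the
#' `unscored` count.
#'
#' @param events Validated event tibble.
#' @param weights A [severity_weights()] table.
#' @param event_type Event type(s) in scope (default `"near_miss"`).
#' @param period_id Optional period label (`"YYYY-MM"` or `"YYYY-Qn"`):
#'   restrict to events whose date falls in that period.
#' @param unit_domain Optional unit/domain filter.
#' @return A `near_miss_index`: list with `value`, `period_id`,
#'   `counts_by_class` (named, all four classes), `unscored`,
#'   `weights`, `n_scored`.
#' @export
#' @examples
#' ev <- worked_example()$events
#' compute_nmi(ev) # value 19
compute_nmi <- function(events, weights = severity_weights(),
                        event_type = "near_miss", period_id = NULL,
                        unit_domain = NULL) {
  stopifnot(inherits(weights, "severity_weights"))
  ev <- events[events$event_type %in% event_type, , drop = FALSE]
  if (!is.null(unit_domain)) {
    ev <- ev[ev$unit_domain %in% unit_domain, , drop = FALSE]
  }
  if (!is.null(period_id)) {
    kind <- period_kind(period_id)
    if (is.na(kind)) stop("malformed period_id: ", period_id, call. = FALSE)
    ev <- ev[period_of(ev$event_date, kind) == period_id, , drop = FALSE]
  }
  counts <- table(factor(ev$severity_class, levels = SEVERITY_CLASSES))
  counts <- stats::setNames(as.integer(counts), SEVERITY_CLASSES)
  unscored <- sum(is.na(ev$severity_class))
  structure(
    list(
      value = sum(as.integer(weights) * counts),
      period_id = if (is.null(period_id)) "all" else period_id,
      counts_by_class = counts,
      unscored = unscored,
      weights = weights,
      n_scored = sum(counts)
    ),
    class = "near_miss_index"
  )
}

#' @export
print.near_miss_index <- function(x, ...) {
  cat(sprintf(
    "<near_miss_index> period %s: NMI = %g over %d scored event(s) (%d unscored)\n",
    x$period_id, x$value, x$n_scored, x$unscored
  ))
  cat("  counts: ", paste(names(x$counts_by_class), x$counts_by_class,
    sep = "=", collapse = ", "
  ), "\n")
  invisible(x)
}

#' Near Miss Index per 1000 exposure units
#'
#' Optional normalization of the raw index for cross-period comparison:
#' raw NMI divided by exposure, times the scaling constant.
#'
#' @param nmi A `near_miss_index`.
#' @param exposure Exposure denominator for the same period (positive).
#' @param scaling_constant Reporting scale (default 1000).
#' @return Numeric normalized index.
#' @export
nmi_per_exposure <- function(nmi, exposure, scaling_constant = 1000) {
  stopifnot(inherits(nmi, "near_miss_index"))
  if (exposure <= 0) stop("domain error: exposure must be positive", call. = FALSE)
  nmi$value / exposure * scaling_constant
}

#' Cohen's kappa for a two-rater severity scoring file
#'
#' Chance-corrected agreement between two raters assigning severity
#' classes to the same events: \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' observed agreement \eqn{p_o} and chance agreement \eqn{p_e} from the
#' raters' marginal class frequencies. Returns `NA` when chance
#' agreement is 1 (both raters constant).
#'
#' @param rater1,rater2 Character vectors of severity classes, same length.
#' @return A list with `kappa`, `observed_agreement`, `n`.
#' @export
severity_kappa <- function(rater1, rater2) {
  stopifnot(length(rater1) == length(rater2))
  ok <- !is.na(rater1) & !is.na(rater2)
  r1 <- factor(rater1[ok], levels = SEVERITY_CLASSES)
  r2 <- factor(rater2[ok], levels = SEVERITY_CLASSES)
  n <- length(r1)
  if (n == 0) {
    return(list(kappa = NA_real_, observed_agreement = NA_real_, n = 0L))
  }
  tab <- table(r1, r2)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  list(kappa = kappa, observed_agreement = po, n = n)
}

#' Write an NMI report row as CSV
#'
#' Columns: `period_id`, `scope`, one column per severity class count,
#' `unscored`, the weights used, and `value`.
#'
#' @param nmi A `near_miss_index` or list of them.
#' @param path Output CSV path.
#' @param scope Scope label recorded in the report.
#' @return `path`, invisibly.
#' @export
write_nmi_report <- function(nmi, path, scope = "hospital_wide") {
  if (inherits(nmi, "near_miss_index")) nmi <- list(nmi)
  rows <- lapply(nmi, function(x) {
    tibble::tibble(
      period_id = x$period_id,
      scope = scope,
      minor = x$counts_by_class[["minor"]],
      moderate = x$counts_by_class[["moderate"]],
      major = x$counts_by_class[["major"]],
      catastrophic = x$counts_by_class[["catastrophic"]],
      unscored = x$unscored,
      weights = paste(names(x$weights), as.integer(x$weights),
        sep = "=", collapse = ";"
      ),
      value = x$value
    )
  })
  readr::write_csv(dplyr::bind_rows(rows), path, na = "")
  invisible(path)
}
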