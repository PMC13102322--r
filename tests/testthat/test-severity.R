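# Severity weighting and the Near Miss Index.

test_that("weight tables enforce strict ordering; scoring looks up or marks unscored", {
  w <- severity_weights()
  expect_equal(unname(as.integer(w)), c(1, 2, 3, 5))
  expect_error(severity_weights(2, 2, 3, 5), "strictly increasing")
  expect_error(severity_weights(0, 1, 2, 3), "positive")

  expect_equal(score_event("catastrophic"), 5L)
  expect_equal(score_event("minor"), 1L)
  expect_true(is.na(score_event(NA_character_))) # unscored marker, not zero
  expect_error(score_event("fatal"), "unknown severity_class")
  # data-frame input scores the severity_class column
  expect_equal(score_event(event_row(severity_class = "major")), 3L)
})

test_that("the index is the weighted class tally, with unscored events set aside", {
  ev <- validate_events(event_row(
    sprintf("e%d", 1:11),
    severity_class = c(rep("minor", 5), rep("moderate", 3), "major",
      "catastrophic", NA
    )
  ))
  nmi <- compute_nmi(ev)
  expect_equal(nmi$value, 19)
  expect_equal(
    nmi$counts_by_class,
    c(minor = 5L, moderate = 3L, major = 1L, catastrophic = 1L)
  )
  expect_equal(nmi$unscored, 1)

  expect_equal(compute_nmi(ev[0, ])$value, 0)
  two_cat <- validate_events(event_row(c("c1", "c2"),
    severity_class = "catastrophic"
  ))
  expect_equal(compute_nmi(two_cat)$value, 10)
  # non-near-miss events are out of scope by default
  harm <- validate_events(event_row("h1",
    event_type = "harmful_incident",
    reached_patient = "yes", severity_class = "major"
  ))
  expect_equal(compute_nmi(dplyr::bind_rows(ev, harm))$value, 19)
})

test_that("index properties: additivity, monotonicity, weight scaling, oracle equality", {
  set.seed(303)
  for (i in 1:30) {
    ev <- random_event_set(sample(5:40, 1))
    expect_equal(compute_nmi(ev)$value, nmi_oracle(ev))

    # additivity over a disjoint split
    half <- sample(nrow(ev), nrow(ev) %/% 2)
    expect_equal(
      compute_nmi(ev[half, ])$value + compute_nmi(ev[-half, ])$value,
      compute_nmi(ev)$value
    )
    # doubling every weight doubles the index
    w2 <- severity_weights(2, 4, 6, 10)
    expect_equal(compute_nmi(ev, w2)$value, 2 * compute_nmi(ev)$value)
  }
  # adding any scored near miss strictly increases the index
  base <- random_event_set(10)
  extra <- validate_events(event_row("zzz", severity_class = "minor"))
  expect_gt(
    compute_nmi(dplyr::bind_rows(base, extra))$value,
    compute_nmi(base)$value
  )
})

test_that("period and domain scoping restrict the tally", {
  ev <- validate_events(dplyr::bind_rows(
    event_row("p1", "2025-01-10", severity_class = "major"),
    event_row("p2", "2025-04-10", severity_class = "minor"),
    event_row("p3", "2025-04-12",
      unit_domain = "icu", severity_class = "moderate"
    )
  ))
  expect_equal(compute_nmi(ev, period_id = "2025-Q1")$value, 3)
  expect_equal(compute_nmi(ev, period_id = "2025-04")$value, 3)
  expect_equal(compute_nmi(ev, unit_domain = "icu")$value, 2)
  expect_equal(nmi_per_exposure(compute_nmi(ev), 50000), 6 / 50000 * 1000)
})

test_that("two-rater kappa has its closed-form values on known tables", {
  # perfect agreement
  r <- rep(SEVERITY_CLASSES, times = c(4, 3, 2, 1))
  expect_equal(severity_kappa(r, r)$kappa, 1)
  # independence-level agreement on a balanced table is ~0
  r1 <- rep(c("minor", "moderate"), each = 10)
  r2 <- rep(c("minor", "moderate"), times = 10)
  expect_equal(severity_kappa(r1, r2)$kappa, 0)
  # both raters constant: chance agreement 1, kappa undefined
  expect_true(is.na(severity_kappa(rep("minor", 5), rep("minor", 5))$kappa))
})
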