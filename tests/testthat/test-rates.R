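# Standardized rates, the near-miss-to-harm ratio, and quarterly
# aggregation.

test_that("rate and ratio formulas evaluate exactly, with typed edge cases", {
  expect_equal(near_miss_rate(10, 50000, 1000), 0.2)
  expect_equal(near_miss_rate(0, 50000, 1000), 0)
  expect_equal(near_miss_rate(5, 20000, 10000), 2.5)
  expect_error(near_miss_rate(5, 0), "domain error")
  expect_error(near_miss_rate(-1, 100), "domain error")

  expect_equal(nm_to_harm_ratio(10, 50), 0.2)
  expect_equal(nm_to_harm_ratio(0, 50), 0)
  expect_true(is.na(nm_to_harm_ratio(7, 0))) # undefined, not Inf
  expect_error(nm_to_harm_ratio(-1, 5), "domain error")
})

test_that("scaling linearity: rate(c, n, k) = k * rate(c, n, 1)", {
  set.seed(101)
  for (i in 1:20) {
    c <- sample(0:50, 1)
    n <- runif(1, 10, 1e5)
    k <- sample(c(1, 100, 1000, 10000), 1)
    expect_equal(near_miss_rate(c, n, k), k * near_miss_rate(c, n, 1))
  }
})

test_that("build_rate_series counts per period with zero-fill, never omission", {
  ev <- validate_events(dplyr::bind_rows(
    event_row("e1", "2025-01-05"),
    event_row("e2", "2025-01-20"),
    event_row("e3", "2025-03-02"),
    event_row("e4", "2025-02-10", event_type = "harmful_incident",
      reached_patient = "yes", severity_class = NA
    )
  ))
  ex <- validate_exposures(exposure_row(
    c("2025-01", "2025-02", "2025-03"),
    exposure_count = c(1000, 800, 1250)
  ))
  s <- build_rate_series(ev, ex)
  expect_s3_class(s, "rate_series")
  expect_equal(s$numerator, c(2, 0, 1))
  expect_equal(s$rate, c(2, 0, 1) / c(1000, 800, 1250) * 1000)
  # single-quarter worked-example shape
  fx <- worked_example()
  q <- build_rate_series(fx$events, fx$exposures)
  expect_equal(nrow(q), 1)
  expect_equal(q$rate, 0.2)
})

test_that("unit-scoped series use the domain's events and denominators", {
  ev <- validate_events(event_row(
    sprintf("i%d", 1:4), "2025-01-10",
    unit_domain = "icu", severity_class = NA
  ))
  ex <- validate_exposures(dplyr::bind_rows(
    exposure_row("2025-01", "icu", exposure_count = 800),
    exposure_row("2025-01", "ward", exposure_count = 5000)
  ))
  s <- build_rate_series(ev, ex, scope = "icu")
  expect_equal(s$rate, 5.0)
  # an event in a period with no exposure record is an error, with the period named
  ev2 <- validate_events(event_row("x1", "2025-04-02", unit_domain = "icu",
    severity_class = NA
  ))
  expect_error(
    build_rate_series(ev2, ex, scope = "icu"),
    "missing-denominator.*2025-04"
  )
  expect_error(
    build_rate_series(ev, ex, scope = "transfusion"),
    "missing-denominator"
  )
})

test_that("quarterly aggregation fires on small denominators and conserves sums", {
  months <- c("2025-01", "2025-02", "2025-03")
  entries <- validate_exposures(exposure_row(months,
    "transfusion", "units",
    exposure_count = c(300, 250, 280)
  ))
  ev <- validate_events(dplyr::bind_rows(
    event_row("t1", "2025-01-15", unit_domain = "transfusion", severity_class = NA),
    event_row("t2", "2025-03-02", unit_domain = "transfusion", severity_class = NA),
    event_row("t3", "2025-03-20", unit_domain = "transfusion", severity_class = NA)
  ))
  s <- build_rate_series(ev, entries, scope = "transfusion")
  agg <- aggregate_to_quarters(s, stability_threshold = 500)
  expect_equal(agg$period_id, "2025-Q1")
  expect_equal(agg$denominator, 830)
  expect_equal(agg$numerator, 3)
  expect_identical(attr(agg, "period_type"), "quarter")

  # no-op branch when every month clears the threshold
  agg2 <- aggregate_to_quarters(s, stability_threshold = 200)
  expect_identical(agg2, s)
  # quarterly input is rejected
  expect_error(aggregate_to_quarters(agg, 500), "monthly")
})

test_that("aggregation conserves totals and weights rates by exposure (random series)", {
  set.seed(202)
  for (i in 1:25) {
    s <- random_monthly_series(n_quarters = sample(2:5, 1))
    agg <- aggregate_to_quarters(s, stability_threshold = 1000) # always fires
    expect_equal(sum(agg$numerator), sum(s$numerator))
    expect_equal(sum(agg$denominator), sum(s$denominator))
    # each quarter's rate equals the exposure-weighted mix of its months
    for (q in agg$period_id) {
      members <- s[month_to_quarter_oracle(s$period_id) == q, ]
      w <- members$denominator / sum(members$denominator)
      expect_equal(
        agg$rate[agg$period_id == q],
        sum(w * members$rate)
      )
    }
  }
})
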