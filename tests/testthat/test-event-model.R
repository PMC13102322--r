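# Reading, validation and round-tripping of the interchange files.

test_that("valid rows are accepted and invariants are enforced row-wise", {
  df <- dplyr::bind_rows(
    event_row("e1"),
    event_row("e2",
      event_type = "near_miss", reached_patient = "yes",
      severity_class = NA
    ),
    event_row("e3",
      event_type = "no_harm_incident", reached_patient = "no",
      severity_class = NA
    ),
    event_row("e4", event_type = "mishap"),
    event_row("e1", event_date = "2025-02-01"), # duplicate id
    event_row("e5", event_date = "10/02/2025"),
    event_row("e6", detection_mode = "robot"),
    event_row("e7", severity_class = "fatal")
  )
  ev <- validate_events(df)
  expect_equal(ev$event_id, c("e1"))
  rep <- validation_report(ev)
  expect_equal(nrow(rep), 7)
  expect_true(all(rep$action == "quarantined"))
  expect_match(
    rep$problem[rep$id == "e2"], "taxonomy conflict"
  )
  expect_match(
    rep$problem[rep$id == "e3"], "taxonomy conflict"
  )
  # validation is total: accepted + quarantined = input rows
  expect_equal(nrow(ev) + nrow(rep), nrow(df))
})

test_that("strict mode aborts on any violation; unknown units are coerced not dropped", {
  df <- dplyr::bind_rows(
    event_row("e1"),
    event_row("e2", event_type = "near_miss", reached_patient = "yes")
  )
  expect_error(validate_events(df, strict = TRUE), "taxonomy conflict")

  odd <- event_row("e9", unit_domain = "helipad")
  expect_warning(ev <- validate_events(odd), "mapped to 'other'")
  expect_equal(ev$unit_domain, "other")
  expect_equal(validation_report(ev)$action, "coerced")
})

test_that("missing columns are a format error, not a validation report entry", {
  df <- event_row("e1")
  df$event_type <- NULL
  expect_error(validate_events(df), "missing required column")
  expect_error(validate_exposures(exposure_row()[, -3]), "missing required column")
  expect_error(validate_actions(action_row()[, -1]), "missing required column")
})

test_that("exposure defaults and invariants follow the denominator conventions", {
  ex <- validate_exposures(dplyr::bind_rows(
    exposure_row("2025-Q1", exposure_count = 50000),
    exposure_row("2025-01", "pharmacy", "doses", 20000),
    exposure_row("2025-01", "laboratory", "specimens", 3000,
      scaling_constant = "100"
    )
  ))
  expect_equal(ex$scaling_constant, c(1000L, 10000L, 100L))
  expect_error(
    validate_exposures(exposure_row(exposure_count = 0)),
    "positive"
  )
  expect_error(
    validate_exposures(exposure_row(period_id = "Q1-2025")),
    "period_id"
  )
  expect_error(
    validate_exposures(exposure_row(denominator_type = "beds")),
    "denominator_type"
  )
})

test_that("action date ordering and the sustainment tolerance are enforced", {
  ok <- validate_actions(dplyr::bind_rows(
    action_row("a1", implemented_date = "2025-03-01"),
    action_row("a2",
      implemented_date = "2025-02-01",
      sustainment_verified_date = "2025-08-01", # 181 days
      sustainment_evidence = "audit"
    ),
    action_row("a3",
      implemented_date = "2025-02-01",
      # 173 days: inside the 7-day grace on the 180-day mark
      sustainment_verified_date = "2025-07-24",
      sustainment_evidence = "performance_data"
    )
  ))
  expect_equal(ok$sustained, c(FALSE, TRUE, TRUE))

  bad <- validate_actions(dplyr::bind_rows(
    action_row("b1", report_date = "2025-01-10", implemented_date = "2025-01-05"),
    action_row("b2",
      implemented_date = "2025-02-01",
      sustainment_verified_date = "2025-07-23", # 172 days: too early
      sustainment_evidence = "audit"
    ),
    action_row("b3",
      implemented_date = NA_character_,
      sustainment_verified_date = "2025-08-01"
    )
  ))
  expect_equal(nrow(bad), 0)
  expect_equal(nrow(validation_report(bad)), 3)

  # verified but with no objective evidence: accepted, not sustained
  none <- validate_actions(action_row("c1",
    implemented_date = "2025-02-01",
    sustainment_verified_date = "2025-09-01",
    sustainment_evidence = "none"
  ))
  expect_false(none$sustained)
})

test_that("dangling action references warn by default and can be escalated", {
  ev <- validate_events(event_row("e1"))
  acts <- action_row("a1", event_id = "ghost")
  expect_warning(validate_actions(acts, events = ev), "dangling")
  expect_error(
    validate_actions(acts, events = ev, dangling = "error"),
    "dangling"
  )
})

test_that("write-then-read round-trips all three collections field for field", {
  sim <- generate(sim_config(months = 4, seed = 9))
  dir <- withr::local_tempdir()
  write_logs(sim, dir)
  ev2 <- read_events(file.path(dir, "events.csv"))
  ex2 <- read_exposures(file.path(dir, "exposures.csv"))
  ac2 <- read_actions(file.path(dir, "actions.csv"))
  expect_equal(nrow(validation_report(ev2)), 0)
  expect_equal(
    as.data.frame(ev2),
    as.data.frame(sim$events),
    ignore_attr = TRUE
  )
  expect_equal(as.data.frame(ex2), as.data.frame(sim$exposures),
    ignore_attr = TRUE
  )
  expect_equal(as.data.frame(ac2), as.data.frame(sim$actions),
    ignore_attr = TRUE
  )
})

test_that("the worked-example fixture loads 60 events with zero quarantines", {
  fx <- worked_example()
  expect_equal(nrow(fx$events), 60)
  expect_equal(sum(fx$events$event_type == "near_miss"), 10)
  expect_equal(sum(fx$events$event_type == "harmful_incident"), 50)
  expect_equal(nrow(validation_report(fx$events)), 0)
  expect_equal(nrow(fx$actions), 3)
  expect_equal(sum(fx$actions$sustained), 2)
})
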