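# Trend direction and the leadership interpretation matrix.

test_that("trend direction: monotone, constant, and near-flat series", {
  expect_equal(trend_direction(c(1, 2, 3, 4)), "increasing")
  expect_equal(trend_direction(c(4, 3, 2, 1)), "decreasing")
  expect_equal(trend_direction(rep(2.5, 5)), "flat")
  expect_equal(trend_direction(c(5.0, 4.9, 5.1, 5.0)), "flat")
  expect_error(trend_direction(c(1, 2, 3)), "insufficient-data")
  # tighter epsilon turns the near-flat series into a trend call
  expect_equal(trend_direction(c(5.0, 4.9, 5.1, 5.2), epsilon = 0.001),
    "increasing"
  )
})

# brute-force re-statement of the row conditions in precedence order,
# written directly from the matrix rather than via the engine
pattern_oracle <- function(nm, harm, rep_, sig) {
  if (nm == "decreasing" && harm == "decreasing") {
    "disengagement_risk"
  } else if (nm == "flat" && harm == "flat" && !sig) {
    "equilibrium"
  } else if (nm == "increasing" && rep_ == "increasing") {
    "culture_plus_strain"
  } else if (nm == "increasing" && harm %in% c("decreasing", "flat")) {
    "interception_improved"
  } else if (nm == "increasing" && rep_ == "flat") {
    "detection_improved"
  } else {
    "unclassified"
  }
}

test_that("the engine is total over all 54 input cells and matches the rule table", {
  grid <- expand.grid(
    nm = c("increasing", "decreasing", "flat"),
    harm = c("increasing", "decreasing", "flat"),
    rep_ = c("increasing", "decreasing", "flat"),
    sig = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  expect_equal(nrow(grid), 54)
  got <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    a <- classify_pattern(grid$nm[i], grid$harm[i], grid$rep_[i], grid$sig[i])
    expect_length(a$pattern_id, 1)
    got[i] <- a$pattern_id
    expect_equal(
      a$pattern_id,
      pattern_oracle(grid$nm[i], grid$harm[i], grid$rep_[i], grid$sig[i])
    )
  }
  # every named pattern is reachable
  expect_setequal(
    unique(got),
    c(
      "interception_improved", "detection_improved", "culture_plus_strain",
      "disengagement_risk", "equilibrium", "unclassified"
    )
  )
})

test_that("determinism: identical inputs give identical assessments", {
  a <- classify_pattern("increasing", "flat", "decreasing", TRUE)
  b <- classify_pattern("increasing", "flat", "decreasing", TRUE)
  expect_identical(a, b)
  expect_error(classify_pattern("rising", "flat", "flat", FALSE))
})

test_that("row templates are emitted verbatim for the matrix rows", {
  a1 <- classify_pattern("increasing", "decreasing", "flat", FALSE)
  expect_equal(a1$pattern_id, "interception_improved")
  expect_equal(
    a1$action_text,
    "Reinforce effective defenses and promote open reporting"
  )
  a4 <- classify_pattern("decreasing", "decreasing", "decreasing", FALSE)
  expect_equal(a4$pattern_id, "disengagement_risk")
  expect_equal(
    a4$interpretation_text,
    "Reporting fatigue or disengagement rather than true safety improvement"
  )
  a5 <- classify_pattern("flat", "flat", "flat", FALSE)
  expect_equal(a5$pattern_id, "equilibrium")
  # a rule-1 signal in the window vetoes equilibrium
  expect_equal(classify_pattern("flat", "flat", "flat", TRUE)$pattern_id,
    "unclassified"
  )
})

test_that("the simultaneous rise in near misses and harm that no row claims is escalated", {
  a <- classify_pattern("increasing", "increasing", "decreasing", FALSE)
  expect_equal(a$pattern_id, "unclassified")
  expect_true("investigate harm rise" %in% a$diagnostics)
  # user-supplied context lands in diagnostics untouched
  b <- classify_pattern("flat", "flat", "flat", FALSE,
    extra_diagnostics = "SAQ teamwork climate 72 (stable)"
  )
  expect_true("SAQ teamwork climate 72 (stable)" %in% b$diagnostics)
})
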