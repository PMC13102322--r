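# u-chart construction, sigma_z estimation, Laney limits, chart
# selection, and run-rule signal detection.

# closed-form limits recomputed with plain arithmetic, independent of
# the chart constructors
u_limits_oracle <- function(counts, n, sigma = 1) {
  ubar <- sum(counts) / sum(n)
  list(
    center = ubar,
    lcl = pmax(0, ubar - 3 * sigma * sqrt(ubar / n)),
    ucl = ubar + 3 * sigma * sqrt(ubar / n)
  )
}

sigma_z_oracle <- function(counts, n) {
  ubar <- sum(counts) / sum(n)
  z <- (counts / n - ubar) / sqrt(ubar / n)
  sum(abs(z[-1] - z[-length(z)])) / (length(z) - 1) / 1.128
}

test_that("u-chart center and limits match the closed form; LCL floors at zero", {
  ch <- build_u_chart(c(4, 6, 5), c(1000, 1000, 1000))
  expect_equal(ch$center, 0.005)
  expect_equal(ch$periods$ucl, rep(0.005 + 3 * sqrt(0.005 / 1000), 3))
  expect_equal(round(ch$periods$ucl[1], 6), 0.011708)
  expect_equal(ch$periods$lcl, rep(0, 3))
  expect_error(build_u_chart(5, 1000), "insufficient-data")

  # degenerate constant series: every point on the center, no signals
  flat <- build_u_chart(rep(7, 6), rep(1400, 6))
  expect_true(all(flat$periods$u == flat$center))
  expect_equal(nrow(flat$signals), 0)

  # a constructed spike beyond the closed-form UCL is flagged
  counts <- c(5, 4, 6, 5, 40)
  n <- rep(1000, 5)
  lim <- u_limits_oracle(counts, n)
  stopifnot(counts[5] / n[5] > lim$ucl[5])
  spike <- build_u_chart(counts, n)
  expect_true("rule_1" %in% spike$signals$rule_id)
  expect_equal(spike$signals$period_id[spike$signals$rule_id == "rule_1"], "5")
})

test_that("sigma_z follows the moving-range definition and its edge cases", {
  set.seed(7)
  counts <- rpois(30, 6)
  n <- runif(30, 500, 2000)
  expect_equal(laney_sigma_z(counts, n), sigma_z_oracle(counts, n))
  # identical z for all periods -> zero moving range
  expect_equal(laney_sigma_z(rep(5, 10), rep(1000, 10)), 0)
  # no events anywhere -> undefined marker
  expect_true(is.na(laney_sigma_z(rep(0, 5), rep(1000, 5))))
  expect_error(laney_sigma_z(c(1, 2), c(10, 10)), "insufficient-data")
})

test_that("Laney limits are the u-chart limits scaled by sigma_z", {
  set.seed(8)
  counts <- rpois(20, 5)
  n <- runif(20, 400, 1500)
  lan <- build_laney_chart(counts, n)
  sz <- laney_sigma_z(counts, n)
  orc <- u_limits_oracle(counts, n, sigma = sz)
  expect_equal(lan$periods$ucl, orc$ucl)
  expect_equal(lan$periods$lcl, orc$lcl)
  expect_equal(lan$sigma_z, sz)
  expect_identical(lan$chart_type, "laney_u_prime")

  # containment: sigma_z > 1 widens strictly, sigma_z < 1 shrinks strictly
  u <- build_u_chart(counts, n)
  if (sz > 1) {
    expect_true(all(lan$periods$ucl > u$periods$ucl))
  } else if (sz < 1) {
    expect_true(all(lan$periods$ucl < u$periods$ucl))
  }
})

test_that("chart selection switches on the sigma_z threshold and logs the decision", {
  set.seed(21)
  n <- rep(1000, 60)
  pois <- rpois(60, 5)
  sel <- select_chart(pois, n, sigma_z_threshold = 1.3)
  expect_identical(sel$chart_type, "u_chart")
  expect_equal(sel$selection$sigma_z, laney_sigma_z(pois, n))

  od <- rpois(60, 5 * rgamma(60, shape = 1, rate = 1))
  sel2 <- select_chart(od, n, sigma_z_threshold = 1.3)
  expect_identical(sel2$chart_type, "laney_u_prime")

  # threshold 0: Laney whenever there is any dispersion at all
  sel3 <- select_chart(pois, n, sigma_z_threshold = 0)
  expect_identical(sel3$chart_type, "laney_u_prime")
})

test_that("run rules fire as defined: shift at the 8th one-sided point, strict trends", {
  # center for counts c(2,2,8,8,...)/1000 sits between the two levels
  counts <- c(2, 2, rep(8, 8))
  ch <- build_u_chart(counts, rep(1000, 10))
  sig <- detect_signals(ch, shift_rule = TRUE)
  shift <- sig[sig$rule_id == "shift", ]
  expect_equal(shift$period_id, "10") # 8th consecutive point above center

  # ties on the center line break runs
  tied <- build_u_chart(c(rep(5, 9), 5), rep(1000, 10))
  expect_equal(nrow(detect_signals(tied, shift_rule = TRUE)), 0)

  # 6 strictly monotone points trigger the trend rule once
  up <- build_u_chart(c(1, 2, 3, 4, 5, 6), rep(1000, 6))
  tr <- detect_signals(up, trend_rule = TRUE)
  expect_true("trend" %in% tr$rule_id)
  expect_equal(tr$period_id[tr$rule_id == "trend"], "6")
  # a tie inside the run resets it
  plateau <- build_u_chart(c(1, 2, 3, 3, 4, 5), rep(1000, 6))
  expect_false("trend" %in% detect_signals(plateau, trend_rule = TRUE)$rule_id)
})

test_that("charts are invariant to period relabeling and reproducible from inputs", {
  set.seed(31)
  counts <- rpois(12, 4)
  n <- runif(12, 300, 900)
  a <- build_u_chart(counts, n, period_ids = sprintf("2024-%02d", 1:12))
  b <- build_u_chart(counts, n, period_ids = letters[1:12])
  expect_equal(a$center, b$center)
  expect_equal(a$periods$ucl, b$periods$ucl)
  expect_equal(a$periods$u, b$periods$u)
  c2 <- build_u_chart(counts, n, period_ids = sprintf("2024-%02d", 1:12))
  expect_identical(a, c2)
})

test_that("false-signal rate under pure Poisson variation stays within 2% (seeded)", {
  set.seed(77)
  counts <- rpois(300, 8)
  ch <- build_u_chart(counts, rep(1000, 300))
  expect_lte(nrow(ch$signals) / 300, 0.02)
})
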