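test_that("index formulas match their definitions", {
  expect_equal(round_half_up(shock_index(112, 80), 1), 1.4)
  expect_equal(shock_index(100, 100), 1)
  expect_equal(shock_index(130, 70), 130 / 70) # ~1.857, unrounded internally

  expect_equal(mean_arterial_pressure(90, 60), 70)
  expect_equal(mean_arterial_pressure(100, 100), 100)
  expect_equal(mean_arterial_pressure(90, 58), (2 * 58 + 90) / 3)

  expect_equal(pulse_pressure(90, 60), 30)
  expect_equal(pulse_pressure(100, 100), 0)
  expect_equal(pulse_pressure(120, 80), 40)

  expect_true(severe_shock_flag(59.9))   # strict inequality at 60
  expect_false(severe_shock_flag(60))
  expect_false(severe_shock_flag(70))
})

test_that("degenerate inputs yield missing values, never errors", {
  expect_true(is.na(shock_index(100, 0)))
  expect_true(is.na(shock_index(NA, 80)))
  expect_true(is.na(shock_index(-5, 80)))
  expect_true(is.na(mean_arterial_pressure(90, NA)))
  expect_true(is.na(mean_arterial_pressure(80, 90)))  # DBP above SBP
  expect_true(is.na(pulse_pressure(NA, 60)))
  expect_true(is.na(severe_shock_flag(NA)))
})

test_that("shock index is invariant under joint scaling of pulse and SBP", {
  p <- c(80, 110, 130); s <- c(120, 90, 70)
  expect_equal(shock_index(2.5 * p, 2.5 * s), shock_index(p, s))
})

test_that("worst-point selection picks the extremal interval under each rule", {
  rec <- make_patient("A", c(0, 15, 30), pulse = c(110, 120, 115),
                      sbp = c(100, 80, 90), dbp = c(70, 55, 60))
  # SI: 1.10, 1.50, 1.278 -> the 15-minute point under every rule here
  for (rule in c("max_si", "max_pulse", "min_sbp", "min_map")) {
    pt <- select_worst_point(rec, rule = rule)
    expect_equal(pt$minutes_from_entry, 15, info = rule)
  }
  pt <- select_worst_point(rec, rule = "max_si")
  expect_equal(pt$si, 1.5)
  expect_equal(pt$map, (2 * 55 + 80) / 3)
  expect_equal(pt$pulse_pressure, 25)
  expect_false(pt$severe_shock)  # MAP 63.3 is above the 60 mmHg bar
})

test_that("singleton series and out-of-window series behave per contract", {
  one <- make_patient("B", 0, pulse = 120, sbp = 80)
  pt <- select_worst_point(one)
  expect_equal(pt$si, 1.5)
  late <- make_patient("C", 75, pulse = 120, sbp = 80)
  pt <- select_worst_point(late, window_minutes = 60)
  expect_true(is.na(pt$si) && is.na(pt$minutes_from_entry))
})

test_that("selected statistic is extremal over the window (enumeration property)", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(2:5, 1)  # keeps the 15-minute grid inside the [0, 60] window
    rec <- make_patient("X", minutes = (seq_len(k) - 1) * 15,
                        pulse = round(runif(k, 90, 140)),
                        sbp = round(runif(k, 60, 110)),
                        dbp = round(runif(k, 40, 58)))
    si <- shock_index(rec$pulse, rec$sbp)
    map <- mean_arterial_pressure(rec$sbp, rec$dbp)
    expect_equal(select_worst_point(rec, rule = "max_si")$si, max(si))
    expect_equal(select_worst_point(rec, rule = "max_pulse")$pulse, max(rec$pulse))
    expect_equal(select_worst_point(rec, rule = "min_sbp")$sbp, min(rec$sbp))
    expect_equal(select_worst_point(rec, rule = "min_map")$map, min(map))
  }
})

test_that("ties break to the earliest time and constant series agree across rules", {
  rec <- make_patient("T", c(0, 15, 30), pulse = c(120, 120, 120),
                      sbp = c(80, 80, 80), dbp = c(50, 50, 50))
  for (rule in c("max_si", "max_pulse", "min_sbp", "min_map"))
    expect_equal(select_worst_point(rec, rule = rule)$minutes_from_entry, 0)
})

test_that("observations missing the rule's fields are skipped, not fatal", {
  rec <- make_patient("M", c(0, 15), pulse = c(NA, 110), sbp = c(90, 95))
  expect_equal(select_worst_point(rec, rule = "max_si")$minutes_from_entry, 15)
  # min_sbp can still use the 0-minute point (sbp present there)
  expect_equal(select_worst_point(rec, rule = "min_sbp")$minutes_from_entry, 0)
})

test_that("derived indices respect dbp <= map <= sbp", {
  co <- generate_cohort(300, seed = 11)
  d <- derive_worst_points(co)
  ok <- !is.na(d$map)
  expect_true(all(d$dbp[ok] <= d$map[ok] & d$map[ok] <= d$sbp[ok]))
})
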