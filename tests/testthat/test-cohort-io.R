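test_that("the bundled synthetic example reads with NP vitals flagged missing", {
  ws <- capture_warnings(
    co <- read_cohort(fixture_path("synthetic_cohort_small.csv")))
  expect_true(any(grepl("non-palpable", ws)))
  expect_s3_class(co, "shock_cohort")
  expect_equal(length(unique(co$patient_id)), 6)
  expect_true(is.na(co$pulse[co$patient_id == "P001" & co$minutes_from_entry == 30]))
  expect_equal(length(attr(co, "np_rows")), 2) # P001 one obs, P005 entry
})

test_that("write_cohort / read_cohort round-trips field-for-field", {
  co <- generate_cohort(40, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(plain_df(back), plain_df(co))
  # missing values preserved
  expect_equal(is.na(back$dbp), is.na(co$dbp))
})

test_that("schema violations are errors, unparseable numerics are warnings", {
  co <- generate_cohort(5, seed = 1)
  path <- tempfile(fileext = ".csv")
  # drop a mandatory column
  df <- as.data.frame(co); df$pulse <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "")
  expect_error(read_cohort(path), "schema error.*pulse")
  # duplicated (patient, time)
  df2 <- as.data.frame(co)[c(1, 1, 2:8), ]
  utils::write.csv(df2, path, row.names = FALSE, na = "")
  expect_error(read_cohort(path), "duplicate")
  # junk numeric
  df3 <- as.data.frame(co); df3$sbp[2] <- "high"
  utils::write.csv(df3, path, row.names = FALSE, na = "")
  expect_warning(b <- read_cohort(path), "unparseable")
  expect_true(is.na(b$sbp[2]))
})

test_that("exclusion rules drop no-outcome and no-vitals records with a log", {
  co <- make_cohort(
    make_patient("ok", c(0, 15), pulse = c(110, 120), sbp = c(90, 85)),
    make_patient("no_vitals", 0, pulse = NA, sbp = NA),
    make_patient("no_outcome", 0, pulse = 115, sbp = 88, died = NA),
    make_patient("late_only", 75, pulse = 115, sbp = 88) # nothing in first hour
  )
  kept <- apply_exclusions(co)
  expect_setequal(unique(kept$patient_id), "ok")
  log <- exclusion_log(kept)
  expect_equal(log$reason[log$patient_id == "no_vitals"], "no_vitals")
  expect_equal(log$reason[log$patient_id == "no_outcome"], "no_outcome")
  expect_equal(log$reason[log$patient_id == "late_only"], "no_vitals")
  # retained + excluded = input
  expect_equal(attr(kept, "n_retained") + nrow(log), attr(kept, "n_input"))
})

test_that("apply_exclusions is idempotent", {
  co <- generate_cohort(50, seed = 9)
  once <- apply_exclusions(co)
  twice <- apply_exclusions(once)
  expect_equal(plain_df(twice), plain_df(once))
  expect_equal(nrow(exclusion_log(twice)), 0)
})

test_that("a 967-record cohort with 1 no-outcome and 8 no-vitals retains 958", {
  good <- generate_cohort(958, seed = 5)
  bad <- do.call(make_cohort, c(
    list(make_patient("X_no_outcome", 0, pulse = 120, sbp = 80, died = NA)),
    lapply(1:8, function(i) make_patient(paste0("X_np_", i), 0,
                                         pulse = NA, sbp = NA))))
  co <- make_cohort(as.data.frame(good), as.data.frame(bad))
  kept <- apply_exclusions(co)
  expect_equal(attr(kept, "n_input"), 967)
  expect_equal(attr(kept, "n_retained"), 958)
  reasons <- table(exclusion_log(kept)$reason)
  expect_equal(unname(reasons["no_outcome"]), 1L)
  expect_equal(unname(reasons["no_vitals"]), 8L)
})

test_that("eligibility combines the EBL threshold with either vital criterion", {
  r <- make_patient("a", 0, pulse = 80, sbp = 90, ebl = 1000)
  expect_true(eligibility_check(r, ebl_threshold_ml = 750))
  r <- make_patient("b", 0, pulse = 90, sbp = 120, ebl = 1000)
  expect_false(eligibility_check(r, ebl_threshold_ml = 750))   # no vital criterion
  r <- make_patient("c", 0, pulse = 120, sbp = 80, ebl = 400)
  expect_false(eligibility_check(r, ebl_threshold_ml = 500))   # EBL below bar
  r <- make_patient("d", 0, pulse = 120, sbp = 80, ebl = NA)
  expect_true(is.na(eligibility_check(r, ebl_threshold_ml = 500))) # indeterminate
})
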