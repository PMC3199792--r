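test_that("daily-smoker classification follows the 30-days rule", {
  expect_identical(classify_daily_smoker(c(30, 0, 0)), "yes")
  expect_identical(classify_daily_smoker(c(29, 29, 29)), "no")
  expect_identical(classify_daily_smoker(c(NA, 12, 0)), "unknown")
  expect_error(classify_daily_smoker(c(31, 0, 0)), "validation")
  expect_error(classify_daily_smoker(c(-1, 0, 0)), "validation")
  expect_error(classify_daily_smoker(c(0, 0)), "three")
})

test_that("classification agrees with enumeration over all month patterns", {
  vals <- c(0, 12, 30, NA)
  grid <- expand.grid(m1 = vals, m2 = vals, m3 = vals)
  for (i in seq_len(nrow(grid))) {
    d <- as.numeric(grid[i, ])
    # independent enumeration of the rule
    expected <- if (sum(d == 30, na.rm = TRUE) > 0) "yes"
                else if (!anyNA(d)) "no" else "unknown"
    expect_identical(classify_daily_smoker(d), expected)
  }
})

test_that("indicator recoding applies the published rules", {
  r <- recode_indicators(cycle_row(1, 1, cig_lifetime = "no",
                                   cigar_freq = "a bit to try"))
  expect_identical(r$ever_smoked, 1L)   # positive response to either item
  r <- recode_indicators(cycle_row(1, 1, father = "no", mother = "no"))
  expect_identical(r$parents_smoke, 0L)
  r <- recode_indicators(cycle_row(1, 1, need = "rarely"))
  expect_identical(r$need_cigarette, 1L)
  r <- recode_indicators(cycle_row(1, 1, friends = "a few"))
  expect_identical(r$friends_smoke, 1L)
  r <- recode_indicators(cycle_row(1, 1, alcohol = "a bit to try"))
  expect_identical(r$alcohol, 1L)
  r <- recode_indicators(cycle_row(1, 1, n_sis = 0L, n_bro = 2L))
  expect_identical(r$siblings_smoke, 1L)
})

test_that("recoded indicators are missing only when inputs cannot decide", {
  row <- cycle_row(1, 1)
  row$cig_lifetime <- NA; row$cigar_freq <- NA
  expect_true(is.na(recode_indicators(row)$ever_smoked))
  row <- cycle_row(1, 1, cig_lifetime = "no"); row$cigar_freq <- NA
  expect_true(is.na(recode_indicators(row)$ever_smoked))  # negative + missing
  row <- cycle_row(1, 1, cigar_freq = "a bit to try"); row$cig_lifetime <- NA
  expect_identical(recode_indicators(row)$ever_smoked, 1L)  # positive decides
  row <- cycle_row(1, 1, father = "yes"); row$mother_smokes <- NA
  expect_identical(recode_indicators(row)$parents_smoke, 1L)
  row <- cycle_row(1, 1); row$father_smokes <- NA
  expect_true(is.na(recode_indicators(row)$parents_smoke))
  expect_error(recode_indicators(cycle_row(1, 1, friends = "loads")),
               "out-of-vocabulary")
})

test_that("wave database matches the hand-enumerated oracle", {
  specs <- list(
    list(id = 1, daily_from = NA),     # never smoker, complete follow-up
    list(id = 2, daily_from = 5),      # boundary cycle: event of wave 1
    list(id = 3, daily_from = 1),      # prevalent daily smoker at entry
    list(id = 4, daily_from = 14),     # event in wave 4 (1y) / wave 2 (2y)
    list(id = 5, daily_from = NA, unknown_at = 3),  # mid-wave loss
    list(id = 6, daily_from = NA, unknown_at = 1)   # unknown at baseline
  )
  co <- hand_cohort(specs)

  db <- build_risk_database(co, "1y", policy = "complete")
  # participant 1: four observations, all Y = 0
  expect_identical(db$Y[db$participant_id == 1], rep(0L, 4))
  # participant 2: Y=1 in wave 1 only, then excluded
  d2 <- db[db$participant_id == 2, ]
  expect_identical(d2$wave, 1L)
  expect_identical(d2$Y, 1L)
  # participant 3 never appears
  expect_false(3 %in% db$participant_id)
  # participant 4: waves 1-3 Y=0, wave 4 Y=1
  d4 <- db[db$participant_id == 4, ]
  expect_identical(d4$Y[order(d4$wave)], c(0L, 0L, 0L, 1L))
  # participant 5: wave 1 dropped under complete-wave policy
  d5 <- db[db$participant_id == 5, ]
  expect_identical(sort(d5$wave), c(2L, 3L, 4L))
  # participant 6: retained at wave 1 with missing outcome
  d6 <- db[db$participant_id == 6 & db$wave == 1L, ]
  expect_identical(nrow(d6), 1L)
  expect_true(is.na(d6$Y))
  # total rows: 4 + 1 + 0 + 4 + 3 + 4 = 16
  expect_identical(nrow(db), 16L)

  # any-observed policy keeps participant 5's wave 1 as Y=0
  db_any <- build_risk_database(co, "1y", policy = "any")
  expect_identical(db_any$Y[db_any$participant_id == 5 & db_any$wave == 1], 0L)

  db2 <- build_risk_database(co, "2y")
  expect_identical(db2$Y[db2$participant_id == 2], 1L)
  d42 <- db2[db2$participant_id == 4, ]
  expect_identical(d42$Y[order(d42$wave)], c(0L, 1L))
})

test_that("cohort shorter than 17 cycles is a build error", {
  co <- hand_cohort(list(list(id = 1, daily_from = NA)), n_cycles = 12L)
  expect_error(build_risk_database(co, "1y"), "17 cycles")
})

test_that("event conservation and exclusion-after-event hold on generated cohorts", {
  co <- generate_cohort(generator_config(n_participants = 400, seed = 42))
  db1 <- build_risk_database(co, "1y")
  first_daily <- attr(co, "truth")$first_daily
  expect_identical(sum(db1$Y), sum(first_daily >= 2 & first_daily <= 17, na.rm = TRUE))
  # no participant appears in a wave after their first Y=1 wave
  ev <- db1[db1$Y == 1, c("participant_id", "wave")]
  for (i in seq_len(nrow(ev))) {
    later <- db1$participant_id == ev$participant_id[i] & db1$wave > ev$wave[i]
    expect_false(any(later))
  }
})

test_that("2-year wave-1 outcome is the OR of the two 1-year outcomes", {
  co <- generate_cohort(generator_config(n_participants = 400, seed = 43))
  db1 <- build_risk_database(co, "1y")
  db2 <- build_risk_database(co, "2y")
  w1 <- db1[db1$wave == 1, c("participant_id", "Y")]
  w2 <- db1[db1$wave == 2, c("participant_id", "Y")]
  both <- merge(w1, w2, by = "participant_id", suffixes = c(".a", ".b"))
  both$or_1y <- pmax(both$Y.a, both$Y.b)
  m <- merge(both, db2[db2$wave == 1, c("participant_id", "Y")],
             by = "participant_id")
  expect_identical(as.integer(m$or_1y), as.integer(m$Y))
})

test_that("risk databases survive a CSV round trip", {
  co <- generate_cohort(generator_config(n_participants = 60, seed = 9))
  db <- build_risk_database(co, "1y")
  f <- withr::local_tempfile(fileext = ".csv")
  write_risk_db_csv(db, f)
  back <- read_risk_db_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(db), ignore_attr = TRUE)
})
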