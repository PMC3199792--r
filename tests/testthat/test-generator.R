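test_that("invalid configurations are rejected", {
  expect_error(generator_config(covariate_prevalences = c(
    need_cigarette = 1.5, parents_smoke = 0.3, siblings_smoke = 0.2,
    friends_smoke = 0.5, alcohol = 0.5, ever_smoked = 0.4, male = 0.5)),
    "configuration error")
  expect_error(generator_config(transition_rates = c(ever_smoked = -0.1,
    alcohol = 0.01, friends_smoke = 0.01, need_cigarette = 0.01)),
    "configuration error")
  expect_error(generator_config(age_at_entry = c("12" = 0.7, "13" = 0.7)),
    "configuration error")
  expect_error(generator_config(covariate_association = -1),
    "configuration error")
})

test_that("generation is deterministic under a fixed seed, to the byte", {
  cfg <- generator_config(n_participants = 120, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(impose_missingness(a, cfg), fa)
  write_cohort_csv(impose_missingness(b, cfg), fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("a degenerate intercept produces no daily smokers", {
  null_truth <- logit_model(-50, setNames(rep(0, 7), indicator_cols),
                            horizon = "1y")
  co <- generate_cohort(generator_config(n_participants = 300, seed = 5,
                                         outcome_coefficients = null_truth))
  expect_true(all(is.na(attr(co, "truth")$first_daily)))
  db <- build_risk_database(co, "1y")
  expect_identical(sum(db$Y), 0L)
})

test_that("wave-1 baseline prevalences match their targets within 3 points", {
  cfg <- generator_config(seed = 12)
  co <- generate_cohort(cfg)
  db <- build_risk_database(co, "1y")
  w1 <- db[db$wave == 1, ]
  targets <- cfg$covariate_prevalences
  for (v in setdiff(names(targets), "male")) {
    expect_lt(abs(mean(w1[[v]]) - targets[[v]]), 0.03,
              label = sprintf("|prevalence(%s) - target|", v))
  }
  expect_lt(abs(mean(db$sex == "male") - targets[["male"]]), 0.03)
})

test_that("absorbing indicators never revert within a participant", {
  co <- generate_cohort(generator_config(n_participants = 200, seed = 21))
  rec <- recode_indicators(co)
  rec$participant_id <- co$participant_id
  rec$cycle <- co$cycle
  rec <- rec[order(rec$participant_id, rec$cycle), ]
  for (v in c("ever_smoked", "alcohol", "friends_smoke")) {
    drops <- tapply(rec[[v]], rec$participant_id, function(x) any(diff(x) < 0))
    expect_false(any(drops), label = sprintf("%s reverts", v))
  }
  # age non-decreasing, cycles in range, recall days within [0,30]
  expect_false(any(tapply(co$age, co$participant_id, is.unsorted)))
  expect_true(all(co$cycle >= 1 & co$cycle <= 20))
  expect_true(all(co$days_smoked_m1 >= 0 & co$days_smoked_m1 <= 30))
})

test_that("independence configuration yields pairwise odds ratios near 1", {
  cfg <- generator_config(seed = 31, covariate_association = 0)
  co <- generate_cohort(cfg)
  w1 <- recode_indicators(co[co$cycle == 1, ])
  vars <- c("need_cigarette", "parents_smoke", "siblings_smoke",
            "friends_smoke", "alcohol", "ever_smoked")
  for (i in 1:(length(vars) - 1)) for (j in (i + 1):length(vars)) {
    a <- vars[i]; b <- vars[j]
    # felt-need is structurally nested within ever-smoked by design
    if (all(c(a, b) %in% c("need_cigarette", "ever_smoked"))) next
    tab <- table(w1[[a]], w1[[b]]) + 0.5   # brute-force 2x2 contingency
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    expect_lt(abs(log(or)), 0.5, label = sprintf("|log OR(%s,%s)|", a, b))
  }
})

test_that("zero missingness rates leave the table untouched", {
  cfg <- generator_config(n_participants = 100, seed = 8)
  cfg$missingness$rates[] <- 0
  co <- generate_cohort(cfg)
  expect_identical(as.data.frame(impose_missingness(co, cfg)),
                   as.data.frame(co))
})

test_that("missingness follows configured rates and spares protected items", {
  cfg <- generator_config(seed = 13)
  co <- generate_cohort(cfg)
  mis <- impose_missingness(co, cfg)
  expect_false(anyNA(mis$sex)); expect_false(anyNA(mis$age))
  expect_false(anyNA(mis$cig_lifetime)); expect_false(anyNA(mis$cigar_freq))
  # mother's education is the most frequently missing item
  fr <- vapply(c("need_cigarette", "father_smokes", "n_sisters_smoke",
                 "friends_smoke", "alcohol_freq", "mothers_education"),
               function(col) mean(is.na(mis[[col]])), numeric(1))
  expect_identical(names(which.max(fr)), "mothers_education")
  # realized rates within the exact binomial 99% interval of the target
  n <- nrow(mis)
  checks <- c(mothers_education = "mothers_education", alcohol = "alcohol_freq")
  for (k in names(checks)) {
    r <- cfg$missingness$rates[[k]]
    ci <- qbinom(c(0.005, 0.995), n, r) / n
    expect_gte(mean(is.na(mis[[checks[[k]]]])), ci[1])
    expect_lte(mean(is.na(mis[[checks[[k]]]])), ci[2])
  }
  # missingness rises as mother's education falls (MAR driver)
  low <- co$mothers_education == "did not finish high school"
  high <- co$mothers_education == "university"
  expect_gt(mean(is.na(mis$alcohol_freq[low])), mean(is.na(mis$alcohol_freq[high])))
})

test_that("cohort tables survive a CSV round trip with empty-field missing values", {
  cfg <- generator_config(n_participants = 50, seed = 3)
  co <- impose_missingness(generate_cohort(cfg), cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- read_cohort_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(co), ignore_attr = TRUE)
})
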