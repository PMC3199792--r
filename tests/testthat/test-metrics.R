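brute_force_c <- function(y, p) {
  # exhaustive O(n^2) pair counting, ties worth one half
  ev <- which(y == 1); ne <- which(y == 0)
  tot <- 0
  for (i in ev) for (j in ne) {
    tot <- tot + (p[i] > p[j]) + 0.5 * (p[i] == p[j])
  }
  tot / (length(ev) * length(ne))
}

test_that("c-statistic equals the brute-force pair-counting oracle", {
  for (s in 1:10) {
    withr::with_seed(s, {
      n <- 200
      y <- rbinom(n, 1, 0.3)
      p <- round(runif(n), 2)   # rounding forces ties
    })
    if (sum(y) %in% c(0, n)) next
    expect_equal(c_statistic(y, p), brute_force_c(y, p), tolerance = 1e-12)
  }
})

test_that("c-statistic endpoints, tie behaviour and invariance hold", {
  expect_equal(c_statistic(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_equal(c_statistic(c(1, 1, 0, 0), c(0.9, 0.9, 0.1, 0.1)), 1)
  expect_error(c_statistic(c(1, 1), c(0.2, 0.3)), "undefined")
  withr::with_seed(4, {
    y <- rbinom(100, 1, 0.2); p <- runif(100)
  })
  expect_equal(c_statistic(y, p), c_statistic(y, plogis(5 * p - 2)))
})

test_that("Hosmer-Lemeshow statistic matches the hand-computed fixture", {
  # four blocks of five observations at p = .1, .2, .3, .4 with
  # 1, 1, 2, 2 observed events: per-block expected events .5, 1, 1.5, 2
  p <- rep(c(0.1, 0.2, 0.3, 0.4), each = 5)
  y <- c(1, 0, 0, 0, 0,  1, 0, 0, 0, 0,  1, 1, 0, 0, 0,  1, 1, 0, 0, 0)
  hl <- hosmer_lemeshow(y, p, g = 4)
  hand <- (1 - 0.5)^2 / 0.5 + (4 - 4.5)^2 / 4.5 +
          (2 - 1.5)^2 / 1.5 + (3 - 3.5)^2 / 3.5
  expect_equal(hl$statistic, hand, tolerance = 1e-12)
  expect_identical(hl$df, 2L)
  expect_equal(hl$p_value, pchisq(hand, 2, lower.tail = FALSE))
})

test_that("Hosmer-Lemeshow is invariant to relabeling within groups", {
  p <- rep(c(0.1, 0.2, 0.3, 0.4), each = 5)
  y1 <- c(1, 0, 0, 0, 0,  1, 0, 0, 0, 0,  1, 1, 0, 0, 0,  1, 1, 0, 0, 0)
  y2 <- c(0, 0, 0, 0, 1,  0, 1, 0, 0, 0,  0, 1, 1, 0, 0,  0, 0, 1, 1, 0)
  expect_equal(hosmer_lemeshow(y1, p, g = 4)$statistic,
               hosmer_lemeshow(y2, p, g = 4)$statistic)
})

test_that("Hosmer-Lemeshow on a well-specified fitted model rejects at the nominal rate", {
  rej <- 0; done <- 0; s <- 0
  while (done < 120) {
    s <- s + 1
    db <- sim_risk_db(600, seed = 700 + s)
    m <- tryCatch(fit_logistic(db), error = function(e) NULL)
    if (is.null(m)) next   # rare separated draw: no MLE to calibrate
    done <- done + 1
    hl <- suppressWarnings(hosmer_lemeshow(db$Y, predict_risk(m, db)))
    rej <- rej + (hl$p_value < 0.05)
  }
  expect_lt(rej / done, 0.12)   # ~5% nominal with Monte-Carlo slack
})

test_that("maximum-rescaled R2 hits its endpoints and matches a reference fit", {
  expect_equal(max_rescaled_r2(-100, -100, 200), 0)
  n <- 50; ll0 <- n * (0.3 * log(0.3) + 0.7 * log(0.7))
  expect_equal(max_rescaled_r2(ll0, 0, n), 1)   # saturated fit
  expect_error(max_rescaled_r2(-10, -20, 100), "cannot fall below")
  expect_error(max_rescaled_r2(-10, -5, 0), "positive")

  db <- sim_risk_db(400, seed = 17)
  m <- fit_logistic(db)
  ref <- glm(Y ~ age + need_cigarette + parents_smoke + siblings_smoke +
               friends_smoke + alcohol + ever_smoked,
             data = db, family = binomial())
  ref0 <- glm(Y ~ 1, data = db, family = binomial())
  r2_ref <- (1 - exp(2 * (as.numeric(logLik(ref0)) - as.numeric(logLik(ref))) / 400)) /
            (1 - exp(2 * as.numeric(logLik(ref0)) / 400))
  expect_equal(max_rescaled_r2(m$meta$loglik_null, m$meta$loglik, 400),
               r2_ref, tolerance = 1e-8)
})

test_that("informativeness ratio spans its range and matches its identity", {
  y <- c(rep(1, 3), rep(0, 7))
  expect_equal(informativeness_ratio(rep(0.3, 10), y), 0)
  expect_equal(informativeness_ratio(y, y), 1)
  expect_error(informativeness_ratio(rep(0.5, 4), rep(1, 4)), "undefined")
  expect_warning(
    r <- informativeness_ratio(c(0.99, 0.01, 0.99, 0.01, 0.5, 0.5),
                               c(1, 0, 0, 0, 0, 0)), "clipping")
  expect_equal(r, 1)
  withr::with_seed(5, { p <- runif(300, 0, 0.4); y <- rbinom(300, 1, p) })
  ybar <- mean(y)
  expect_equal(informativeness_ratio(p, y),
               mean((p - mean(p))^2) / (ybar * (1 - ybar)), tolerance = 1e-12)
})

test_that("risk-category table matches a hand-enumerated fixture", {
  p <- c(0.01, 0.015, 0.03, 0.04, 0.08, 0.09, 0.15, 0.18, 0.30, 0.50)
  y <- c(0,    0,     0,    1,    0,    1,    0,    1,    1,    1)
  tab <- risk_category_table(y, p)
  expect_equal(tab$pct_of_sample, rep(20, 5))
  expect_equal(tab$observed_risk, c(0, 50, 50, 50, 100))
  expect_equal(tab$mean_predicted_risk,
               100 * c(0.0125, 0.035, 0.085, 0.165, 0.40))
  expect_equal(sum(tab$pct_of_sample), 100)
})

test_that("a homogeneous low-risk sample lands in the lowest stratum only", {
  tab <- risk_category_table(rep(c(1, rep(0, 99)), 1), rep(0.01, 100))
  expect_equal(tab$pct_of_sample, c(100, 0, 0, 0, 0))
  expect_equal(tab$observed_risk[1], 1)
})

test_that("the calibrated pipeline's strata bracket their observed risks", {
  co <- generate_cohort(generator_config(seed = 19))
  db <- build_risk_database(co, "1y")
  m <- fit_logistic(db)
  tab <- risk_category_table(db$Y, predict_risk(m, db))
  bounds <- list(c(0, 2), c(2, 5), c(5, 10), c(10, 20), c(20, 100))
  inside <- vapply(seq_len(5), function(i)
    !is.na(tab$observed_risk[i]) &&
      tab$observed_risk[i] >= bounds[[i]][1] - 1e-9 &&
      tab$observed_risk[i] <= bounds[[i]][2] + 1e-9, logical(1))
  expect_gte(sum(inside), 4)
})
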