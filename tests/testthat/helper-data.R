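# Shared fixtures, built in code.

# One raw cohort-table row with every item at its negative default.
cycle_row <- function(id, cycle, age = 12 + (cycle - 1) / 4, days = c(0, 0, 0),
                      cig_lifetime = "no", cigar_freq = "never",
                      need = "never", father = "no", mother = "no",
                      n_sis = 0L, n_bro = 0L, friends = "none",
                      alcohol = "never", edu = "university", sex = "female") {
  data.frame(
    participant_id = id, cycle = cycle, age = age, sex = sex,
    days_smoked_m1 = days[1], days_smoked_m2 = days[2], days_smoked_m3 = days[3],
    cigs_per_day_m1 = ifelse(days[1] > 0, 5L, 0L),
    cigs_per_day_m2 = ifelse(days[2] > 0, 5L, 0L),
    cigs_per_day_m3 = ifelse(days[3] > 0, 5L, 0L),
    cig_lifetime = cig_lifetime, cigar_freq = cigar_freq,
    need_cigarette = need, father_smokes = father, mother_smokes = mother,
    n_sisters_smoke = n_sis, n_brothers_smoke = n_bro,
    friends_smoke = friends, alcohol_freq = alcohol,
    mothers_education = edu, stringsAsFactors = FALSE
  )
}

# Build a cohort table from a list of per-participant specifications.
# daily_from: first cycle at which the recall shows 30 days (NA = never);
# unknown_at: cycles whose recall is blanked (status unknown).
hand_cohort <- function(specs, n_cycles = 17L) {
  rows <- list()
  for (sp in specs) {
    for (cyc in seq_len(n_cycles)) {
      daily <- !is.na(sp$daily_from) && cyc >= sp$daily_from
      r <- cycle_row(sp$id, cyc,
                     days = if (daily) c(30, 30, 30) else c(0, 0, 0),
                     cig_lifetime = if (daily) "yes, more than 10 times" else "no")
      if (!is.null(sp$unknown_at) && cyc %in% sp$unknown_at) {
        r$days_smoked_m1 <- r$days_smoked_m2 <- r$days_smoked_m3 <- NA
      }
      rows[[length(rows) + 1L]] <- r
    }
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

# Fast direct simulation of a complete risk-set database from a logit model,
# bypassing the cohort generator: covariates drawn with realistic marginals
# and a latent factor, outcomes Bernoulli at the model's predicted risk.
sim_risk_db <- function(n, model = published_models()$model_1y, seed = 1,
                        assoc = 1) {
  withr::with_seed(seed, {
    z <- rnorm(n)
    pr <- function(p, lam) plogis(qlogis(p) + assoc * lam * z)
    ever <- rbinom(n, 1, pr(0.45, 1.3))
    need <- ever * rbinom(n, 1, pr(0.40, 1.6))
    db <- data.frame(
      participant_id = seq_len(n), wave = 1L, horizon = model$horizon,
      age = sample(c(12, 13, 14, 15, 16), n, replace = TRUE,
                   prob = c(.2, .25, .25, .2, .1)),
      need_cigarette = need,
      parents_smoke = rbinom(n, 1, pr(0.295, 0.4)),
      siblings_smoke = rbinom(n, 1, pr(0.176, 0.5)),
      friends_smoke = rbinom(n, 1, pr(0.55, 1.0)),
      alcohol = rbinom(n, 1, pr(0.50, 0.8)),
      ever_smoked = ever,
      sex = sample(c("male", "female"), n, replace = TRUE),
      mothers_education = sample(
        c("did not finish high school", "high school graduate",
          "vocational or technical school", "CEGEP", "university"),
        n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    db$Y <- rbinom(n, 1, predict_risk(model, db))
    attr(db, "horizon") <- model$horizon
    class(db) <- c("risk_db", "data.frame")
    db
  })
}

indicator_cols <- c("age", "need_cigarette", "parents_smoke", "siblings_smoke",
                    "friends_smoke", "alcohol", "ever_smoked")
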