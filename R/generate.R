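# Synthetic longitudinal cohort generator.
#
# Emulates a school cohort of ~1293 adolescents aged 12-13 at entry followed
# over 20 quarterly questionnaire cycles: raw smoking-recall items, household
# and peer smoking items, alcohol use, mother's education, and initiation of
# daily smoking generated wave-by-wave from a configured logistic truth
# equation.  Indicator clustering is induced by a single latent propensity
# factor per participant.

.vocab <- list(
  cig_lifetime = c("no", "yes, 1 or 2 times", "yes, 3 or 4 times",
                   "yes, 5-10 times", "yes, more than 10 times"),
  freq5 = c("never", "a bit to try", "once or a couple of times a month",
            "once or a couple of times a week", "every day"),
  need = c("never", "rarely", "sometimes", "often"),
  friends = c("none", "a few", "about half", "more than half", "most or all"),
  yesno = c("no", "yes"),
  education = c("did not finish high school", "high school graduate",
                "vocational or technical school", "CEGEP", "university")
)

.bin_items <- c("need_cigarette", "parents_smoke", "siblings_smoke",
                "friends_smoke", "alcohol", "ever_smoked")

#' Configuration of the synthetic cohort generator
#'
#' The defaults encode the study conditions the package emulates: 1293
#' participants entering at age 12-13, 20 quarterly cycles, wave-1 indicator
#' prevalences matching the pooled baseline characteristics of the 1-year
#' analytic database, the published 1-year equation as the data-generating
#' outcome model, absorbing onset dynamics for ever-smoked, alcohol, friends
#' and felt-need, and item missingness patterned on mother's education.
#'
#' @param n_participants Number of participants (default 1293).
#' @param n_cycles Number of quarterly cycles (default 20).
#' @param age_at_entry Probabilities of entry ages 12 and 13 (named vector).
#' @param covariate_prevalences Wave-1 baseline prevalence targets of the six
#'   binary indicators plus `male`.
#' @param covariate_association Scalar >= 0 multiplying the latent-factor
#'   loadings; 0 gives mutually independent indicators.
#' @param outcome_coefficients A [logit_model()] used as the data-generating
#'   truth for per-wave initiation of daily smoking (default: the published
#'   1-year equation).
#' @param transition_rates Per-cycle onset probabilities (at latent factor 0)
#'   for the absorbing indicators; `need_cigarette` applies only to current
#'   ever-smokers.
#' @param missingness List with `rates` (marginal per-item blanking
#'   probabilities; `daily_recall` blanks the six recall fields jointly) and
#'   `education_multipliers` (relative rates across the five mother's
#'   education strata, low to high education).
#' @param education_probs Distribution of mother's education (5 levels).
#' @param seed Master seed; all stages draw from documented substreams.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_participants = 1293,
    n_cycles = 20,
    age_at_entry = c("12" = 0.5, "13" = 0.5),
    covariate_prevalences = c(
      need_cigarette = 0.155, parents_smoke = 0.295, siblings_smoke = 0.176,
      friends_smoke = 0.530, alcohol = 0.481, ever_smoked = 0.406,
      male = 0.494
    ),
    covariate_association = 1,
    outcome_coefficients = published_models()$model_1y,
    transition_rates = c(ever_smoked = 0.012, alcohol = 0.014,
                         friends_smoke = 0.010, need_cigarette = 0.034),
    missingness = list(
      rates = c(need_cigarette = 0.010, parents_smoke = 0.027,
                siblings_smoke = 0.045, friends_smoke = 0.008,
                alcohol = 0.016, mothers_education = 0.160,
                daily_recall = 0.003),
      education_multipliers = c(1.5, 1.1, 1.0, 0.9, 0.7)
    ),
    education_probs = c(0.14, 0.26, 0.20, 0.17, 0.23),
    seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_cycles = as.integer(n_cycles),
    age_at_entry = age_at_entry,
    covariate_prevalences = covariate_prevalences,
    covariate_association = covariate_association,
    outcome_coefficients = outcome_coefficients,
    transition_rates = transition_rates,
    missingness = missingness,
    education_probs = education_probs,
    seed = seed
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_participants < 1L) stop("configuration error: n_participants must be >= 1")
  if (cfg$n_cycles < 1L) stop("configuration error: n_cycles must be >= 1")
  pv <- cfg$covariate_prevalences
  if (!all(c(.bin_items, "male") %in% names(pv)))
    stop("configuration error: covariate_prevalences must name the six indicators and 'male'")
  if (!is_prob(pv)) stop("configuration error: prevalences must lie in [0,1]")
  if (!is_prob(cfg$age_at_entry) || abs(sum(cfg$age_at_entry) - 1) > 1e-8)
    stop("configuration error: age_at_entry must be a probability distribution")
  if (!is_prob(cfg$transition_rates))
    stop("configuration error: transition rates must lie in [0,1]")
  if (!is_prob(cfg$missingness$rates))
    stop("configuration error: missingness rates must lie in [0,1]")
  if (!is_prob(cfg$education_probs) || abs(sum(cfg$education_probs) - 1) > 1e-8)
    stop("configuration error: education_probs must be a probability distribution")
  if (!is.numeric(cfg$covariate_association) || cfg$covariate_association < 0)
    stop("configuration error: covariate_association must be >= 0")
  stopifnot(inherits(cfg$outcome_coefficients, "logit_model"))
  invisible(cfg)
}

# Latent-factor loadings per indicator (multiplied by covariate_association).
# Smoking-proximal indicators load most strongly; calibrated jointly with the
# transition rates so the pooled risk, c-statistic and informativeness of the
# built database land on the study conditions.
.loadings <- c(need_cigarette = 1.60, parents_smoke = 0.40,
               siblings_smoke = 0.50, friends_smoke = 1.00,
               alcohol = 0.80, ever_smoked = 1.30)

# Solve the intercept a such that E_z[ plogis(a + lambda*z) * w(z) ] equals
# `target`, where z is standard normal and w(z) an optional weight in [0,1]
# (used for indicators defined conditionally, e.g. felt-need among
# ever-smokers).  Quadrature over a fine grid.
.solve_marginal <- function(target, lambda, weight = NULL) {
  z <- seq(-6, 6, length.out = 801)
  w <- stats::dnorm(z); w <- w / sum(w)
  wt <- if (is.null(weight)) rep(1, length(z)) else weight(z)
  cap <- sum(w * wt)
  if (target >= cap) return(Inf)     # weight cannot support the marginal
  if (target <= 0) return(-Inf)
  f <- function(a) sum(w * wt * plogis(a + lambda * z)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Generate a complete synthetic cohort
#'
#' Simulates participant-level latent propensities, baseline indicators,
#' absorbing onset transitions, and wave-wise initiation of daily smoking
#' from the configured truth equation; emits one row of raw questionnaire
#' items per participant-cycle with no missing values.  Onset of daily
#' smoking within a wave is drawn with probability `P = 1/(1+exp(-L))` from
#' the indicator values at the wave's baseline cycle, and the first daily
#' cycle is placed uniformly within the wave; once daily, always daily.
#'
#' @param config A [generator_config()].
#' @return A `cohort_table`: data frame with one row per participant-cycle
#'   and the raw item columns, plus attributes `config` and `truth` (per
#'   participant-cycle latent indicator states and first daily cycle).
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  n <- config$n_participants
  K <- config$n_cycles
  pv <- config$covariate_prevalences
  lam <- .loadings * config$covariate_association

  with_seed(substream_seed(config$seed, "cohort"), {
    z <- rnorm(n)

    sex <- ifelse(runif(n) < pv[["male"]], "male", "female")
    entry_age <- as.numeric(sample(names(config$age_at_entry), n,
                                   replace = TRUE, prob = config$age_at_entry))
    edu <- sample(.vocab$education, n, replace = TRUE,
                  prob = config$education_probs)

    # Time-constant household structure.
    a_par <- .solve_marginal(pv[["parents_smoke"]], lam[["parents_smoke"]])
    parents <- rbinom(n, 1, plogis(a_par + lam[["parents_smoke"]] * z))
    both <- runif(n) < 0.35
    fpick <- runif(n) < 0.55
    father <- as.integer(parents == 1L & (both | fpick))
    mother <- as.integer(parents == 1L & (both | !fpick))
    a_sib <- .solve_marginal(pv[["siblings_smoke"]], lam[["siblings_smoke"]])
    sibs <- rbinom(n, 1, plogis(a_sib + lam[["siblings_smoke"]] * z))
    n_sis <- integer(n); n_bro <- integer(n)
    sis_first <- runif(n) < 0.5
    n_sis[sibs == 1 & sis_first] <- 1L + rbinom(sum(sibs == 1 & sis_first), 1, 0.15)
    n_bro[sibs == 1 & !sis_first] <- 1L + rbinom(sum(sibs == 1 & !sis_first), 1, 0.15)

    # Baseline states of the time-varying absorbing indicators.
    st <- list()
    for (j in c("ever_smoked", "friends_smoke", "alcohol")) {
      a_j <- .solve_marginal(pv[[j]], lam[[j]])
      st[[j]] <- rbinom(n, 1, plogis(a_j + lam[[j]] * z))
    }
    # Felt-need is generated only among current ever-smokers.
    a_ever <- .solve_marginal(pv[["ever_smoked"]], lam[["ever_smoked"]])
    a_need <- .solve_marginal(
      pv[["need_cigarette"]], lam[["need_cigarette"]],
      weight = function(zz) plogis(a_ever + lam[["ever_smoked"]] * zz)
    )
    st$need_cigarette <- st$ever_smoked *
      rbinom(n, 1, plogis(a_need + lam[["need_cigarette"]] * z))

    tr <- config$transition_rates
    truth_model <- config$outcome_coefficients

    first_daily <- rep(NA_integer_, n)
    state_mat <- vector("list", K)   # indicator states per cycle
    wave_starts <- seq(1L, K, by = 4L)
    wave_starts <- wave_starts[wave_starts < K]

    for (cyc in seq_len(K)) {
      if (cyc > 1L) {
        for (j in c("ever_smoked", "friends_smoke", "alcohol")) {
          can <- st[[j]] == 0L
          if (any(can)) {
            h <- plogis(qlogis(tr[[j]]) + lam[[j]] * z[can])
            st[[j]][can] <- rbinom(sum(can), 1, h)
          }
        }
        can <- st$need_cigarette == 0L & st$ever_smoked == 1L
        if (any(can)) {
          h <- plogis(qlogis(tr[["need_cigarette"]]) +
                        lam[["need_cigarette"]] * z[can])
          st$need_cigarette[can] <- rbinom(sum(can), 1, h)
        }
      }

      if (cyc %in% wave_starts) {
        span <- min(4L, K - cyc)
        at_risk <- is.na(first_daily)
        if (any(at_risk)) {
          nd <- data.frame(
            age = entry_age[at_risk] + (cyc - 1) / 4,
            need_cigarette = st$need_cigarette[at_risk],
            parents_smoke = parents[at_risk],
            siblings_smoke = sibs[at_risk],
            friends_smoke = st$friends_smoke[at_risk],
            alcohol = st$alcohol[at_risk],
            ever_smoked = st$ever_smoked[at_risk]
          )
          p <- predict_risk(truth_model, nd)
          if (span < 4L) p <- 1 - (1 - p)^(span / 4)   # partial trailing wave
          ev <- runif(sum(at_risk)) < p
          onset_cycle <- cyc + sample.int(span, sum(at_risk), replace = TRUE)
          idx <- which(at_risk)[ev]
          first_daily[idx] <- onset_cycle[ev]
          # Initiation implies lifetime smoking: force ever-smoked on by the
          # onset cycle (handled below when states are snapshotted).
        }
      }

      # Daily smokers are ever-smokers by definition.
      st$ever_smoked[!is.na(first_daily) & first_daily <= cyc] <- 1L
      state_mat[[cyc]] <- data.frame(
        need_cigarette = st$need_cigarette, parents_smoke = parents,
        siblings_smoke = sibs, friends_smoke = st$friends_smoke,
        alcohol = st$alcohol, ever_smoked = st$ever_smoked
      )
    }

    # ---- Emit raw item rows ------------------------------------------------
    rows <- vector("list", K)
    for (cyc in seq_len(K)) {
      s <- state_mat[[cyc]]
      daily <- !is.na(first_daily) & first_daily <= cyc
      newly <- !is.na(first_daily) & first_daily == cyc

      days3 <- matrix(0L, n, 3)
      cigs3 <- matrix(0L, n, 3)
      occ <- s$ever_smoked == 1L & !daily
      if (any(occ)) {
        k <- sum(occ)
        days3[occ, ] <- matrix(rbinom(3 * k, size = 12, prob = 0.15), k, 3)
        cigs3[occ, ] <- matrix(ifelse(days3[occ, ] > 0, 1L + rbinom(3 * k, 2, 0.3), 0L), k, 3)
      }
      if (any(daily)) {
        k <- sum(daily)
        est <- daily & !newly
        days3[daily, 3] <- 30L
        days3[est, 1:2] <- 30L
        days3[newly, 1:2] <- matrix(rbinom(2 * sum(newly), 20, 0.5), sum(newly), 2)
        cigs3[daily, ] <- ifelse(days3[daily, , drop = FALSE] > 0,
                                 5L + matrix(rbinom(3 * k, 8, 0.4), k, 3), 0L)
      }

      cig_life <- ifelse(s$ever_smoked == 1L,
                         .vocab$cig_lifetime[2L + rbinom(n, 3, 0.45)],
                         "no")
      cigar <- ifelse(s$ever_smoked == 1L & runif(n) < 0.25,
                      .vocab$freq5[1L + pmax(1L, rbinom(n, 2, 0.4))],
                      "never")
      need_it <- ifelse(s$need_cigarette == 1L,
                        .vocab$need[2L + rbinom(n, 2, 0.4)], "never")
      friends_it <- ifelse(s$friends_smoke == 1L,
                           .vocab$friends[2L + rbinom(n, 3, 0.35)], "none")
      alc_it <- ifelse(s$alcohol == 1L,
                       .vocab$freq5[2L + rbinom(n, 2, 0.35)], "never")

      rows[[cyc]] <- data.frame(
        participant_id = seq_len(n),
        cycle = cyc,
        age = entry_age + (cyc - 1) / 4,
        sex = sex,
        days_smoked_m1 = days3[, 1], days_smoked_m2 = days3[, 2],
        days_smoked_m3 = days3[, 3],
        cigs_per_day_m1 = cigs3[, 1], cigs_per_day_m2 = cigs3[, 2],
        cigs_per_day_m3 = cigs3[, 3],
        cig_lifetime = cig_life, cigar_freq = cigar,
        need_cigarette = need_it,
        father_smokes = .vocab$yesno[father + 1L],
        mother_smokes = .vocab$yesno[mother + 1L],
        n_sisters_smoke = n_sis, n_brothers_smoke = n_bro,
        friends_smoke = friends_it, alcohol_freq = alc_it,
        mothers_education = edu,
        stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$participant_id, tab$cycle), ]
    rownames(tab) <- NULL
    attr(tab, "config") <- config
    attr(tab, "truth") <- list(first_daily = first_daily, latent = z)
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}

#' Impose item-level missingness patterned on mother's education
#'
#' Blanks item values stochastically with probabilities proportional to the
#' configured marginal rates and a relative multiplier per mother's-education
#' stratum (missing at random given the stratum). Sex, age and the
#' ever-smoked items are never blanked; the six recall fields are blanked
#' jointly at the `daily_recall` rate; the parent pair and the sibling pair
#' are blanked jointly, mirroring questionnaire-page nonresponse.
#'
#' @param table A complete `cohort_table`.
#' @param config The [generator_config()] whose `missingness` entry to apply
#'   (defaults to the table's own config).
#' @return The cohort table with `NA`s inserted.
#' @export
impose_missingness <- function(table, config = attr(table, "config")) {
  stopifnot(inherits(table, "cohort_table"))
  if (is.null(config)) config <- generator_config()
  ms <- config$missingness
  rates <- ms$rates
  mult <- ms$education_multipliers
  if (length(mult) != 5L) stop("education_multipliers must have 5 entries")

  stratum <- match(table$mothers_education, .vocab$education)
  # normalize multipliers so the configured rate is the marginal rate
  wbar <- sum(config$education_probs * mult)
  rel <- mult / wbar

  nr <- nrow(table)
  out <- table
  with_seed(substream_seed(config$seed, "missingness"), {
    blank <- function(rate) runif(nr) < pmin(1, rate * rel[stratum])
    groups <- list(
      need_cigarette = "need_cigarette",
      parents_smoke = c("father_smokes", "mother_smokes"),
      siblings_smoke = c("n_sisters_smoke", "n_brothers_smoke"),
      friends_smoke = "friends_smoke",
      alcohol = "alcohol_freq",
      mothers_education = "mothers_education",
      daily_recall = c("days_smoked_m1", "days_smoked_m2", "days_smoked_m3",
                       "cigs_per_day_m1", "cigs_per_day_m2", "cigs_per_day_m3")
    )
    for (g in names(groups)) {
      r <- rates[[g]] %||% 0
      if (r <= 0) next
      hit <- blank(r)
      for (col in groups[[g]]) out[[col]][hit] <- NA
    }
  })
  out
}

#' Write / read a cohort table as CSV
#'
#' Missing values are encoded as empty fields; the header is the documented
#' column set of the cohort table.
#'
#' @param table A `cohort_table`.
#' @param path File path.
#' @return `read_cohort_csv()` returns a `cohort_table`.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", check.names = FALSE)
  # empty strings in character columns are missing values
  for (col in names(tab)) if (is.character(tab[[col]])) tab[[col]][tab[[col]] == ""] <- NA
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
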