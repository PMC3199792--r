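# Wave-based risk-set construction: daily-smoker classification from the
# 3-month recall, indicator recoding from raw items, and the five-step
# pooled-wave database build for the 1- and 2-year horizons.

#' Classify daily-smoking status from the 3-month recall
#'
#' A participant is a daily smoker as of a cycle if any observed recall month
#' shows smoking on all 30 days; definitely not a daily smoker if all three
#' months are observed below 30 days; otherwise the status is unknown.
#'
#' @param days Numeric vector of length 3: days smoked in each recall month
#'   (0-30, `NA` allowed).
#' @param cigs Optional cigarettes-per-day values (carried but not used by
#'   the rule).
#' @return `"yes"`, `"no"` or `"unknown"`.
#' @export
classify_daily_smoker <- function(days, cigs = NULL) {
  if (length(days) != 3L) stop("validation error: three recall months required")
  obs <- days[!is.na(days)]
  if (any(obs < 0 | obs > 30)) stop("validation error: days smoked must lie in [0,30]")
  if (any(obs == 30)) return("yes")
  if (length(obs) == 3L) return("no")
  "unknown"
}

# Vectorized classification over a cohort table; returns character vector.
.classify_rows <- function(tab) {
  d <- cbind(tab$days_smoked_m1, tab$days_smoked_m2, tab$days_smoked_m3)
  bad <- d < 0 | d > 30
  if (any(bad, na.rm = TRUE)) stop("validation error: days smoked must lie in [0,30]")
  any30 <- rowSums(d == 30, na.rm = TRUE) > 0
  allobs <- rowSums(!is.na(d)) == 3L
  ifelse(any30, "yes", ifelse(allobs, "no", "unknown"))
}

.positive_or <- function(a_pos, b_pos) {
  # OR of two possibly missing binaries: 1 if either observed positive,
  # 0 only if both observed negative, otherwise NA.
  ifelse(!is.na(a_pos) & a_pos, 1L,
         ifelse(!is.na(b_pos) & b_pos, 1L,
                ifelse(!is.na(a_pos) & !is.na(b_pos), 0L, NA_integer_)))
}

.check_vocab <- function(x, levels, item) {
  bad <- !is.na(x) & !x %in% levels
  if (any(bad))
    stop("validation error: out-of-vocabulary code for ", item, ": ",
         paste(unique(x[bad]), collapse = ", "))
  invisible(x)
}

#' Recode raw questionnaire items into the binary prognostic indicators
#'
#' Applies the published recoding rules: ever-smoked is positive on either
#' the lifetime-cigarette item or the cigar/cigarillo item; felt-need is no
#' for "never" and yes otherwise; parent and sibling smoking are positive if
#' one or both/one or more are; friends smoking contrasts "none" with "a few
#' or more"; alcohol contrasts "never" with any use. A derived indicator is
#' missing only when its inputs cannot decide it (both inputs missing, or the
#' observed input negative and the other missing).
#'
#' @param record A data frame of raw cohort-table rows (any number of rows).
#' @return A data frame with integer columns `need_cigarette`,
#'   `parents_smoke`, `siblings_smoke`, `friends_smoke`, `alcohol`,
#'   `ever_smoked` (0/1/NA).
#' @export
recode_indicators <- function(record) {
  record <- as.data.frame(record)
  .check_vocab(record$cig_lifetime, .vocab$cig_lifetime, "cig_lifetime")
  .check_vocab(record$cigar_freq, .vocab$freq5, "cigar_freq")
  .check_vocab(record$need_cigarette, .vocab$need, "need_cigarette")
  .check_vocab(record$father_smokes, .vocab$yesno, "father_smokes")
  .check_vocab(record$mother_smokes, .vocab$yesno, "mother_smokes")
  .check_vocab(record$friends_smoke, .vocab$friends, "friends_smoke")
  .check_vocab(record$alcohol_freq, .vocab$freq5, "alcohol_freq")
  if (any(record$n_sisters_smoke < 0, na.rm = TRUE) ||
      any(record$n_brothers_smoke < 0, na.rm = TRUE))
    stop("validation error: sibling counts must be non-negative")

  cig_pos <- ifelse(is.na(record$cig_lifetime), NA, record$cig_lifetime != "no")
  cigar_pos <- ifelse(is.na(record$cigar_freq), NA, record$cigar_freq != "never")
  sis_pos <- ifelse(is.na(record$n_sisters_smoke), NA, record$n_sisters_smoke > 0)
  bro_pos <- ifelse(is.na(record$n_brothers_smoke), NA, record$n_brothers_smoke > 0)
  fat_pos <- ifelse(is.na(record$father_smokes), NA, record$father_smokes == "yes")
  mot_pos <- ifelse(is.na(record$mother_smokes), NA, record$mother_smokes == "yes")

  data.frame(
    need_cigarette = ifelse(is.na(record$need_cigarette), NA_integer_,
                            as.integer(record$need_cigarette != "never")),
    parents_smoke = .positive_or(fat_pos, mot_pos),
    siblings_smoke = .positive_or(sis_pos, bro_pos),
    friends_smoke = ifelse(is.na(record$friends_smoke), NA_integer_,
                           as.integer(record$friends_smoke != "none")),
    alcohol = ifelse(is.na(record$alcohol_freq), NA_integer_,
                     as.integer(record$alcohol_freq != "never")),
    ever_smoked = .positive_or(cig_pos, cigar_pos)
  )
}

#' Build the pooled wave risk-set database
#'
#' Implements the five construction steps: (i) cycles are partitioned into
#' fixed waves (1-year horizon: baselines at cycles 1, 5, 9, 13, each wave
#' spanning five cycles; 2-year horizon: baselines at cycles 1 and 9, each
#' spanning nine cycles); (ii) the outcome is initiation of daily smoking at
#' any cycle of the wave after its baseline; (iii) participants already
#' classified daily smokers at or before a wave's baseline are removed from
#' that wave and all later waves; (iv) covariates are drawn from the wave's
#' baseline cycle (left missing if missing there); (v) eligible
#' participant-waves are pooled. A first classification at a boundary cycle
#' counts as an event of the earlier wave. Participants whose daily-smoking
#' status is unknown at a wave baseline are retained with a missing outcome.
#'
#' @param cohort A `cohort_table` spanning at least 17 cycles.
#' @param horizon `"1y"` or `"2y"`.
#' @param policy Mid-wave follow-up policy: `"complete"` (default) requires
#'   classifiable status at every post-baseline cycle of the wave for a Y=0
#'   observation; `"any"` accepts at least one classifiable cycle.
#' @return A `risk_db`: data frame with one row per participant-wave
#'   (`participant_id`, `wave`, `horizon`, `Y`, `age`, the six indicators,
#'   `sex`, `mothers_education`) plus provenance attributes.
#' @export
build_risk_database <- function(cohort, horizon = c("1y", "2y"),
                                policy = c("complete", "any")) {
  horizon <- match.arg(horizon)
  policy <- match.arg(policy)
  stopifnot(inherits(cohort, "cohort_table") || is.data.frame(cohort))
  need_cycles <- 17L
  if (max(cohort$cycle) < need_cycles)
    stop("build error: cohort must span at least ", need_cycles, " cycles")

  baselines <- if (horizon == "1y") c(1L, 5L, 9L, 13L) else c(1L, 9L)
  span <- if (horizon == "1y") 4L else 8L

  cohort <- cohort[order(cohort$participant_id, cohort$cycle), ]
  status <- .classify_rows(cohort)
  rec <- recode_indicators(cohort)

  ids <- sort(unique(cohort$participant_id))
  n_ids <- length(ids)
  K <- max(cohort$cycle)
  pidx <- match(cohort$participant_id, ids)

  # participant x cycle lookup of row indices and classification status
  rowm <- matrix(NA_integer_, n_ids, K)
  rowm[cbind(pidx, cohort$cycle)] <- seq_len(nrow(cohort))
  statm <- matrix(NA_character_, n_ids, K)
  statm[cbind(pidx, cohort$cycle)] <- status

  # first cycle classified daily, per participant
  yesm <- !is.na(statm) & statm == "yes"
  fy <- apply(yesm, 1L, function(r) if (any(r)) which(r)[1] else NA_integer_)

  out <- vector("list", length(baselines))
  for (w in seq_along(baselines)) {
    b <- baselines[w]
    win <- (b + 1L):(b + span)
    at_risk <- (is.na(fy) | fy > b) & !is.na(rowm[, b])
    base_unknown <- at_risk & statm[, b] == "unknown"
    event <- at_risk & !is.na(fy) & fy > b & fy <= b + span
    n_no <- rowSums(!is.na(statm[, win, drop = FALSE]) &
                      statm[, win, drop = FALSE] == "no")
    followed <- if (policy == "complete") n_no == length(win) else n_no > 0L
    keep <- at_risk & (base_unknown | event | followed)
    y <- ifelse(base_unknown, NA_integer_, ifelse(event, 1L, 0L))

    ib <- rowm[keep, b]
    if (!length(ib)) next
    out[[w]] <- data.frame(
      participant_id = ids[keep], wave = w, horizon = horizon,
      Y = y[keep],
      age = cohort$age[ib],
      need_cigarette = rec$need_cigarette[ib],
      parents_smoke = rec$parents_smoke[ib],
      siblings_smoke = rec$siblings_smoke[ib],
      friends_smoke = rec$friends_smoke[ib],
      alcohol = rec$alcohol[ib],
      ever_smoked = rec$ever_smoked[ib],
      sex = cohort$sex[ib],
      mothers_education = cohort$mothers_education[ib],
      stringsAsFactors = FALSE
    )
  }
  db <- do.call(rbind, out)
  rownames(db) <- NULL
  attr(db, "horizon") <- horizon
  attr(db, "policy") <- policy
  attr(db, "source_config") <- attr(cohort, "config")
  class(db) <- c("risk_db", "data.frame")
  db
}

#' Write / read a risk-set database as CSV
#' @param db A `risk_db`.
#' @param path File path.
#' @return `read_risk_db_csv()` returns a `risk_db`.
#' @export
write_risk_db_csv <- function(db, path) {
  utils::write.csv(as.data.frame(db), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_risk_db_csv
#' @export
read_risk_db_csv <- function(path) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  class(db) <- c("risk_db", "data.frame")
  attr(db, "horizon") <- db$horizon[1]
  db
}
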