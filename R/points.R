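# Framingham-style points system: conversion of logistic coefficients into
# integer points anchored to the supported age span, profile scoring, and the
# points-to-risk lookup.

#' Points-table container
#'
#' Holds an integer scoring system derived from (or published alongside) a
#' logistic prognostic model: per-item points for a "yes" answer, an
#' age-to-points map over ages 11-19, the logit-per-point scale, the anchor
#' logit at 0 points, and an ordered points-to-risk lookup grid.
#'
#' @param horizon `"1y"` or `"2y"`.
#' @param item_points Named integer vector over the six yes/no indicators.
#' @param age_points Named integer vector over ages `"11"`..`"19"`,
#'   strictly decreasing from 100 to 0.
#' @param scale Logit units per point.
#' @param anchor Logit value at 0 total points.
#' @param risk_lookup Data frame with columns `points` and `risk` (percent),
#'   strictly increasing in both.
#' @param meta Provenance metadata list.
#' @return An object of class `points_table`.
#' @export
points_table <- function(horizon, item_points, age_points, scale, anchor,
                         risk_lookup, meta = list()) {
  stopifnot(horizon %in% c("1y", "2y"))
  item_points <- item_points[.items6]
  if (anyNA(item_points)) stop("item_points must cover the six indicators")
  ages <- as.character(11:19)
  age_points <- age_points[ages]
  if (anyNA(age_points)) stop("age_points must cover ages 11..19")
  if (any(diff(age_points) >= 0)) stop("age_points must be strictly decreasing in age")
  if (age_points[["11"]] != 100 || age_points[["19"]] != 0)
    stop("age points must run from 100 at age 11 to 0 at age 19")
  if (any(item_points < 0)) stop("item points must be non-negative")
  rl <- as.data.frame(risk_lookup)
  stopifnot(all(c("points", "risk") %in% names(rl)))
  if (is.unsorted(rl$points, strictly = TRUE) || is.unsorted(rl$risk))
    stop("risk_lookup must be increasing in points and risk")
  structure(
    list(horizon = horizon, item_points = item_points, age_points = age_points,
         scale = scale, anchor = anchor, risk_lookup = rl, meta = meta),
    class = "points_table"
  )
}

#' @export
print.points_table <- function(x, ...) {
  cat(sprintf("Points table (%s risk of initiating daily smoking)\n", x$horizon))
  cat("  item points (yes):",
      paste(sprintf("%s=%d", names(x$item_points), x$item_points), collapse = " "),
      "\n")
  cat("  age points 11..19:", paste(x$age_points, collapse = " "), "\n")
  cat(sprintf("  scale = %.6f logit/point, anchor = %.5f\n", x$scale, x$anchor))
  flags <- x$meta$inconsistent_with_coefficients
  if (length(flags))
    cat("  flagged inconsistent with coefficients:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}

#' Derive an integer points table from a logistic model
#'
#' Converts logistic coefficients into integer points by anchoring the
#' supported 8-year age span (11-19 years) to 100 points: one point equals
#' `|age slope| * 8 / 100` logit units. Each yes/no item receives
#' `round(coefficient / scale)` points (nearest integer, halves away from
#' zero); the age row receives `(19 - age)/8 * 100` points with half-points
#' rounded down, the convention of the published age column. The anchor logit
#' (0 points) corresponds to a 19-year-old answering no to every item, and
#' the points-to-risk grid is regenerated from
#' `P = 1/(1 + exp(-(anchor + scale * points)))`.
#'
#' @param model A [logit_model()] with a negative age slope.
#' @param grid_step Spacing of the regenerated points-to-risk grid (default
#'   20 points).
#' @return A [points_table()].
#' @export
derive_points_table <- function(model, grid_step = 20) {
  stopifnot(inherits(model, "logit_model"))
  b_age <- model$slopes[["age"]]
  if (!is.finite(b_age) || b_age >= 0)
    stop("age slope must be negative so that age maps to decreasing points")
  scale <- abs(b_age) * (19 - 11) / 100
  item_points <- round_half_up(model$slopes[.items6] / scale)
  item_points <- pmax(item_points, 0)  # defensively: protective items get 0
  ages <- 11:19
  age_points <- round_half_down((19 - ages) / (19 - 11) * 100)
  names(age_points) <- as.character(ages)
  anchor <- model$intercept + b_age * 19
  max_pts <- 100 + sum(item_points)
  grid <- unique(c(seq(0, max_pts, by = grid_step), max_pts))
  rl <- data.frame(points = grid,
                   risk = round_half_up(100 * plogis(anchor + scale * grid)))
  # enforce a usable (weakly increasing) lookup; risk is monotone in points
  points_table(model$horizon, item_points, age_points, scale, anchor, rl,
               meta = list(source = "derived", from_corrected = model$corrected))
}

#' Risk profile of one adolescent
#'
#' @param age Age in years, within 11-19.
#' @param ever_smoked,parents_smoke,siblings_smoke,need_cigarette,alcohol,friends_smoke
#'   Yes/no answers; accepted codings are `"yes"`/`"no"`, `TRUE`/`FALSE`,
#'   or `1`/`0`.
#' @return An object of class `risk_profile`: a named list with `age` and the
#'   six indicators coded 0/1.
#' @export
risk_profile <- function(age, ever_smoked = "no", parents_smoke = "no",
                         siblings_smoke = "no", need_cigarette = "no",
                         alcohol = "no", friends_smoke = "no") {
  if (!is.numeric(age) || length(age) != 1L || is.na(age) || age < 11 || age > 19)
    stop("age must be a single value within 11-19 years")
  as01 <- function(x, what) {
    if (is.logical(x)) return(as.integer(x))
    if (is.numeric(x) && x %in% c(0, 1)) return(as.integer(x))
    if (is.character(x) && tolower(x) %in% c("yes", "no", "y", "n"))
      return(as.integer(tolower(x) %in% c("yes", "y")))
    stop(what, " must be yes/no (or 0/1, TRUE/FALSE)")
  }
  structure(list(
    age = age,
    need_cigarette = as01(need_cigarette, "need_cigarette"),
    parents_smoke = as01(parents_smoke, "parents_smoke"),
    siblings_smoke = as01(siblings_smoke, "siblings_smoke"),
    friends_smoke = as01(friends_smoke, "friends_smoke"),
    alcohol = as01(alcohol, "alcohol"),
    ever_smoked = as01(ever_smoked, "ever_smoked")
  ), class = "risk_profile")
}

#' Score a risk profile against a points table
#'
#' Total points = age points (age rounded to integer years for the table
#' lookup) plus the item points of every "yes" answer.
#'
#' @param table A [points_table()].
#' @param profile A [risk_profile()].
#' @return Integer total points.
#' @export
score_profile <- function(table, profile) {
  stopifnot(inherits(table, "points_table"), inherits(profile, "risk_profile"))
  age_int <- as.character(round_half_up(profile$age))
  if (!age_int %in% names(table$age_points))
    stop("age outside the supported 11-19 year range")
  yes <- vapply(.items6, function(it) profile[[it]], integer(1))
  unname(table$age_points[[age_int]] + sum(table$item_points[.items6] * yes))
}

#' Map total points to risk (percent)
#'
#' Returns the tabulated risk when the total matches a lookup row exactly,
#' otherwise linearly interpolates between the bracketing rows; the result is
#' rounded to the nearest percent.
#'
#' @param table A [points_table()].
#' @param total_points Total points from [score_profile()].
#' @return Risk in percent (integer-valued).
#' @export
points_to_risk <- function(table, total_points) {
  stopifnot(inherits(table, "points_table"),
            is.numeric(total_points), length(total_points) == 1L)
  rl <- table$risk_lookup
  if (total_points < min(rl$points)) stop("total points below the table minimum")
  if (total_points > max(rl$points)) stop("total points above the table maximum")
  i <- findInterval(total_points, rl$points)
  if (rl$points[i] == total_points) return(rl$risk[i])
  p0 <- rl$points[i]; p1 <- rl$points[i + 1]
  r <- rl$risk[i] + (total_points - p0) / (p1 - p0) * (rl$risk[i + 1] - rl$risk[i])
  as.numeric(round_half_up(r))
}

#' Risk from the logistic equation for one profile
#'
#' Evaluates the model's linear predictor on the profile's indicator values
#' (age used at full resolution, not rounded) and applies the logistic
#' transformation `P = 1/(1+exp(-L))`.
#'
#' @param model A [logit_model()].
#' @param profile A [risk_profile()].
#' @return Probability in (0,1).
#' @export
risk_from_equation <- function(model, profile) {
  stopifnot(inherits(model, "logit_model"), inherits(profile, "risk_profile"))
  nd <- data.frame(
    age = profile$age, need_cigarette = profile$need_cigarette,
    parents_smoke = profile$parents_smoke, siblings_smoke = profile$siblings_smoke,
    friends_smoke = profile$friends_smoke, alcohol = profile$alcohol,
    ever_smoked = profile$ever_smoked
  )
  unname(predict_risk(model, nd))
}
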