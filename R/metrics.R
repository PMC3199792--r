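# Performance statistics: Hosmer-Lemeshow, c-statistic, maximum-rescaled
# R-squared, the discriminating-informativeness variance ratio, and the
# risk-category observed/expected table.

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Observations are grouped into `g` groups by deciles (quantiles) of
#' predicted risk, ties assigned to the lower group; the statistic is the
#' sum over groups and both outcome levels of `(O-E)^2/E`, referred to a
#' chi-squared distribution with `g - 2` degrees of freedom. Groups with a
#' zero expected count are merged into their neighbour with a warning.
#'
#' @param y Binary outcomes (0/1).
#' @param p Predicted risks in (0,1).
#' @param g Number of groups (default 10, minimum 3).
#' @return List with `statistic`, `df`, `p_value` and the per-group table.
#' @export
hosmer_lemeshow <- function(y, p, g = 10L) {
  stopifnot(length(y) == length(p), g >= 3L)
  if (any(p <= 0 | p >= 1)) stop("predicted risks must lie strictly in (0,1)")
  y <- as.numeric(y)
  br <- unique(quantile(p, probs = seq(0, 1, length.out = g + 1L), type = 7))
  grp <- cut(p, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- data.frame(
    group = sort(unique(grp)),
    n = as.vector(table(grp)),
    observed = as.vector(tapply(y, grp, sum)),
    expected = as.vector(tapply(p, grp, sum))
  )
  # merge groups whose expected events or non-events vanish
  repeat {
    bad <- which(tab$expected <= 0 | (tab$n - tab$expected) <= 0)
    if (!length(bad) || nrow(tab) <= 3L) break
    warning("merging Hosmer-Lemeshow group with zero expected count")
    i <- bad[1]
    j <- if (i == nrow(tab)) i - 1L else i + 1L
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab <- tab[-i, ]
  }
  O1 <- tab$observed; E1 <- tab$expected
  O0 <- tab$n - O1;   E0 <- tab$n - E1
  stat <- sum((O1 - E1)^2 / E1 + (O0 - E0)^2 / E0)
  df <- nrow(tab) - 2L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), table = tab)
}

#' Concordance (c-) statistic
#'
#' The probability that a randomly chosen event carries a higher predicted
#' risk than a randomly chosen non-event, ties counting one half. Computed
#' by rank sums (equivalent to exhaustive pair counting).
#'
#' @param y Binary outcomes with at least one event and one non-event.
#' @param p Predicted risks.
#' @return Concordance in `[0,1]`.
#' @export
c_statistic <- function(y, p) {
  stopifnot(length(y) == length(p))
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("c-statistic undefined: need at least one event and one non-event")
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Maximum-rescaled (Nagelkerke) R-squared
#'
#' Cox-Snell `R2 = 1 - exp(2*(loglik_null - loglik_model)/n)` divided by its
#' attainable maximum `1 - exp(2*loglik_null/n)`.
#'
#' @param loglik_null Log-likelihood of the intercept-only model.
#' @param loglik_model Log-likelihood of the fitted model (>= null).
#' @param n Number of observations.
#' @return Value in `[0,1]`.
#' @export
max_rescaled_r2 <- function(loglik_null, loglik_model, n) {
  if (n <= 0) stop("n must be positive")
  if (loglik_model < loglik_null - 1e-8)
    stop("model log-likelihood cannot fall below the null log-likelihood")
  r2_cs <- 1 - exp(2 * (loglik_null - loglik_model) / n)
  r2_max <- 1 - exp(2 * loglik_null / n)
  r2_cs / r2_max
}

#' Discriminating-informativeness variance ratio
#'
#' Ratio of the variance of the model's predicted risks to the variance of
#' the observed binary outcomes (the variance a hypothetical perfect model
#' would achieve, since it would predict 0 for every non-event and 1 for
#' every event). Both variances use the population (divide-by-n) estimator
#' so that `p = y` gives exactly 1. Ranges from 0 (non-informative) to 1
#' (perfect); values above 1 from Monte-Carlo noise are clipped with a
#' warning.
#'
#' @param p Predicted risks.
#' @param y Observed binary outcomes with mean strictly inside (0,1).
#' @return Ratio in `[0,1]`.
#' @export
informativeness_ratio <- function(p, y) {
  stopifnot(length(y) == length(p), length(y) > 0)
  y <- as.numeric(y)
  ybar <- mean(y)
  if (ybar <= 0 || ybar >= 1)
    stop("informativeness undefined: outcomes are all events or all non-events")
  popvar <- function(x) mean((x - mean(x))^2)
  ratio <- popvar(p) / popvar(y)
  if (ratio > 1) {
    warning("informativeness ratio above 1; clipping")
    ratio <- 1
  }
  ratio
}

.risk_breaks <- c(0, 2, 5, 10, 20, 100)
.risk_labels <- c("0% to <=2%", ">2% to <=5%", ">5% to <=10%",
                  ">10% to <=20%", ">20%")

#' Risk-category observed/expected table
#'
#' Tabulates the five published risk strata (<=2%, 2-5%, 5-10%, 10-20%,
#' >20% predicted risk): share of the sample, empirical ("observed") event
#' risk, and mean predicted risk per stratum.
#'
#' @param y Binary outcomes.
#' @param p Predicted risks (proportions in (0,1)).
#' @return Data frame with one row per stratum.
#' @export
risk_category_table <- function(y, p) {
  stopifnot(length(y) == length(p))
  y <- as.numeric(y)
  grp <- cut(100 * p, breaks = .risk_breaks, include.lowest = TRUE,
             labels = .risk_labels)
  n <- as.vector(table(grp))
  obs <- as.vector(tapply(y, grp, function(v) if (length(v)) 100 * mean(v) else NA_real_))
  prd <- as.vector(tapply(p, grp, function(v) if (length(v)) 100 * mean(v) else NA_real_))
  data.frame(
    category = .risk_labels,
    pct_of_sample = 100 * n / length(y),
    observed_risk = obs,
    mean_predicted_risk = prd
  )
}

#' Full performance report of a model on a database
#'
#' @param model A [logit_model()].
#' @param db A complete `risk_db`.
#' @param g Hosmer-Lemeshow groups (default 10).
#' @return List of class `performance_report` with the Hosmer-Lemeshow test,
#'   c-statistic, maximum-rescaled R-squared, informativeness ratio and the
#'   risk-category table.
#' @export
performance_report <- function(model, db, g = 10L) {
  df <- as.data.frame(db)
  used <- df[c("Y", .indicators)]
  if (anyNA(used)) stop("database contains missing values; impute first")
  y <- as.numeric(used$Y)
  p <- predict_risk(model, used)
  lp <- qlogis(p)
  loglik <- sum(y * log(p) + (1 - y) * log1p(-p))
  p0 <- mean(y)
  loglik_null <- sum(y * log(p0) + (1 - y) * log1p(-p0))
  hl <- hosmer_lemeshow(y, p, g = g)
  structure(list(
    hl_statistic = hl$statistic, hl_df = hl$df, hl_pvalue = hl$p_value,
    c_statistic = c_statistic(y, p),
    max_rescaled_r2 = max_rescaled_r2(loglik_null, loglik, length(y)),
    informativeness_ratio = informativeness_ratio(p, y),
    risk_table = risk_category_table(y, p),
    overall_risk = 100 * p0, n = length(y)
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Performance on n = %d observations (overall risk %.1f%%)\n",
              x$n, x$overall_risk))
  cat(sprintf("  Hosmer-Lemeshow chi2 = %.2f (df %d), p = %.2f\n",
              x$hl_statistic, x$hl_df, x$hl_pvalue))
  cat(sprintf("  c-statistic = %.3f; max-rescaled R2 = %.3f; informativeness = %.3f\n",
              x$c_statistic, x$max_rescaled_r2, x$informativeness_ratio))
  print(x$risk_table, row.names = FALSE, digits = 3)
  invisible(x)
}
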