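# Bootstrap cross-validation: calibration-slope shrinkage factor and the
# correction of the naive coefficients.

#' Bootstrap calibration-slope shrinkage
#'
#' For each of `B` bootstrap replicates, the analytic database is resampled
#' with replacement to its original size, the logistic model is refitted on
#' the replicate, the replicate coefficients are combined with the indicator
#' values of the evaluation dataset to produce linear predictor values, and
#' a logistic regression of the evaluation outcomes on that single linear
#' predictor is fitted, recording its intercept B0 and slope B1. The
#' shrinkage factor is the mean of the retained B1 values. Non-converged
#' replicates are skipped and counted, keeping the replicate stream
#' seed-stable.
#'
#' @param db A complete `risk_db`.
#' @param B Number of bootstrap replicates (default 10000; scale down for
#'   exploratory runs).
#' @param seed Seed for the resampling stream.
#' @param eval Evaluation dataset for the linear predictor: `"original"`
#'   (default; measures out-of-sample calibration) or `"bootstrap"` (the
#'   replicate's own sample).
#' @param unit Resampling unit: `"observation"` rows (default) or
#'   `"participant"` cluster bootstrap.
#' @return An object of class `shrinkage_result`: `B`, per-replicate
#'   `slopes` and `intercepts`, `shrinkage_factor` (mean retained slope) and
#'   `n_failed`.
#' @export
bootstrap_shrinkage <- function(db, B = 10000L, seed = 1L,
                                eval = c("original", "bootstrap"),
                                unit = c("observation", "participant")) {
  eval <- match.arg(eval)
  unit <- match.arg(unit)
  if (B < 1L) stop("validation error: B must be >= 1")
  df <- as.data.frame(db)
  used <- df[c("Y", .indicators)]
  if (anyNA(used)) stop("validation error: database contains missing values")
  y <- as.numeric(used$Y)
  X <- .design_matrix(used)
  n <- nrow(X)

  slopes <- rep(NA_real_, B)
  intercepts <- rep(NA_real_, B)
  with_seed(seed, {
    clusters <- if (unit == "participant") df$participant_id else NULL
    uc <- if (!is.null(clusters)) unique(clusters) else NULL
    for (b in seq_len(B)) {
      idx <- if (unit == "observation") {
        sample.int(n, n, replace = TRUE)
      } else {
        picked <- sample(uc, length(uc), replace = TRUE)
        unlist(lapply(picked, function(cid) which(clusters == cid)),
               use.names = FALSE)
      }
      fit_b <- tryCatch(.newton_logit(X[idx, , drop = FALSE], y[idx]),
                        error = function(e) NULL)
      if (is.null(fit_b)) next
      if (eval == "original") {
        lp <- drop(X %*% fit_b$beta)
        ye <- y
      } else {
        lp <- drop(X[idx, , drop = FALSE] %*% fit_b$beta)
        ye <- y[idx]
      }
      cal <- tryCatch(.newton_logit(cbind(1, lp), ye), error = function(e) NULL)
      if (is.null(cal)) next
      intercepts[b] <- cal$beta[[1]]
      slopes[b] <- cal$beta[[2]]
    }
  })
  keep <- !is.na(slopes)
  if (!any(keep)) stop("validation error: all bootstrap replicates failed")
  structure(list(B = B, slopes = slopes[keep], intercepts = intercepts[keep],
                 shrinkage_factor = mean(slopes[keep]),
                 n_failed = sum(!keep), eval = eval, unit = unit),
            class = "shrinkage_result")
}

#' @export
print.shrinkage_result <- function(x, ...) {
  cat(sprintf("Bootstrap shrinkage: factor = %.4f over %d replicates (%d failed)\n",
              x$shrinkage_factor, x$B, x$n_failed))
  invisible(x)
}

#' Apply a shrinkage factor to a naive model
#'
#' Multiplies the slope coefficients by the shrinkage factor, leaving the
#' intercept unchanged, and flags the model as corrected. Applying a factor
#' to an already corrected model is an error (prevents double correction).
#'
#' @param model A naive [logit_model()].
#' @param factor A positive shrinkage factor (or a `shrinkage_result`).
#' @return The corrected [logit_model()].
#' @export
apply_shrinkage <- function(model, factor) {
  stopifnot(inherits(model, "logit_model"))
  if (inherits(factor, "shrinkage_result")) factor <- factor$shrinkage_factor
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0)
    stop("validation error: shrinkage factor must be a positive number")
  if (model$corrected)
    stop("validation error: model is already shrinkage-corrected")
  out <- model
  out$slopes <- model$slopes * factor
  out$corrected <- TRUE
  out$meta$shrinkage_factor <- factor
  out$vcov <- NULL   # naive covariance no longer applies to scaled slopes
  out
}
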