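# Maximum-likelihood logistic fitting of the prognostic model, pairwise
# interaction screening, and Rubin pooling across imputed datasets.

.design_matrix <- function(db, extra = NULL) {
  cols <- .indicators
  miss <- setdiff(c("Y", cols), names(db))
  if (length(miss)) stop("fit error: database lacks columns ", paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1, as.matrix(as.data.frame(db)[cols]))
  if (!is.null(extra)) X <- cbind(X, extra)
  storage.mode(X) <- "double"
  X
}

# Newton-Raphson / IRLS for the Bernoulli logit likelihood.
.newton_logit <- function(X, y, tol = 1e-8, max_iter = 50L, ridge = 0) {
  p_mean <- mean(y)
  beta <- c(qlogis(min(max(p_mean, 1e-6), 1 - 1e-6)), rep(0, ncol(X) - 1L))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    grad <- drop(crossprod(X, y - mu)) - ridge * c(0, beta[-1])
    H <- crossprod(X * w, X)
    if (ridge > 0) H <- H + diag(c(0, rep(ridge, ncol(X) - 1L)))
    step <- tryCatch(solve(H, grad), error = function(e)
      stop("fit error: singular design matrix"))
    beta <- beta + step
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  # diverging slope with fitted values pinned at 0/1 indicates (quasi-)
  # complete separation, whether or not the score has numerically vanished
  if (ridge == 0 && max(abs(beta[-1])) > 15) {
    culprit <- colnames(X)[-1][which.max(abs(beta[-1]))]
    if (is.null(culprit) || is.na(culprit)) culprit <- "unknown"
    stop("fit error: perfect separation on covariate ", culprit)
  }
  if (!converged) stop("fit error: Newton iterations did not converge")
  H <- crossprod(X * (mu * (1 - mu)), X)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  loglik <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  p0 <- mean(y)
  loglik_null <- sum(y * log(p0) + (1 - y) * log1p(-p0))
  list(beta = setNames(beta, colnames(X)), vcov = vc, loglik = loglik,
       loglik_null = loglik_null, n = length(y), fitted = mu,
       iterations = it)
}

#' Fit the multivariable logistic prognostic model
#'
#' Maximum-likelihood logistic regression of the daily-smoking initiation
#' indicator on age and the six binary indicators, by Newton iterations to a
#' score norm below `tol`; standard errors come from the inverse observed
#' information.
#'
#' @param db A complete `risk_db` (no missing values in `Y` or the seven
#'   indicator columns) with at least one event and one non-event.
#' @param tol Convergence tolerance on the score norm (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return A [logit_model()] with coefficient covariance and fit statistics
#'   (`meta$loglik`, `meta$loglik_null`, `meta$n`, `meta$se`).
#' @export
fit_logistic <- function(db, tol = 1e-8, max_iter = 50L) {
  df <- as.data.frame(db)
  used <- df[c("Y", .indicators)]
  if (anyNA(used)) stop("fit error: database contains missing values; impute first")
  y <- as.numeric(used$Y)
  if (!all(y %in% c(0, 1))) stop("fit error: Y must be binary")
  if (length(unique(y)) < 2L) stop("fit error: outcome is constant")
  X <- .design_matrix(used)
  f <- .newton_logit(X, y, tol = tol, max_iter = max_iter)
  horizon <- attr(db, "horizon") %||% (if (!is.null(df$horizon)) df$horizon[1] else "1y")
  logit_model(
    intercept = f$beta[[1]],
    slopes = f$beta[-1],
    horizon = horizon,
    vcov = f$vcov,
    corrected = FALSE,
    meta = list(loglik = f$loglik, loglik_null = f$loglik_null, n = f$n,
                se = sqrt(diag(f$vcov)), iterations = f$iterations)
  )
}

#' Screen pairwise interactions among the prognostic indicators
#'
#' For each of the 21 pairs of the seven indicators, refits the model with
#' that single product term added and records its Wald test; terms with
#' p below `alpha` are retained. An empty result means the main-effects
#' model stands. Pairs whose augmented fit fails are logged and treated as
#' not retained.
#'
#' @param db A complete `risk_db`.
#' @param alpha Per-term significance level (default 0.05).
#' @return Data frame with one row per pair (`term`, `estimate`, `se`, `z`,
#'   `p`, `retained`); attribute `retained` holds the retained term names.
#' @export
screen_interactions <- function(db, alpha = 0.05) {
  df <- as.data.frame(db)
  used <- df[c("Y", .indicators)]
  if (anyNA(used)) stop("fit error: database contains missing values; impute first")
  y <- as.numeric(used$Y)
  pairs <- utils::combn(.indicators, 2L)
  res <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    term <- paste(a, b, sep = ":")
    prod_col <- matrix(used[[a]] * used[[b]], ncol = 1,
                       dimnames = list(NULL, term))
    f <- tryCatch(.newton_logit(.design_matrix(used, prod_col), y),
                  error = function(e) e)
    if (inherits(f, "error")) {
      res[[j]] <- data.frame(term = term, estimate = NA_real_, se = NA_real_,
                             z = NA_real_, p = NA_real_, retained = FALSE,
                             note = conditionMessage(f))
      next
    }
    k <- length(f$beta)
    est <- f$beta[[k]]
    se <- sqrt(f$vcov[k, k])
    zst <- est / se
    pval <- 2 * pnorm(-abs(zst))
    res[[j]] <- data.frame(term = term, estimate = est, se = se, z = zst,
                           p = pval, retained = is.finite(pval) && pval < alpha,
                           note = "")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "retained") <- out$term[out$retained]
  out
}

#' Pool logistic models across imputed datasets (Rubin's rules)
#'
#' Pooled coefficients are the arithmetic means across imputations; the
#' pooled covariance is the mean within-imputation covariance plus
#' `(1 + 1/M)` times the between-imputation covariance of the coefficient
#' vectors.
#'
#' @param models A list of two or more structurally identical
#'   [logit_model()]s.
#' @return A pooled [logit_model()] with `m` set and between/within variance
#'   components in `meta`.
#' @export
pool_models <- function(models) {
  if (!is.list(models) || length(models) < 2L)
    stop("pooling error: at least two models required")
  ok <- vapply(models, inherits, logical(1), what = "logit_model")
  if (!all(ok)) stop("pooling error: all elements must be logit_model objects")
  h <- unique(vapply(models, `[[`, character(1), "horizon"))
  corr <- unique(vapply(models, function(m) m$corrected, logical(1)))
  if (length(h) != 1L || length(corr) != 1L)
    stop("pooling error: mismatched model structures")
  M <- length(models)
  coefs <- t(vapply(models, function(m) c(m$intercept, m$slopes), numeric(8)))
  qbar <- colMeans(coefs)
  B <- stats::cov(coefs)
  haveW <- all(vapply(models, function(m) !is.null(m$vcov), logical(1)))
  W <- if (haveW) Reduce(`+`, lapply(models, `[[`, "vcov")) / M else NULL
  total <- if (haveW) W + (1 + 1 / M) * B else NULL
  logit_model(
    intercept = qbar[1], slopes = qbar[-1], horizon = h,
    vcov = total, corrected = corr, m = M,
    meta = list(between = B, within = W,
                loglik = mean(vapply(models, function(m) m$meta$loglik %||% NA_real_, numeric(1))),
                loglik_null = mean(vapply(models, function(m) m$meta$loglik_null %||% NA_real_, numeric(1))),
                n = models[[1]]$meta$n %||% NA_real_)
  )
}
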