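# Multiple imputation by chained equations with Gibbs-style sweeps.
#
# Each incomplete variable is regressed on all others (binary: Bayesian
# ridge-stabilized logistic; continuous: Bayesian linear; 5-level mother's
# education: multinomial), and imputations are drawn from the fitted
# predictive distribution with parameters drawn from their asymptotic
# posterior, so that between-imputation variance reflects estimation
# uncertainty.

#' Imputation configuration
#'
#' @param m Number of imputed datasets (default 25).
#' @param n_iterations Gibbs sweeps per dataset (default 10).
#' @param include_sex Include sex as a predictor in the conditional models
#'   (default TRUE).
#' @param ridge Fixed ridge penalty stabilizing conditional logistic fits
#'   against separation (default 0.1).
#' @param seed Seed for the imputation substreams.
#' @return A list of class `imputation_config`.
#' @export
imputation_config <- function(m = 25L, n_iterations = 10L, include_sex = TRUE,
                              ridge = 0.1, seed = 1L) {
  if (m < 2L) stop("imputation error: m must be >= 2")
  if (n_iterations < 1L) stop("imputation error: n_iterations must be >= 1")
  structure(list(m = as.integer(m), n_iterations = as.integer(n_iterations),
                 include_sex = isTRUE(include_sex), ridge = ridge,
                 seed = seed),
            class = "imputation_config")
}

.draw_mvn <- function(mean, vcov) {
  L <- tryCatch(chol(vcov), error = function(e) NULL)
  if (is.null(L)) return(mean)   # degenerate posterior: use the point estimate
  drop(mean + t(L) %*% rnorm(length(mean)))
}

# Bayesian-draw logistic imputation of a binary column.
.impute_binary <- function(dat, v, predictors, mis, ridge) {
  X <- cbind(1, as.matrix(dat[predictors]))
  y <- dat[[v]]
  f <- tryCatch(.newton_logit(X[!mis, , drop = FALSE], y[!mis], ridge = ridge),
                error = function(e) NULL)
  if (is.null(f))
    f <- tryCatch(.newton_logit(X[!mis, , drop = FALSE], y[!mis], ridge = ridge * 100),
                  error = function(e) NULL)
  if (is.null(f)) {
    warning("imputation fallback to marginal draws for ", v)
    return(sample(y[!mis], sum(mis), replace = TRUE))
  }
  beta <- .draw_mvn(f$beta, f$vcov)
  p <- plogis(drop(X[mis, , drop = FALSE] %*% beta))
  rbinom(sum(mis), 1L, p)
}

.impute_linear <- function(dat, v, predictors, mis) {
  X <- cbind(1, as.matrix(dat[predictors]))
  y <- dat[[v]]
  Xo <- X[!mis, , drop = FALSE]; yo <- y[!mis]
  XtX <- crossprod(Xo) + diag(1e-8, ncol(Xo))
  bhat <- solve(XtX, crossprod(Xo, yo))
  res <- yo - drop(Xo %*% bhat)
  df <- max(length(yo) - ncol(Xo), 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)   # scaled inverse-chisq draw
  beta <- .draw_mvn(drop(bhat), sigma2 * solve(XtX))
  drop(X[mis, , drop = FALSE] %*% beta) + rnorm(sum(mis), 0, sqrt(sigma2))
}

.impute_multinomial <- function(dat, v, predictors, mis) {
  df_fit <- data.frame(.y = factor(dat[[v]][!mis]), dat[!mis, predictors, drop = FALSE])
  fit <- tryCatch(
    nnet::multinom(.y ~ ., data = df_fit, trace = FALSE, maxit = 200),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("imputation fallback to marginal draws for ", v)
    return(sample(dat[[v]][!mis], sum(mis), replace = TRUE))
  }
  nd <- dat[mis, predictors, drop = FALSE]
  pr <- predict(fit, newdata = nd, type = "probs")
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = sum(mis))
  lev <- levels(df_fit$.y)
  if (ncol(pr) == 1L) pr <- cbind(1 - pr, pr)   # two observed levels only
  apply(pr, 1L, function(p) sample(lev, 1L, prob = pmax(p, 1e-12)))
}

#' Multiple imputation of a risk-set database
#'
#' Runs chained-equations imputation of the missing cells among the outcome,
#' the seven prognostic indicators, sex and mother's education, producing
#' `m` completed copies of the database. Missing cells are initialized by
#' draws from the observed marginals, then each incomplete variable is
#' revisited in turn for `n_iterations` Gibbs sweeps; each completed copy
#' uses an independent random substream. Observed cells are never altered.
#'
#' @param db A `risk_db` (possibly with missing indicator cells).
#' @param config An [imputation_config()].
#' @return An object of class `imputed_set`: list with `datasets` (list of
#'   `m` complete `risk_db` copies), `diagnostics` (per-variable missing
#'   fractions and per-sweep imputed-mean traces), and `config`.
#' @export
impute <- function(db, config = imputation_config()) {
  stopifnot(inherits(config, "imputation_config"))
  df <- as.data.frame(db)
  model_vars <- c("Y", .indicators, "mothers_education",
                  if (config$include_sex) "sex")
  model_vars <- intersect(model_vars, names(df))

  work <- df[model_vars]
  if ("sex" %in% model_vars) work$sex <- as.integer(df$sex == "male")
  frac_missing <- vapply(work, function(x) mean(is.na(x)), numeric(1))
  if (any(frac_missing == 1))
    stop("imputation error: variable 100% missing: ",
         paste(names(frac_missing)[frac_missing == 1], collapse = ", "))
  incomplete <- names(frac_missing)[frac_missing > 0]

  if (!length(incomplete)) {
    datasets <- replicate(config$m, db, simplify = FALSE)
    return(structure(list(datasets = datasets,
                          diagnostics = list(frac_missing = frac_missing,
                                             trace = NULL),
                          config = config),
                     class = "imputed_set"))
  }

  binary_vars <- intersect(incomplete,
                           c("Y", "need_cigarette", "parents_smoke",
                             "siblings_smoke", "friends_smoke", "alcohol",
                             "ever_smoked", "sex"))
  cont_vars <- intersect(incomplete, "age")
  cat_vars <- intersect(incomplete, "mothers_education")

  mism <- lapply(work, is.na)
  datasets <- vector("list", config$m)
  trace <- array(NA_real_, dim = c(config$m, config$n_iterations, length(incomplete)),
                 dimnames = list(NULL, NULL, incomplete))

  for (im in seq_len(config$m)) {
    with_seed(substream_seed(config$seed, 100L + im), {
      dat <- work
      # mother's education modelled through stratum score in others' models
      for (v in names(dat)) {
        mis <- mism[[v]]
        if (any(mis)) dat[[v]][mis] <- sample(dat[[v]][!mis], sum(mis), replace = TRUE)
      }
      for (sweep in seq_len(config$n_iterations)) {
        for (v in incomplete) {
          mis <- mism[[v]]
          predictors <- setdiff(names(dat), v)
          # numeric working copy: education enters as an ordinal score
          num <- dat
          if ("mothers_education" %in% names(num))
            num$mothers_education <- as.numeric(match(num$mothers_education,
                                                      .vocab$education))
          if (v %in% binary_vars) {
            dat[[v]][mis] <- .impute_binary(num, v, predictors, mis, config$ridge)
          } else if (v %in% cont_vars) {
            dat[[v]][mis] <- .impute_linear(num, v, predictors, mis)
          } else if (v %in% cat_vars) {
            dat[[v]][mis] <- .impute_multinomial(
              within(num, mothers_education <- dat$mothers_education),
              v, predictors, mis)
          }
          vi <- dat[[v]][mis]
          trace[im, sweep, v] <- if (is.numeric(vi)) mean(vi) else
            mean(match(vi, .vocab$education))
        }
      }
      completed <- df
      for (v in incomplete) {
        mis <- mism[[v]]
        if (v == "sex") {
          completed$sex[mis] <- ifelse(dat$sex[mis] == 1L, "male", "female")
        } else {
          completed[[v]][mis] <- dat[[v]][mis]
        }
      }
      dsi <- completed
      for (a in c("horizon", "policy")) attr(dsi, a) <- attr(db, a)
      class(dsi) <- c("risk_db", "data.frame")
      datasets[[im]] <- dsi
    })
  }

  structure(list(datasets = datasets,
                 diagnostics = list(frac_missing = frac_missing, trace = trace),
                 config = config),
            class = "imputed_set")
}

#' @export
print.imputed_set <- function(x, ...) {
  cat(sprintf("Imputed set: %d completed databases (%d Gibbs sweeps each)\n",
              length(x$datasets), x$config$n_iterations))
  fm <- x$diagnostics$frac_missing
  fm <- fm[fm > 0]
  if (length(fm))
    cat("  imputed variables:",
        paste(sprintf("%s (%.1f%%)", names(fm), 100 * fm), collapse = ", "), "\n")
  else cat("  no missing cells; copies are identical\n")
  invisible(x)
}

#' Fit the prognostic model on each imputed dataset and pool
#'
#' @param imp An [impute()] result.
#' @return List with `fits` (per-imputation [logit_model()]s) and `pooled`
#'   (the Rubin-pooled model).
#' @export
fit_imputed <- function(imp) {
  stopifnot(inherits(imp, "imputed_set"))
  fits <- lapply(imp$datasets, fit_logistic)
  list(fits = fits, pooled = pool_models(fits))
}
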