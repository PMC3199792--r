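#' @importFrom stats plogis qlogis rnorm rbinom runif quantile var pchisq pnorm qnorm predict setNames dnorm uniroot cov rchisq
#' @importFrom utils combn
NULL

# Canonical indicator order of the prognostic model.  X1 is age in years;
# X2..X7 are the six binary yes/no indicators.
.indicators <- c(
  "age", "need_cigarette", "parents_smoke", "siblings_smoke",
  "friends_smoke", "alcohol", "ever_smoked"
)

#' Construct a logistic prognostic model
#'
#' A `logit_model` stores the intercept and the seven slope coefficients of
#' the daily-smoking initiation model (age in years plus six binary
#' indicators), together with an optional coefficient covariance matrix and a
#' flag recording whether the slopes have been shrinkage-corrected.
#'
#' @param intercept Intercept on the logit scale.
#' @param slopes Numeric vector of 7 slopes in the order: age,
#'   need_cigarette, parents_smoke, siblings_smoke, friends_smoke, alcohol,
#'   ever_smoked. Names, if present, must match.
#' @param horizon `"1y"` or `"2y"`.
#' @param vcov Optional 8x8 covariance matrix (intercept first).
#' @param corrected Logical; `TRUE` once slopes have been multiplied by a
#'   shrinkage factor.
#' @param m Number of imputations pooled into this model, if pooled.
#' @param meta Optional list of provenance metadata.
#' @return An object of class `logit_model`.
#' @export
logit_model <- function(intercept, slopes, horizon = c("1y", "2y"),
                        vcov = NULL, corrected = FALSE, m = NULL,
                        meta = list()) {
  horizon <- match.arg(horizon)
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(slopes), length(slopes) == 7L)
  if (!is.null(names(slopes)) && !identical(names(slopes), .indicators)) {
    slopes <- slopes[.indicators]
    if (anyNA(slopes)) stop("slope names must be the seven canonical indicators")
  }
  names(slopes) <- .indicators
  structure(
    list(intercept = unname(intercept), slopes = slopes, horizon = horizon,
         vcov = vcov, corrected = isTRUE(corrected), m = m, meta = meta),
    class = "logit_model"
  )
}

#' @export
print.logit_model <- function(x, ...) {
  cat(sprintf("Logistic daily-smoking initiation model (%s horizon)%s\n",
              x$horizon, if (x$corrected) ", shrinkage-corrected" else ""))
  cat(sprintf("  L = %.5f %s\n", x$intercept,
              paste(sprintf("%+.4f*%s", x$slopes, names(x$slopes)),
                    collapse = " ")))
  if (!is.null(x$m)) cat(sprintf("  pooled over %d imputations\n", x$m))
  invisible(x)
}

#' Linear predictor and predicted risk
#'
#' Evaluates `L = intercept + sum(slopes * x)` and `P = 1/(1 + exp(-L))` for
#' rows of indicator values.
#'
#' @param model A [logit_model()].
#' @param newdata Data frame (or named list) holding columns `age`,
#'   `need_cigarette`, `parents_smoke`, `siblings_smoke`, `friends_smoke`,
#'   `alcohol`, `ever_smoked` (binary indicators coded 0/1).
#' @return `linear_predictor()` returns L; `predict_risk()` returns P in (0,1).
#' @export
linear_predictor <- function(model, newdata) {
  stopifnot(inherits(model, "logit_model"))
  newdata <- as.data.frame(newdata)
  miss <- setdiff(.indicators, names(newdata))
  if (length(miss)) stop("newdata lacks columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[.indicators])
  drop(model$intercept + X %*% model$slopes)
}

#' @rdname linear_predictor
#' @export
predict_risk <- function(model, newdata) {
  plogis(linear_predictor(model, newdata))
}

# Serialization: models as JSON so fitted/corrected models can be archived
# and reloaded bit-for-bit at full double precision.

#' Write / read a model as JSON
#' @param model A [logit_model()].
#' @param path File path.
#' @return `read_model_json()` returns a [logit_model()].
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "logit_model"))
  obj <- list(
    horizon = model$horizon,
    intercept = model$intercept,
    slopes = as.list(model$slopes),
    corrected = model$corrected,
    m = model$m,
    vcov = if (!is.null(model$vcov)) as.vector(model$vcov) else NULL,
    meta = model$meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vc <- NULL
  if (!is.null(obj$vcov) && length(obj$vcov)) vc <- matrix(unlist(obj$vcov), 8, 8)
  logit_model(obj$intercept, unlist(obj$slopes), horizon = obj$horizon,
              vcov = vc, corrected = isTRUE(obj$corrected),
              m = obj$m, meta = as.list(obj$meta))
}
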