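# Internal helpers: seed substreams, rounding conventions, validation.

# Deterministic substream seeds derived from one master seed.  Each stochastic
# stage of the pipeline draws its own seed so stages are independently
# reproducible.  Kept strictly below 2^31 - 1.
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  streams <- c(
    cohort = 1L, missingness = 2L, imputation = 3L, fit = 4L,
    bootstrap = 5L, metrics = 6L, pipeline = 7L
  )
  k <- if (is.character(stream)) {
    if (!stream %in% names(streams)) stop("unknown substream: ", stream)
    streams[[stream]]
  } else {
    as.integer(stream)
  }
  ((as.double(master) %% 2147483647) * 48271 + k * 69621) %% 2147483629 + 1
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Nearest integer, halves away from zero (commercial rounding; base round()
# uses round-half-even which does not reproduce the printed point values).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Nearest integer, halves toward zero: the convention of the printed age-points
# column (87.5 -> 87, 62.5 -> 62, ...).
round_half_down <- function(x) sign(x) * ceiling(abs(x) - 0.5)

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) log(p / (1 - p))
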