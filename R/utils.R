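# Internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

is_power_of_two <- function(n) {
  n <- as.integer(n)
  length(n) == 1L && !is.na(n) && n >= 1L && bitwAnd(n, n - 1L) == 0L
}

# Deterministic sub-stream ids for the package RNG. All randomness in a
# simulation flows from one explicit seed; distinct purposes (field draws,
# noise draws, sensor pattern, ...) and distinct stacks get distinct streams.
rng_stream <- function(kind, i = 0L, j = 0L) {
  kind + 8 * (i + 10000 * j)
}
STREAM_FIELD <- 1L
STREAM_NOISE <- 2L
STREAM_PATTERN <- 3L
STREAM_TRAIN <- 4L

# Run code with R's global RNG seeded to `seed`, restoring the caller's RNG
# state afterwards (used where base R sampling is convenient, e.g. training
# set draws and minibatch shuffling).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Recycle a scalar or verify a matrix of the given dimensions.
as_map <- function(x, height, width, what) {
  if (length(x) == 1L) {
    matrix(as.numeric(x), height, width)
  } else {
    x <- as.matrix(x)
    if (!identical(dim(x), c(height, width))) {
      stop(sprintf("'%s' must be a scalar or a %d x %d matrix", what,
                   height, width), call. = FALSE)
    }
    storage.mode(x) <- "double"
    x
  }
}

stopifnot_scalar_number <- function(x, what, min = -Inf, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= min
  if (!ok) stop(sprintf("'%s' must be a single number >= %g", what, min),
                call. = FALSE)
  invisible(x)
}
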