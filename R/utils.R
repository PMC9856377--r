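# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the ambient RNG untouched.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

.assertScalar <- function(x, name, positive = FALSE, nonNegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be > 0 (got ", format(x), ")", call. = FALSE)
  if (nonNegative && x < 0)
    stop("'", name, "' must be >= 0 (got ", format(x), ")", call. = FALSE)
  invisible(x)
}

.assertIncreasing <- function(x, name, strict = TRUE) {
  if (length(x) == 0L || any(!is.finite(x)))
    stop("'", name, "' must be non-empty and finite", call. = FALSE)
  d <- diff(x)
  if ((strict && any(d <= 0)) || (!strict && any(d < 0)))
    stop("'", name, "' must be sorted in increasing order", call. = FALSE)
  invisible(x)
}
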