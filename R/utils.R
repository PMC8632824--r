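## internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic operations in the package funnel through this so that the
## same seed yields bit-identical output regardless of surrounding code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Round-half-up (round() in R rounds half to even, which is not what a
## fixed-count allocation wants: 0.5 of 3 genes must give 2, not sometimes 1).
round_half_up <- function(x) floor(x + 0.5)

## Numerical inversion of the trigamma function on (0, Inf); Newton iteration.
## trigamma is convex decreasing so the iteration is monotone from a point
## above the root.
trigamma_inverse <- function(y) {
  if (y <= 0) stop("trigamma_inverse requires a positive argument", call. = FALSE)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(100)) {
    delta <- (trigamma(x) - y) / psigamma(x, deriv = 2L)
    x <- x - delta
    if (x <= 0) x <- .Machine$double.eps
    if (abs(delta) < 1e-10 * x) break
  }
  x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
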