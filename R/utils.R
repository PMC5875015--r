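# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Centered running mean with edge truncation: element i averages the samples
# within floor(k/2) positions of i that exist.
running_mean <- function(x, k) {
  stopifnot(k >= 1)
  n <- length(x)
  h <- floor(k / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Mean-preserving multiplicative lognormal noise; cv = 0 is the identity.
mult_noise <- function(x, cv) {
  if (cv == 0) return(x)
  s <- sqrt(log(1 + cv^2))
  x * stats::rlnorm(length(x), meanlog = -s^2 / 2, sdlog = s)
}

# Draws with a target arithmetic mean m and coefficient of variation cv.
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - s^2 / 2, sdlog = s)
}

# Run set.seed() without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_input <- function(...) stop(..., call. = FALSE)
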