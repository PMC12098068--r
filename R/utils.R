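#' Derive a child seed from a master seed
#'
#' Deterministic mixing of a master seed with a stream index, kept within
#' the 32-bit signed integer range accepted by [set.seed()]. Used so every
#' stage (simulation, per-fold training, dropout, shuffling) draws from its
#' own reproducible stream.
#'
#' @param seed Master seed (non-negative integer).
#' @param k Stream index (non-negative integer).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.numeric(k), length(k) == 1L, k >= 0)
  m <- 2147483629
  # products stay below 2^53, so double arithmetic is exact here
  as.integer(((seed %% m) * 48271 + (k %% m) * 16807) %% m)
}

# Run code with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  # warm-up: discard the first draws, which are weakly correlated across
  # nearby Mersenne-Twister seeds and would otherwise couple the profiles
  # of different subjects seeded from one master seed
  invisible(runif(20))
  force(code)
}

#' Truncated-normal sampler with mean correction
#'
#' Draws from a normal distribution truncated to `[lower, upper]`, with the
#' location parameter adjusted so the *truncated* mean equals the requested
#' target. Plain truncation of a normal at a nearby bound biases the mean
#' (for example a variable targeted at 13.2 with SD 8.8 truncated at zero);
#' the adjustment removes that bias so cohort-level moments are recovered.
#'
#' @param n Number of draws.
#' @param mean Target mean of the truncated distribution.
#' @param sd Standard deviation of the untruncated parent distribution.
#' @param lower,upper Truncation bounds.
#' @return Numeric vector of `n` draws in `[lower, upper]`.
#' @export
rtruncnorm_mean <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper, mean > lower, mean < upper)
  mu <- truncnorm_location(mean, sd, lower, upper)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mu, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Mean of N(mu, sd) truncated to [lower, upper].
truncnorm_expected <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Solve for the location parameter whose truncated mean hits `target`.
truncnorm_location <- function(target, sd, lower, upper) {
  if (!is.finite(lower) && !is.finite(upper)) return(target)
  f <- function(mu) truncnorm_expected(mu, sd, lower, upper) - target
  stats::uniroot(f, interval = c(target - 6 * sd, target + 6 * sd),
                 tol = 1e-10)$root
}

# stop() with sprintf-style formatting, no call in the condition.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) &&
    x >= min
}
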