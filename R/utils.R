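`%||%` <- function(a, b) if (is.null(a)) b else a

# population SD (divisor N); r in relative mode is proportional to it
popSd <- function(x) sqrt(mean((x - mean(x))^2))

# stationary AR(1) noise: x_t = phi x_{t-1} + e_t, stationary SD = sd
ar1Noise <- function(n, sd, phi) {
  if (sd == 0 || n == 0L) return(numeric(n))
  innovSd <- sd * sqrt(1 - phi^2)
  e <- stats::rnorm(n, 0, innovSd)
  as.numeric(stats::filter(e, phi, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

# one truncated-normal draw by rejection
rnormTrunc <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

# run expr with a temporarily seeded RNG, restoring the caller's stream
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

checkPositiveScalar <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("parameter '", name, "' must be a single finite positive number",
         call. = FALSE)
  }
  invisible(x)
}

checkNonNegativeScalar <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0) {
    stop("parameter '", name, "' must be a single finite non-negative number",
         call. = FALSE)
  }
  invisible(x)
}

# centred moving-average envelope used for threshold detection on noisy
# channels; width in samples, forced odd
movingAverage <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  k <- rep(1 / width, width)
  y <- stats::filter(x, k, sides = 2)
  # fill edges with the nearest computed value
  y <- as.numeric(y)
  half <- (width - 1L) / 2L
  n <- length(x)
  y[seq_len(half)] <- y[half + 1L]
  y[(n - half + 1L):n] <- y[n - half]
  y
}
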