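# internal helpers shared across modules

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# C1-continuous smoothstep ramp: 0 below 0, 1 above 1, 3v^2 - 2v^3 between.
smoothstep <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  v * v * (3 - 2 * v)
}

# Trapezoidal integral of y over x (seconds in, units(y)*s out).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Central-difference derivative with one-sided differences at the ends.
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(rep(NA_real_, n))
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2L) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name), call. = FALSE)
  invisible(x)
}
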