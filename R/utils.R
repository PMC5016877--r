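# Shared numeric helpers. Trapezoidal quadrature is used everywhere a profile
# is averaged so that synthesis and extraction measure mean speed identically.

trapz_mean <- function(t, v) {
  pracma::trapz(t, v) / (t[length(t)] - t[1])
}

# Central differences on a (possibly non-uniform) strictly increasing grid;
# one-sided at the ends.
finite_diff <- function(t, x) {
  n <- length(t)
  stopifnot(n >= 3L, length(x) == n)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  d[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  d
}

# Gaussian basis matrix: one column per submovement, unit amplitude.
gaussian_basis <- function(t_grid, times, sigmas) {
  sapply(seq_along(times), function(i) {
    exp(-((t_grid - times[i]) / (sqrt(2) * sigmas[i]))^2)
  })
}

# Uniform grid over [0, t_dur] with step ~1/hz whose last point is exactly
# t_dur, so that averaged-profile constraints and extraction agree on the
# movement duration.
time_grid <- function(t_dur, sampling_hz) {
  seq(0, t_dur, length.out = max(2L, as.integer(round(t_dur * sampling_hz))) + 1L)
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name),
          class = "reachkin_invalid_argument")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "reachkin_invalid_argument")
  }
  invisible(as.integer(x))
}
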