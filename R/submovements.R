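#' Specification of a tangential speed profile
#'
#' The generative model of one movement's tangential speed needs four
#' parameters: the number of submovements `npk`, their average duration scale
#' `mean_sigma` (s), the movement duration `t_dur` (s), and the average
#' tangential speed `mv` (m/s). Peaks must fit into the movement with at
#' least `2 * mean_sigma` between successive peak times, so a spec is feasible
#' only when `(npk - 1) * 2 * mean_sigma <= t_dur`.
#'
#' @param npk Number of submovements (>= 1).
#' @param mean_sigma Average submovement duration scale (s).
#' @param t_dur Movement duration (s).
#' @param mv Average tangential speed (m/s).
#' @return A list of class `tangential_spec`.
#' @export
tangential_spec <- function(npk, mean_sigma, t_dur, mv) {
  npk <- check_count(npk, "npk")
  check_scalar_positive(mean_sigma, "mean_sigma")
  check_scalar_positive(t_dur, "t_dur")
  check_scalar_positive(mv, "mv")
  if ((npk - 1) * 2 * mean_sigma > t_dur) {
    abort(sprintf(
      "Infeasible spec: %d peaks spaced >= 2*%.3g s do not fit in %.3g s.",
      npk, mean_sigma, t_dur), class = "reachkin_infeasible")
  }
  structure(list(npk = npk, mean_sigma = mean_sigma, t_dur = t_dur, mv = mv),
            class = "tangential_spec")
}

#' Sample submovement peak times
#'
#' Peak times are drawn uniformly on `[0, t_dur]` subject to successive peaks
#' being at least `2 * mean_sigma` apart (to avoid peak overlap). Sampling is
#' by rejection of sorted uniform draws; after `max_attempts` failures a
#' jittered equal spacing that satisfies the constraint is used instead.
#'
#' @param spec A [tangential_spec()].
#' @param max_attempts Rejection-sampling budget.
#' @param min_gap_factor Minimum spacing between peak times as a multiple of
#'   `mean_sigma` (default 2, the no-overlap constraint; larger values give
#'   well-separated peaks).
#' @return Sorted numeric vector of `npk` peak times.
#' @export
sample_peak_schedule <- function(spec, max_attempts = 10000L,
                                 min_gap_factor = 2) {
  stopifnot(inherits(spec, "tangential_spec"))
  npk <- spec$npk
  gap <- min_gap_factor * spec$mean_sigma
  if ((npk - 1) * gap > spec$t_dur) {
    abort("Requested peak spacing does not fit in the movement duration.",
          class = "reachkin_infeasible")
  }
  if (npk == 1L) return(runif(1, 0, spec$t_dur))
  for (i in seq_len(max_attempts)) {
    tt <- sort(runif(npk, 0, spec$t_dur))
    if (min(diff(tt)) >= gap) return(tt)
  }
  # Fallback: equal spacing with uniform jitter inside the residual slack.
  slack <- (spec$t_dur - (npk - 1) * gap) / npk
  base <- slack / 2 + (seq_len(npk) - 1) * (gap + slack)
  sort(base + runif(npk, -slack / 2, slack / 2))
}

#' Sample submovement duration scales
#'
#' Individual sigmas are drawn uniformly in
#' `[(1 - jitter_w), (1 + jitter_w)] * mean_sigma` and then rescaled so their
#' sample mean equals `mean_sigma` exactly, honouring the model constraint
#' `E[sigma] = <sigma>`.
#'
#' @param npk Number of submovements.
#' @param mean_sigma Target mean sigma (s).
#' @param jitter_w Relative half-width of the sampling interval (default 0.3).
#' @return Numeric vector of `npk` positive sigmas with mean `mean_sigma`.
#' @export
sample_sigmas <- function(npk, mean_sigma, jitter_w = 0.3) {
  npk <- check_count(npk, "npk")
  check_scalar_positive(mean_sigma, "mean_sigma")
  stopifnot(jitter_w >= 0, jitter_w < 1)
  if (npk == 1L || jitter_w == 0) return(rep(mean_sigma, npk))
  s <- runif(npk, (1 - jitter_w) * mean_sigma, (1 + jitter_w) * mean_sigma)
  s * mean_sigma / mean(s)
}

#' Build a submovement set
#'
#' @param times Peak times (s).
#' @param amplitudes Peak amplitudes (m/s); positive for tangential
#'   submovements, signed for longitudinal/transversal ones.
#' @param sigmas Duration scales (s), positive.
#' @param t_dur Movement duration (s).
#' @return A tibble of class `submovement_set` with columns `t_i`, `A_i`,
#'   `sigma_i` and attribute `t_dur`.
#' @export
submovement_set <- function(times, amplitudes, sigmas, t_dur) {
  stopifnot(length(times) == length(amplitudes),
            length(times) == length(sigmas), all(sigmas > 0))
  out <- tibble(t_i = as.numeric(times), A_i = as.numeric(amplitudes),
                sigma_i = as.numeric(sigmas))
  attr(out, "t_dur") <- t_dur
  class(out) <- c("submovement_set", class(out))
  out
}

#' Evaluate a submovement sum on a time grid
#'
#' The profile is the pointwise sum of Gaussian bells
#' `A_i * exp(-((t - t_i) / (sqrt(2) * sigma_i))^2)`.
#'
#' @param subs A [submovement_set()].
#' @param t_grid Evaluation times (s).
#' @param axis Axis tag: `"tangential"`, `"longitudinal"` or `"transversal"`.
#' @return A tibble of class `speed_profile` with columns `t`, `v` and an
#'   `axis` attribute.
#' @export
evaluate_profile <- function(subs, t_grid, axis = "tangential") {
  v <- if (nrow(subs) == 0L) {
    numeric(length(t_grid))
  } else {
    as.numeric(gaussian_basis(t_grid, subs$t_i, subs$sigma_i) %*% subs$A_i)
  }
  speed_profile(t_grid, v, axis = axis)
}

#' @rdname evaluate_profile
#' @param t,v Sample times (s) and speeds (m/s).
#' @export
speed_profile <- function(t, v, axis = "tangential") {
  axis <- match.arg(axis, c("tangential", "longitudinal", "transversal"))
  stopifnot(length(t) == length(v))
  out <- tibble(t = as.numeric(t), v = as.numeric(v))
  attr(out, "axis") <- axis
  class(out) <- c("speed_profile", class(out))
  out
}

#' Fit submovement amplitudes under the mean-speed constraint
#'
#' Given fixed peak times and sigmas, amplitudes are chosen to minimize
#' `|MV - (1/t) integral v(t)|` subject to `A_i > 0`. The time-averaged speed
#' is linear in the amplitudes (`mean = sum A_i c_i / t_dur`, with `c_i` the
#' trapezoidal integral of the i-th unit Gaussian over the movement), so the
#' minimizer is obtained by scaling the equal-contribution initial point
#' `A_i = MV t / (npk sigma_i sqrt(2 pi))` onto the constraint hyperplane;
#' the objective reaches zero (to rounding) and positivity holds by
#' construction. A bounded quasi-Newton polish is run as a safeguard when the
#' scaled solution misses the tolerance.
#'
#' @param times,sigmas Fixed peak times and duration scales.
#' @param spec A [tangential_spec()].
#' @param sampling_hz Grid rate used for quadrature (default 200).
#' @param tol_mv Absolute tolerance on the mean-speed residual, as a fraction
#'   of MV (default 1e-4).
#' @return A [submovement_set()] with attribute `residual` (the achieved
#'   `|MV - mean|`).
#' @export
fit_amplitudes_constrained <- function(times, sigmas, spec,
                                       sampling_hz = 200, tol_mv = 1e-4) {
  stopifnot(inherits(spec, "tangential_spec"),
            length(times) == spec$npk, length(sigmas) == spec$npk)
  t_grid <- time_grid(spec$t_dur, sampling_hz)
  basis <- gaussian_basis(t_grid, times, sigmas)
  ci <- apply(basis, 2, function(col) pracma::trapz(t_grid, col))
  a0 <- spec$mv * spec$t_dur / (spec$npk * sigmas * sqrt(2 * pi))
  a <- a0 * spec$mv * spec$t_dur / sum(a0 * ci)
  resid <- abs(spec$mv - sum(a * ci) / spec$t_dur)
  if (resid > tol_mv * spec$mv) {
    eps <- 1e-6 * spec$mv
    fit <- optim(a, function(p) (spec$mv - sum(p * ci) / spec$t_dur)^2,
                 method = "L-BFGS-B", lower = rep(eps, spec$npk))
    if (sqrt(fit$value) > tol_mv * spec$mv) {
      abort(sprintf("Amplitude fit did not converge (residual %.3g).",
                    sqrt(fit$value)), class = "reachkin_convergence")
    }
    a <- fit$par
    resid <- sqrt(fit$value)
  }
  out <- submovement_set(times, a, sigmas, spec$t_dur)
  attr(out, "residual") <- resid
  out
}

#' Synthesize a tangential speed profile
#'
#' Composes peak-time sampling, sigma sampling and constrained amplitude
#' fitting, then evaluates the submovement sum on a uniform grid at
#' `sampling_hz`.
#'
#' @inheritParams fit_amplitudes_constrained
#' @param spec A [tangential_spec()].
#' @param jitter_w Sigma jitter width passed to [sample_sigmas()].
#' @param min_gap_factor Peak spacing multiple passed to
#'   [sample_peak_schedule()].
#' @return A list with `profile` (a `speed_profile`) and `submovements`
#'   (a `submovement_set`).
#' @export
synthesize_tangential <- function(spec, sampling_hz = 200, jitter_w = 0.3,
                                  tol_mv = 1e-4, min_gap_factor = 2) {
  times <- sample_peak_schedule(spec, min_gap_factor = min_gap_factor)
  sigmas <- sample_sigmas(spec$npk, spec$mean_sigma, jitter_w)
  subs <- fit_amplitudes_constrained(times, sigmas, spec,
                                     sampling_hz = sampling_hz, tol_mv = tol_mv)
  t_grid <- time_grid(spec$t_dur, sampling_hz)
  list(profile = evaluate_profile(subs, t_grid, axis = "tangential"),
       submovements = subs)
}

#' Overlap between two Gaussian submovements
#'
#' The area of the intersection of the two Gaussian curves divided by the sum
#' of their areas; 0.5 for identical submovements, approaching 0 as they
#' separate. Progressive submovement blending during recovery raises this
#' value.
#'
#' @param sub1,sub2 Single-row [submovement_set()]s or lists with `t_i`,
#'   `A_i`, `sigma_i`.
#' @return Overlap fraction in `[0, 0.5]`.
#' @export
submovement_overlap <- function(sub1, sub2) {
  g <- function(s) list(t = s$t_i[1], A = abs(s$A_i[1]), sig = s$sigma_i[1])
  g1 <- g(sub1); g2 <- g(sub2)
  stopifnot(g1$sig > 0, g2$sig > 0)
  lo <- min(g1$t - 8 * g1$sig, g2$t - 8 * g2$sig)
  hi <- max(g1$t + 8 * g1$sig, g2$t + 8 * g2$sig)
  tt <- seq(lo, hi, length.out = 4001L)
  c1 <- g1$A * exp(-((tt - g1$t) / (sqrt(2) * g1$sig))^2)
  c2 <- g2$A * exp(-((tt - g2$t) / (sqrt(2) * g2$sig))^2)
  inter <- pracma::trapz(tt, pmin(c1, c2))
  areas <- pracma::trapz(tt, c1) + pracma::trapz(tt, c2)
  inter / areas
}
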