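#' Specification of the longitudinal/transversal profile pair
#'
#' Six parameters extend the tangential model to the plane: the mean absolute
#' transversal speed `mv_n`, the numbers `cont_l`/`cont_n` of longitudinal and
#' transversal peaks that coincide with tangential peaks, the amplitude ratios
#' `ratio_amp_l`/`ratio_amp_n` (mean longitudinal resp. transversal peak
#' amplitude over mean tangential peak amplitude), and `ratio_npk` (peak-count
#' ratio between the longitudinal and tangential profiles). The mean
#' longitudinal speed is not a free parameter: `MV_L = D / t_dur`, the
#' theoretical path length over the movement duration.
#'
#' @param mv_n Mean absolute transversal speed (m/s, >= 0).
#' @param cont_l,cont_n Counts of contributing peaks (>= 0).
#' @param ratio_amp_l,ratio_amp_n Amplitude ratios (>= 0).
#' @param ratio_npk Peak-count ratio (> 0).
#' @return A list of class `planar_spec`.
#' @export
planar_spec <- function(mv_n, cont_l, cont_n, ratio_amp_l, ratio_amp_n,
                        ratio_npk) {
  stopifnot(mv_n >= 0, ratio_amp_l >= 0, ratio_amp_n >= 0, ratio_npk > 0)
  cont_l <- check_count(cont_l, "cont_l", min = 0L)
  cont_n <- check_count(cont_n, "cont_n", min = 0L)
  structure(list(mv_n = mv_n, cont_l = cont_l, cont_n = cont_n,
                 ratio_amp_l = ratio_amp_l, ratio_amp_n = ratio_amp_n,
                 ratio_npk = ratio_npk),
            class = "planar_spec")
}

#' Longitudinal/transversal peak counts from the count ratio
#'
#' The longitudinal and transversal profiles are assumed to have comparable
#' numbers of peaks, both derived from the tangential count through
#' `ratio_npk`; at least one peak is always kept.
#'
#' @param ratio_npk Peak-count ratio (> 0).
#' @param npk Tangential peak count.
#' @return Named integer vector `c(npk_l, npk_n)`.
#' @export
derive_ln_counts <- function(ratio_npk, npk) {
  stopifnot(ratio_npk > 0)
  npk <- check_count(npk, "npk")
  k <- max(1L, as.integer(round(ratio_npk * npk)))
  c(npk_l = k, npk_n = k)
}

#' Place the peak times of a longitudinal or transversal profile
#'
#' `cont_x` of the returned times coincide with tangential peak times (a
#' random subset when `cont_x` is smaller than the number available); the
#' remaining `npk_x - cont_x` are drawn uniformly on `[0, t_dur]` under the
#' same minimum spacing constraint (`2 * mean_sigma`) as the tangential
#' schedule.
#'
#' @param tangential_peaks Tangential peak times (s).
#' @param npk_x Total number of peaks to place.
#' @param cont_x Number of peaks tied to tangential peak times.
#' @param t_dur Movement duration (s).
#' @param mean_sigma Average sigma (s) setting the spacing constraint.
#' @param max_attempts Rejection budget for the free peaks.
#' @return Sorted vector of `npk_x` times; attribute `coupled` marks which
#'   are tangential-coincident.
#' @export
assign_ln_peak_times <- function(tangential_peaks, npk_x, cont_x, t_dur,
                                 mean_sigma, max_attempts = 10000L) {
  npk_x <- check_count(npk_x, "npk_x")
  cont_x <- check_count(cont_x, "cont_x", min = 0L)
  if (cont_x > min(npk_x, length(tangential_peaks))) {
    warn("cont_x exceeds available peaks; clipping.")
    cont_x <- min(npk_x, length(tangential_peaks))
  }
  fixed <- if (cont_x > 0) {
    sort(sample(tangential_peaks, cont_x))
  } else numeric(0)
  n_free <- npk_x - cont_x
  gap <- 2 * mean_sigma
  if (n_free == 0L) {
    out <- fixed
  } else {
    ok <- FALSE
    for (i in seq_len(max_attempts)) {
      free <- runif(n_free, 0, t_dur)
      all_t <- sort(c(fixed, free))
      if (length(all_t) == 1L || min(diff(all_t)) >= gap) { ok <- TRUE; break }
    }
    if (!ok) {
      # Deterministic fallback: drop free peaks into the largest gaps.
      anchors <- sort(c(0, fixed, t_dur))
      free <- numeric(0)
      for (j in seq_len(n_free)) {
        cur <- sort(c(anchors, free))
        gaps <- diff(cur)
        gi <- which.max(gaps)
        cand <- (cur[gi] + cur[gi + 1]) / 2
        free <- c(free, cand)
      }
      all_t <- sort(c(fixed, free))
      if (length(all_t) > 1L && min(diff(all_t)) < gap) {
        abort("Cannot place longitudinal/transversal peaks with the required spacing.",
              class = "reachkin_infeasible")
      }
    }
    out <- all_t
  }
  attr(out, "coupled") <- out %in% fixed
  out
}

#' Synthesize the longitudinal and transversal speed profiles
#'
#' Both profiles are sums of Gaussian submovements sharing the tangential
#' sigma statistics. Their amplitudes solve a single unconstrained problem
#' weighting the longitudinal and transversal mean-speed residuals
#' asymmetrically: `min alpha |MV_L - mean(v_L)| + beta |MV_N - mean(|v_N|)|`
#' with defaults `alpha = 0.8`, `beta = 0.2`, so longitudinal compliance is
#' prioritized. Initial amplitudes are the corresponding amplitude ratio times
#' the mean tangential peak amplitude (alternating signs for the transversal
#' profile); a Nelder-Mead simplex search with restarts refines them.
#'
#' @param tangential A `submovement_set` for the tangential profile.
#' @param spec A [planar_spec()].
#' @param mv_l Target mean longitudinal speed (m/s), typically `D / t_dur`.
#' @param alpha,beta Objective weights (`<= 1`).
#' @param sampling_hz Grid rate (default 200).
#' @param jitter_w Sigma jitter for the resampled L/N sigmas.
#' @param optimizer_tol Convergence tolerance on the objective.
#' @param max_restarts Number of re-jittered restarts.
#' @return A list with `v_l`, `v_n` (speed_profiles), `subs_l`, `subs_n`
#'   (submovement_sets) and `residuals` (named: longitudinal, transversal).
#' @export
synthesize_planar <- function(tangential, spec, mv_l, alpha = 0.8, beta = 0.2,
                              sampling_hz = 200, jitter_w = 0.3,
                              optimizer_tol = 1e-6, max_restarts = 3L) {
  stopifnot(inherits(spec, "planar_spec"), alpha > 0, alpha <= 1,
            beta > 0, beta <= 1)
  t_dur <- attr(tangential, "t_dur")
  mean_sigma <- mean(tangential$sigma_i)
  t_grid <- time_grid(t_dur, sampling_hz)
  counts <- derive_ln_counts(spec$ratio_npk, nrow(tangential))
  cont_l <- min(spec$cont_l, counts[["npk_l"]], nrow(tangential))
  cont_n <- min(spec$cont_n, counts[["npk_n"]], nrow(tangential))

  times_l <- assign_ln_peak_times(tangential$t_i, counts[["npk_l"]], cont_l,
                                  t_dur, mean_sigma)
  times_n <- assign_ln_peak_times(tangential$t_i, counts[["npk_n"]], cont_n,
                                  t_dur, mean_sigma)
  sig_l <- sample_sigmas(counts[["npk_l"]], mean_sigma, jitter_w)
  sig_n <- sample_sigmas(counts[["npk_n"]], mean_sigma, jitter_w)
  basis_l <- gaussian_basis(t_grid, times_l, sig_l)
  basis_n <- gaussian_basis(t_grid, times_n, sig_n)

  amp_t <- mean(tangential$A_i)
  nl <- counts[["npk_l"]]; nn <- counts[["npk_n"]]
  a_l0 <- rep(spec$ratio_amp_l * amp_t, nl)
  a_n0 <- spec$ratio_amp_n * amp_t * (-1)^(seq_len(nn) - 1)
  # The longitudinal term is linear in the amplitudes, so the initial point is
  # refined by scaling the longitudinal group onto its mean-speed target; the
  # transversal group keeps the amplitude-ratio initialization and is left to
  # the simplex search under its (lower) weight.
  ml0 <- trapz_mean(t_grid, as.numeric(basis_l %*% a_l0))
  if (ml0 > 0) a_l0 <- a_l0 * mv_l / ml0

  degenerate_n <- spec$mv_n == 0 && spec$ratio_amp_n == 0

  objective <- function(par) {
    vl <- as.numeric(basis_l %*% par[seq_len(nl)])
    vn <- if (degenerate_n) numeric(length(t_grid)) else
      as.numeric(basis_n %*% par[nl + seq_len(nn)])
    alpha * abs(mv_l - trapz_mean(t_grid, vl)) +
      beta * abs(spec$mv_n - trapz_mean(t_grid, abs(vn)))
  }

  par0 <- c(a_l0, if (degenerate_n) rep(0, nn) else a_n0)
  best <- NULL
  for (r in 0:max_restarts) {
    start <- if (r == 0) par0 else par0 * (1 + 0.2 * rnorm(length(par0)))
    fit <- optim(start, objective, method = "Nelder-Mead",
                 control = list(maxit = 2000L * length(par0),
                                reltol = optimizer_tol))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value <= optimizer_tol * max(mv_l, 1e-6)) break
  }
  if (is.null(best) || !is.finite(best$value)) {
    abort("Planar amplitude optimization failed to converge.",
          class = "reachkin_convergence")
  }
  a_l <- best$par[seq_len(nl)]
  a_n <- if (degenerate_n) rep(0, nn) else best$par[nl + seq_len(nn)]
  # Final polish: the longitudinal term is linear in a_l, so rescaling onto
  # its mean-speed target strictly improves the objective (the transversal
  # term does not involve a_l).
  ml <- trapz_mean(t_grid, as.numeric(basis_l %*% a_l))
  if (ml > 0) a_l <- a_l * mv_l / ml
  vl <- as.numeric(basis_l %*% a_l)
  vn <- as.numeric(basis_n %*% a_n)
  list(
    v_l = speed_profile(t_grid, vl, axis = "longitudinal"),
    v_n = speed_profile(t_grid, vn, axis = "transversal"),
    subs_l = submovement_set(times_l, a_l, sig_l, t_dur),
    subs_n = submovement_set(times_n, a_n, sig_n, t_dur),
    residuals = c(longitudinal = abs(mv_l - trapz_mean(t_grid, vl)),
                  transversal = abs(spec$mv_n - trapz_mean(t_grid, abs(vn))))
  )
}

#' Integrate speed profiles to a path in the L/N frame
#'
#' Cumulative trapezoidal integration of the longitudinal and transversal
#' speed profiles, starting from the movement origin.
#'
#' @param v_l,v_n `speed_profile`s on identical time grids.
#' @return A tibble of class `path_ln` with columns `t`, `x_l`, `x_n`;
#'   attribute `excursion` reports `x_l` at the final sample.
#' @export
integrate_to_path <- function(v_l, v_n) {
  if (length(v_l$t) != length(v_n$t) || any(abs(v_l$t - v_n$t) > 1e-12)) {
    abort("v_l and v_n must share the same time grid.",
          class = "reachkin_invalid_argument")
  }
  x_l <- pracma::cumtrapz(v_l$t, v_l$v)[, 1]
  x_n <- pracma::cumtrapz(v_n$t, v_n$v)[, 1]
  out <- tibble(t = v_l$t, x_l = x_l, x_n = x_n)
  attr(out, "excursion") <- x_l[length(x_l)]
  class(out) <- c("path_ln", class(out))
  out
}

#' Place an L/N path into the workspace
#'
#' Rigid (isometric) mapping `(x, y) = origin + x_l * L + x_n * N`.
#'
#' @param path A [integrate_to_path()] result.
#' @param frame An [ln_frame_for()] frame.
#' @param meta Metadata list attached to the returned trajectory.
#' @return A `reach_trajectory`.
#' @export
place_in_workspace <- function(path, frame, meta = list()) {
  stopifnot(inherits(frame, "ln_frame"))
  x <- frame$origin[1] + path$x_l * frame$L[1] + path$x_n * frame$N[1]
  y <- frame$origin[2] + path$x_l * frame$L[2] + path$x_n * frame$N[2]
  trajectory(path$t, x, y, meta = meta)
}

#' Simulate one point-to-point movement
#'
#' End-to-end composition: tangential synthesis, coupled planar synthesis,
#' integration, and placement along the movement's theoretical path.
#'
#' @param tang_spec A [tangential_spec()].
#' @param plan_spec A [planar_spec()].
#' @param geometry A [task_geometry()].
#' @param target Target index.
#' @param direction `"outward"` or `"backward"`.
#' @param meta Extra metadata merged into the trajectory's metadata.
#' @param sampling_hz,jitter_w,alpha,beta,min_gap_factor Passed to
#'   [synthesize_tangential()] and [synthesize_planar()].
#' @return A `reach_trajectory`; attribute `model` carries the submovement
#'   sets and residuals.
#' @export
simulate_movement <- function(tang_spec, plan_spec, geometry,
                              target = 1L, direction = "outward",
                              meta = list(), sampling_hz = 200,
                              jitter_w = 0.3, alpha = 0.8, beta = 0.2,
                              min_gap_factor = 2) {
  frame <- ln_frame_for(geometry, target, direction)
  tang <- synthesize_tangential(tang_spec, sampling_hz = sampling_hz,
                                jitter_w = jitter_w,
                                min_gap_factor = min_gap_factor)
  mv_l <- geometry$radius / tang_spec$t_dur
  plan <- synthesize_planar(tang$submovements, plan_spec, mv_l = mv_l,
                            alpha = alpha, beta = beta,
                            sampling_hz = sampling_hz, jitter_w = jitter_w)
  path <- integrate_to_path(plan$v_l, plan$v_n)
  meta <- utils::modifyList(list(target = target, direction = direction), meta)
  traj <- place_in_workspace(path, frame, meta = meta)
  attr(traj, "model") <- list(tangential = tang$submovements,
                              subs_l = plan$subs_l, subs_n = plan$subs_n,
                              residuals = plan$residuals)
  traj
}
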