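# Extraction of the model-based and evaluation kinematic parameters from a
# planar trajectory (real or simulated).

#' Tangential speed of a trajectory
#'
#' Speed magnitude from central differences of the endpoint coordinates.
#' Optional zero-phase low-pass smoothing of the coordinates (forward-backward
#' second-order Butterworth) can be enabled for noisy recordings; it is off by
#' default, which is appropriate for simulated data.
#'
#' @param traj A [trajectory()].
#' @param smooth_hz Optional low-pass cutoff (Hz); `NULL` disables smoothing.
#' @return A `speed_profile` tagged `tangential`.
#' @export
tangential_speed <- function(traj, smooth_hz = NULL) {
  if (nrow(traj) < 3L) {
    abort("Need at least 3 samples.", class = "reachkin_invalid_argument")
  }
  xy <- smooth_coords(traj, smooth_hz)
  vx <- finite_diff(traj$t, xy$x)
  vy <- finite_diff(traj$t, xy$y)
  speed_profile(traj$t, sqrt(vx^2 + vy^2), axis = "tangential")
}

smooth_coords <- function(traj, smooth_hz) {
  if (is.null(smooth_hz)) return(list(x = traj$x, y = traj$y))
  fs <- 1 / median(diff(traj$t))
  bf <- signal::butter(2, min(0.99, 2 * smooth_hz / fs))
  list(x = as.numeric(signal::filtfilt(bf, traj$x)),
       y = as.numeric(signal::filtfilt(bf, traj$y)))
}

#' Project a trajectory's velocity onto the L/N frame
#'
#' Returns the tangential magnitude together with the signed longitudinal and
#' transversal components; pointwise `v_l^2 + v_n^2 = v_t^2`.
#'
#' @param traj A [trajectory()].
#' @param frame An [ln_frame_for()] frame.
#' @param smooth_hz Optional low-pass cutoff (Hz).
#' @return List with `v_t`, `v_l`, `v_n` speed profiles.
#' @export
decompose_ln <- function(traj, frame, smooth_hz = NULL) {
  stopifnot(inherits(frame, "ln_frame"))
  xy <- smooth_coords(traj, smooth_hz)
  vx <- finite_diff(traj$t, xy$x)
  vy <- finite_diff(traj$t, xy$y)
  vl <- vx * frame$L[1] + vy * frame$L[2]
  vn <- vx * frame$N[1] + vy * frame$N[2]
  list(v_t = speed_profile(traj$t, sqrt(vx^2 + vy^2), axis = "tangential"),
       v_l = speed_profile(traj$t, vl, axis = "longitudinal"),
       v_n = speed_profile(traj$t, vn, axis = "transversal"))
}

local_maxima_idx <- function(v, thr) {
  pk <- pracma::findpeaks(v, minpeakheight = thr)
  if (is.null(pk)) return(integer(0))
  sort(pk[, 2])
}

polarity_peaks <- function(t, v, threshold_frac) {
  vmax <- max(v)
  if (!is.finite(vmax) || vmax <= 1e-12) {
    return(tibble(time = numeric(0), amplitude = numeric(0)))
  }
  idx <- local_maxima_idx(v, threshold_frac * vmax)
  idx <- idx[v[idx] > threshold_frac * vmax]  # strict "larger than"
  if (length(idx) == 0L) {
    # Degenerate profiles (e.g. constant speed) have a maximum but no strict
    # interior local max; count the global maximum as the single peak.
    idx <- which.max(v)
  }
  tibble(time = t[idx], amplitude = v[idx])
}

#' Detect speed-profile peaks with the 10 percent amplitude rule
#'
#' Local maxima whose amplitude exceeds `threshold_frac` (default 10 percent)
#' of the profile's maximum amplitude. For signed (longitudinal/transversal)
#' profiles the rule is applied separately to the positive part and to the
#' negated negative part, yielding positive and negative peaks.
#'
#' @param profile A `speed_profile`.
#' @param threshold_frac Amplitude threshold as a fraction of the maximum
#'   (default 0.1).
#' @return A tibble of class `peak_set` with columns `time`, `amplitude`
#'   (signed) and `polarity` (`"pos"`/`"neg"`).
#' @export
detect_peaks <- function(profile, threshold_frac = 0.1) {
  signed <- attr(profile, "axis") %in% c("longitudinal", "transversal")
  if (!signed) {
    pos <- polarity_peaks(profile$t, profile$v, threshold_frac)
    out <- dplyr::mutate(pos, polarity = "pos")
  } else {
    pos <- polarity_peaks(profile$t, pmax(profile$v, 0), threshold_frac)
    neg <- polarity_peaks(profile$t, pmax(-profile$v, 0), threshold_frac)
    out <- dplyr::bind_rows(
      dplyr::mutate(pos, polarity = "pos"),
      dplyr::mutate(neg, amplitude = -.data$amplitude, polarity = "neg")
    )
    out <- dplyr::arrange(out, .data$time)
  }
  class(out) <- c("peak_set", class(out))
  out
}

# Half-width of v around peak index p at level `level * v[p]`, interpolated;
# used to seed and as fallback for the per-peak Gaussian fit.
halfwidth_sigma <- function(t, v, p, level = exp(-0.5)) {
  h <- v[p] * level
  left <- NA_real_; right <- NA_real_
  i <- p
  while (i > 1L && v[i] > h) i <- i - 1L
  if (v[i] <= h) {
    left <- t[p] - approx(v[i:(i + 1)], t[i:(i + 1)], xout = h)$y
  }
  i <- p
  n <- length(v)
  while (i < n && v[i] > h) i <- i + 1L
  if (v[i] <= h) {
    right <- approx(v[(i - 1):i], t[(i - 1):i], xout = h)$y - t[p]
  }
  w <- mean(c(left, right), na.rm = TRUE)
  if (!is.finite(w) || w <= 0) w <- (t[length(t)] - t[1]) / (4 * length(v))
  w
}

#' Fit per-peak Gaussian submovements and their average sigma
#'
#' Each detected peak is fitted by a Gaussian bell (nonlinear least squares
#' seeded at the peak) over a window of four half-width-based sigmas around
#' it, clipped at the midpoints towards neighbouring peaks so that adjacent
#' submovements do not contaminate the fit. When a fit fails, that peak's
#' sigma falls back to the half-width of the profile at 60.65 percent of the
#' peak height (the Gaussian `exp(-1/2)` level). The movement's `<sigma>` is
#' the mean of the fitted sigmas.
#'
#' @param profile A `speed_profile` (tangential, or a rectified polarity).
#' @param peaks A `peak_set` from [detect_peaks()] (positive amplitudes).
#' @return List with `mean_sigma`, `sigmas` (per peak), and `submovements`
#'   (a [submovement_set()] of the fitted bells).
#' @export
fit_mean_sigma <- function(profile, peaks) {
  if (nrow(peaks) == 0L) {
    abort("No peaks to fit.", class = "reachkin_degenerate_movement")
  }
  t <- profile$t
  v <- abs(profile$v)
  n <- length(t)
  pk_times <- sort(peaks$time)
  fits <- purrr::map(seq_len(nrow(peaks)), function(i) {
    p <- which.min(abs(t - peaks$time[i]))
    sig0 <- halfwidth_sigma(t, v, p)
    prev <- pk_times[pk_times < peaks$time[i] - 1e-12]
    nxt <- pk_times[pk_times > peaks$time[i] + 1e-12]
    lo_t <- max(t[1], t[p] - 4 * sig0,
                if (length(prev) > 0) (max(prev) + t[p]) / 2 else -Inf)
    hi_t <- min(t[n], t[p] + 4 * sig0,
                if (length(nxt) > 0) (min(nxt) + t[p]) / 2 else Inf)
    win <- which(t >= lo_t & t <= hi_t)
    fit <- tryCatch({
      df <- data.frame(tt = t[win], vv = v[win])
      # optimizer chatter on degenerate windows is handled by the fallback
      m <- suppressWarnings(minpack.lm::nlsLM(
        vv ~ A * exp(-((tt - mu)^2) / (2 * sig^2)), data = df,
        start = list(A = v[p], mu = t[p], sig = sig0),
        lower = c(A = 0, mu = t[1], sig = 1e-6),
        upper = c(A = Inf, mu = t[n], sig = t[n] - t[1]),
        control = minpack.lm::nls.lm.control(maxiter = 100)))
      co <- coef(m)
      list(A = co[["A"]], mu = co[["mu"]], sig = co[["sig"]])
    }, error = function(e) NULL)
    if (is.null(fit)) fit <- list(A = v[p], mu = t[p], sig = sig0)
    fit
  })
  sigs <- vapply(fits, `[[`, numeric(1), "sig")
  subs <- submovement_set(vapply(fits, `[[`, numeric(1), "mu"),
                          vapply(fits, `[[`, numeric(1), "A"),
                          sigs, t_dur = t[n] - t[1])
  list(mean_sigma = mean(sigs), sigmas = sigs, submovements = subs)
}

#' Count contributing peaks
#'
#' A longitudinal or transversal peak "contributes" when it falls within a
#' time window as wide as sigma centered on a tangential peak. Windows use the
#' per-tangential-peak fitted sigma by default; each x-peak is counted at most
#' once even if it lies in several windows.
#'
#' @param peaks_x `peak_set` of the longitudinal or transversal profile.
#' @param peaks_t `peak_set` of the tangential profile.
#' @param sigma_window Per-tangential-peak window widths (s); recycled if
#'   scalar.
#' @return Integer count.
#' @export
contributing_peaks <- function(peaks_x, peaks_t, sigma_window) {
  stopifnot(all(sigma_window > 0))
  if (nrow(peaks_x) == 0L || nrow(peaks_t) == 0L) return(0L)
  sw <- rep_len(sigma_window, nrow(peaks_t))
  inside <- vapply(peaks_x$time, function(tx) {
    any(abs(tx - peaks_t$time) <= sw / 2)
  }, logical(1))
  sum(inside)
}

# Index of the nearest tangential peak whose sigma-window contains each
# contributing x-peak (NA when outside every window).
match_contributing <- function(peaks_x, peaks_t, sigma_window) {
  sw <- rep_len(sigma_window, nrow(peaks_t))
  vapply(peaks_x$time, function(tx) {
    d <- abs(tx - peaks_t$time)
    ok <- which(d <= sw / 2)
    if (length(ok) == 0L) NA_integer_ else ok[which.min(d[ok])]
  }, integer(1))
}

#' Mean deviation from the theoretical path
#'
#' Mean absolute transversal coordinate of the trajectory relative to the
#' straight start-to-target line.
#'
#' @param traj A [trajectory()].
#' @param frame The movement's [ln_frame_for()] frame.
#' @return MD in meters.
#' @export
mean_deviation <- function(traj, frame) {
  stopifnot(inherits(frame, "ln_frame"))
  xn <- (traj$x - frame$origin[1]) * frame$N[1] +
        (traj$y - frame$origin[2]) * frame$N[2]
  mean(abs(xn))
}

# One pass over a movement computing everything the two parameter sets need.
analyze_movement <- function(traj, frame, threshold_frac = 0.1,
                             smooth_hz = NULL,
                             cont_window = c("per_peak", "mean_sigma")) {
  cont_window <- match.arg(cont_window)
  prof <- decompose_ln(traj, frame, smooth_hz = smooth_hz)
  peaks_t <- detect_peaks(prof$v_t, threshold_frac)
  if (nrow(peaks_t) == 0L) {
    abort("No tangential peak detected; degenerate movement.",
          class = "reachkin_degenerate_movement")
  }
  sig_fit <- fit_mean_sigma(prof$v_t, peaks_t)
  peaks_l <- detect_peaks(prof$v_l, threshold_frac)
  peaks_n <- detect_peaks(prof$v_n, threshold_frac)
  windows <- if (cont_window == "per_peak") sig_fit$sigmas else
    sig_fit$mean_sigma
  t <- prof$v_t$t
  list(
    prof = prof, peaks_t = peaks_t, peaks_l = peaks_l, peaks_n = peaks_n,
    sig_fit = sig_fit, windows = windows,
    t_dur = t[length(t)] - t[1],
    mv = trapz_mean(t, prof$v_t$v),
    mv_l = trapz_mean(t, prof$v_l$v),
    mv_n = trapz_mean(t, abs(prof$v_n$v)),
    md = mean_deviation(traj, frame)
  )
}

#' Extract the ten model-based parameters
#'
#' The parameters that drive the generative model: tangential peak count
#' `npk`, average fitted sigma `mean_sigma`, duration `t_dur`, mean tangential
#' speed `mv`, mean absolute transversal speed `mv_n`, contributing-peak
#' counts `cont_l`/`cont_n`, amplitude ratios `ratio_amp_l`/`ratio_amp_n`
#' (absolute peak amplitudes over mean tangential peak amplitude), and the
#' peak-count ratio `ratio_npk` (longitudinal peaks of both polarities over
#' tangential peaks).
#'
#' @inheritParams analyze_movement
#' @param traj A [trajectory()].
#' @param frame The movement's [ln_frame_for()] frame.
#' @return A one-row tibble.
#' @export
extract_model_params <- function(traj, frame, threshold_frac = 0.1,
                                 smooth_hz = NULL,
                                 cont_window = c("per_peak", "mean_sigma")) {
  an <- analyze_movement(traj, frame, threshold_frac, smooth_hz, cont_window)
  amp_t <- mean(abs(an$peaks_t$amplitude))
  npk_l <- nrow(an$peaks_l)
  tibble(
    npk = nrow(an$peaks_t),
    mean_sigma = an$sig_fit$mean_sigma,
    t_dur = an$t_dur,
    mv = an$mv,
    mv_n = an$mv_n,
    cont_l = contributing_peaks(an$peaks_l, an$peaks_t, an$windows),
    cont_n = contributing_peaks(an$peaks_n, an$peaks_t, an$windows),
    ratio_amp_l = if (npk_l > 0) mean(abs(an$peaks_l$amplitude)) / amp_t else 0,
    ratio_amp_n = if (nrow(an$peaks_n) > 0)
      mean(abs(an$peaks_n$amplitude)) / amp_t else 0,
    ratio_npk = npk_l / nrow(an$peaks_t)
  )
}

#' Extract the fourteen evaluation parameters
#'
#' Held-out validation measures not used by the generative model: mean
#' longitudinal speed `mv_l`, mean tangential peak amplitude `a`, per-polarity
#' peak amplitudes and counts for the longitudinal and transversal profiles,
#' the contributing-peak amplitude ratios `cont_l_amp`/`cont_n_amp`, the mean
#' deviation `md`, and the mean `overlap` between adjacent fitted tangential
#' submovements. Amplitude fields of an empty polarity class are `NA`
#' (missing), not 0.
#'
#' @inheritParams extract_model_params
#' @return A one-row tibble.
#' @export
extract_evaluation_params <- function(traj, frame, threshold_frac = 0.1,
                                      smooth_hz = NULL,
                                      cont_window = c("per_peak", "mean_sigma")) {
  an <- analyze_movement(traj, frame, threshold_frac, smooth_hz, cont_window)
  amp_mean <- function(pk, pol) {
    a <- abs(pk$amplitude[pk$polarity == pol])
    if (length(a) == 0L) NA_real_ else mean(a)
  }
  cont_amp <- function(peaks_x) {
    m <- match_contributing(peaks_x, an$peaks_t, an$windows)
    if (all(is.na(m))) return(NA_real_)
    mean(abs(peaks_x$amplitude[!is.na(m)])) /
      mean(abs(an$peaks_t$amplitude[unique(m[!is.na(m)])]))
  }
  subs <- an$sig_fit$submovements
  ov <- if (nrow(subs) >= 2L) {
    ord <- order(subs$t_i)
    mean(vapply(seq_len(nrow(subs) - 1L), function(i) {
      submovement_overlap(subs[ord[i], ], subs[ord[i + 1L], ])
    }, numeric(1)))
  } else NA_real_
  tibble(
    mv_l = an$mv_l,
    a = mean(abs(an$peaks_t$amplitude)),
    a_l_pos = amp_mean(an$peaks_l, "pos"),
    a_l_neg = amp_mean(an$peaks_l, "neg"),
    a_n_pos = amp_mean(an$peaks_n, "pos"),
    a_n_neg = amp_mean(an$peaks_n, "neg"),
    npk_l_pos = sum(an$peaks_l$polarity == "pos"),
    npk_l_neg = sum(an$peaks_l$polarity == "neg"),
    npk_n_pos = sum(an$peaks_n$polarity == "pos"),
    npk_n_neg = sum(an$peaks_n$polarity == "neg"),
    cont_l_amp = cont_amp(an$peaks_l),
    cont_n_amp = cont_amp(an$peaks_n),
    md = an$md,
    overlap = ov
  )
}
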