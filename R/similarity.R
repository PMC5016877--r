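# Trajectory-similarity metrics used to validate simulated movements against
# real recordings: a normalized mean curve distance, its within-set version
# (intrinsic variability E_I), and the real-vs-simulated version (E_RS).

arc_length_resample <- function(traj, n_points) {
  s <- c(0, cumsum(sqrt(diff(traj$x)^2 + diff(traj$y)^2)))
  total <- s[length(s)]
  if (total <= 0) {
    abort("Zero-length path.", class = "reachkin_undefined_measure")
  }
  # collapse duplicate arc-length knots (stationary samples)
  keep <- !duplicated(s)
  u <- seq(0, total, length.out = n_points)
  list(x = approx(s[keep], traj$x[keep], xout = u)$y,
       y = approx(s[keep], traj$y[keep], xout = u)$y,
       length = total)
}

#' Normalized mean distance between two curves
#'
#' Both curves are resampled to `n_points` by arc length (so that differences
#' in speed do not masquerade as geometric dissimilarity); the mean pointwise
#' Euclidean distance is divided by the total path length of the reference
#' curve and expressed in percent.
#'
#' @param ref Reference trajectory (the real curve, whose path length
#'   normalizes the distance).
#' @param other Comparison trajectory.
#' @param n_points Resampling count (default 100).
#' @return Distance in percent.
#' @export
curve_distance <- function(ref, other, n_points = 100L) {
  n_points <- check_count(n_points, "n_points", min = 2L)
  a <- arc_length_resample(ref, n_points)
  b <- arc_length_resample(other, n_points)
  100 * mean(sqrt((a$x - b$x)^2 + (a$y - b$y)^2)) / a$length
}

direction_key <- function(traj) {
  m <- trajectory_meta(traj)
  paste(m$target %||% NA, m$direction %||% NA, sep = "/")
}

#' Intrinsic variability of a trajectory set (E_I)
#'
#' Mean [curve_distance()] over all ordered pairs of curves sharing a
#' movement direction (target x sense), reported per direction and pooled.
#' Directions with a single curve are excluded with a warning.
#'
#' @param trajs List of trajectories (metadata must carry `target` and
#'   `direction`).
#' @param n_points Resampling count.
#' @return A list of class `distance_report`: tibble `per_direction`
#'   (`direction`, `value`, `n_pairs`), `pooled` mean (%), `dispersion`
#'   (SD across directions, %), and `scheme`.
#' @export
intrinsic_variability <- function(trajs, n_points = 100L) {
  keys <- vapply(trajs, direction_key, character(1))
  per <- purrr::map_dfr(unique(keys), function(k) {
    grp <- trajs[keys == k]
    if (length(grp) < 2L) {
      warn(sprintf("Direction %s has a single curve; excluded.", k))
      return(NULL)
    }
    pairs <- expand.grid(i = seq_along(grp), j = seq_along(grp))
    pairs <- pairs[pairs$i != pairs$j, ]
    d <- mapply(function(i, j) curve_distance(grp[[i]], grp[[j]], n_points),
                pairs$i, pairs$j)
    tibble(direction = k, value = mean(d), n_pairs = nrow(pairs))
  })
  if (nrow(per) == 0L) {
    abort("No direction with at least two curves.",
          class = "reachkin_undefined_measure")
  }
  structure(list(per_direction = per, pooled = mean(per$value),
                 dispersion = sd(per$value), scheme = "all-ordered-pairs"),
            class = "distance_report")
}

#' Real-versus-simulated trajectory distance (E_RS)
#'
#' Mean [curve_distance()] over all real x simulated pairs within each
#' movement direction, with the real curve as reference; pooled mean and
#' dispersion across directions. Directions absent from the simulated set are
#' excluded with a warning.
#'
#' @param real,sim Lists of trajectories.
#' @param n_points Resampling count.
#' @return A `distance_report` (see [intrinsic_variability()]).
#' @export
real_sim_distance <- function(real, sim, n_points = 100L) {
  rk <- vapply(real, direction_key, character(1))
  sk <- vapply(sim, direction_key, character(1))
  per <- purrr::map_dfr(unique(rk), function(k) {
    rs <- real[rk == k]; ss <- sim[sk == k]
    if (length(ss) == 0L) {
      warn(sprintf("Direction %s has no simulated curves; excluded.", k))
      return(NULL)
    }
    d <- unlist(lapply(rs, function(r) {
      vapply(ss, function(s) curve_distance(r, s, n_points), numeric(1))
    }))
    tibble(direction = k, value = mean(d), n_pairs = length(d))
  })
  if (nrow(per) == 0L) {
    abort("No direction shared between the two sets.",
          class = "reachkin_undefined_measure")
  }
  structure(list(per_direction = per, pooled = mean(per$value),
                 dispersion = sd(per$value), scheme = "real-x-sim, ref = real"),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("<distance_report> pooled %.2f %% (SD %.2f), scheme: %s\n",
              x$pooled, x$dispersion, x$scheme))
  print(x$per_direction)
  invisible(x)
}
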