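#' Two-link arm geometry
#'
#' Planar shoulder-elbow model of the reaching arm. Defaults follow 50th
#' percentile adult male anthropometry: upper arm 0.282 m, and a distal
#' segment of 0.36 m (forearm 0.254 m + wrist-to-handle 0.076 m + handle
#' radius 0.03 m).
#'
#' @param l1 Upper-arm length (m).
#' @param l2 Forearm-plus-hand-to-handle length (m).
#' @return A list of class `arm_geometry`.
#' @export
arm_geometry <- function(l1 = 0.282, l2 = 0.254 + 0.076 + 0.03) {
  check_scalar_positive(l1, "l1")
  check_scalar_positive(l2, "l2")
  structure(list(l1 = l1, l2 = l2), class = "arm_geometry")
}

ik_k <- function(r2, l1, l2) {
  k2 <- (r2 + l1^2 + l2^2)^2 - 2 * (r2^2 + l1^4 + l2^4)
  # k is analytically >= 0 on the reachable annulus and exactly 0 on its
  # boundary; clamp rounding noise relative to the leading term.
  tol <- 1e-12 * (r2 + l1^2 + l2^2)^2
  if (abs(k2) < tol) k2 <- 0
  if (k2 < 0) return(NA_real_)
  sqrt(k2)
}

#' Inverse kinematics of the two-link arm
#'
#' Shoulder and elbow angles of a planar endpoint position `(x, y)` expressed
#' in the shoulder frame:
#' `theta1 = atan2(y, x) - atan2(k, x^2 + y^2 + l1^2 - l2^2)` and
#' `theta2 = atan2(k, x^2 + y^2 - l1^2 - l2^2) + theta1`, with
#' `k = sqrt((x^2 + y^2 + l1^2 + l2^2)^2 - 2((x^2 + y^2)^2 + l1^4 + l2^4))`.
#' Angles are absolute link orientations (elbow-right branch, `k >= 0`);
#' `theta2 - theta1` is the included elbow flexion.
#'
#' @param x,y Endpoint coordinates in the shoulder frame (m).
#' @param arm An [arm_geometry()].
#' @return Named numeric vector `c(theta1, theta2)` (rad).
#' @export
inverse_kinematics <- function(x, y, arm = arm_geometry()) {
  r2 <- x^2 + y^2
  r <- sqrt(r2)
  if (r > arm$l1 + arm$l2 + 1e-12 || r < abs(arm$l1 - arm$l2) - 1e-12) {
    abort(sprintf(
      "Point at radius %.4f m unreachable for links (%.3f, %.3f) m.",
      r, arm$l1, arm$l2), class = "reachkin_unreachable")
  }
  k <- ik_k(r2, arm$l1, arm$l2)
  if (is.na(k)) {
    abort(sprintf("Point at radius %.4f m unreachable (k imaginary).", r),
          class = "reachkin_unreachable")
  }
  th1 <- atan2(y, x) - atan2(k, r2 + arm$l1^2 - arm$l2^2)
  th2 <- atan2(k, r2 - arm$l1^2 - arm$l2^2) + th1
  c(theta1 = th1, theta2 = th2)
}

#' Forward kinematics of the two-link arm
#'
#' Endpoint position from absolute link orientations, the convention under
#' which [inverse_kinematics()] inverts exactly:
#' `x = l1 cos(theta1) + l2 cos(theta2)`, `y = l1 sin(theta1) + l2 sin(theta2)`.
#'
#' @param theta1,theta2 Shoulder and elbow (absolute) angles (rad).
#' @param arm An [arm_geometry()].
#' @return Named numeric vector `c(x, y)` (m).
#' @export
forward_kinematics <- function(theta1, theta2, arm = arm_geometry()) {
  c(x = arm$l1 * cos(theta1) + arm$l2 * cos(theta2),
    y = arm$l1 * sin(theta1) + arm$l2 * sin(theta2))
}

#' Joint-angle time series of a trajectory
#'
#' Samplewise inverse kinematics after translating workspace coordinates into
#' the shoulder frame. The default shoulder sits 0.45 m proximal to the
#' workspace origin along -y, which keeps the whole 14 cm target circle
#' inside the reachable annulus of the default arm.
#'
#' @param traj A [trajectory()].
#' @param shoulder Workspace coordinates of the shoulder (length-2, m).
#' @param arm An [arm_geometry()].
#' @return A tibble of class `joint_trace` with columns `t`, `theta1`,
#'   `theta2` (rad).
#' @export
joint_trace <- function(traj, shoulder = c(0, -0.45), arm = arm_geometry()) {
  xs <- traj$x - shoulder[1]
  ys <- traj$y - shoulder[2]
  r <- sqrt(xs^2 + ys^2)
  bad <- which(r > arm$l1 + arm$l2 + 1e-12 | r < abs(arm$l1 - arm$l2) - 1e-12)
  if (length(bad) > 0L) {
    abort(sprintf("Unreachable samples: %s",
                  paste(utils::head(bad, 10L), collapse = ", ")),
          class = "reachkin_unreachable")
  }
  th <- t(vapply(seq_len(nrow(traj)), function(i) {
    inverse_kinematics(xs[i], ys[i], arm)
  }, numeric(2)))
  if (nrow(th) > 1L && any(abs(diff(th[, 1])) > pi / 2 |
                           abs(diff(th[, 2])) > pi / 2)) {
    warn("Joint trace has a jump larger than pi/2 between adjacent samples.")
  }
  out <- tibble(t = traj$t, theta1 = th[, 1], theta2 = th[, 2])
  class(out) <- c("joint_trace", class(out))
  out
}

#' Normalized distance between two joint-angle trajectories
#'
#' Both traces are linearly resampled to `n_points`; the mean absolute angular
#' difference is normalized by the maximum angular excursion of the reference
#' (real) trace and expressed in percent. Computed per joint.
#'
#' @param real,sim `joint_trace`s (reference first).
#' @param n_points Resampling count (default 100).
#' @return Named numeric vector `c(shoulder, elbow)` in percent.
#' @export
angular_distance_pct <- function(real, sim, n_points = 100L) {
  n_points <- check_count(n_points, "n_points", min = 2L)
  res <- function(tr) {
    u <- seq(0, 1, length.out = n_points)
    g <- function(th) approx(seq(0, 1, length.out = length(th)), th, xout = u)$y
    list(th1 = g(tr$theta1), th2 = g(tr$theta2))
  }
  a <- res(real); b <- res(sim)
  one <- function(ra, sa) {
    exc <- max(ra) - min(ra)
    if (exc <= 0) {
      abort("Zero angular excursion in the reference trace.",
            class = "reachkin_undefined_measure")
    }
    100 * mean(abs(ra - sa)) / exc
  }
  c(shoulder = one(a$th1, b$th1), elbow = one(a$th2, b$th2))
}
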