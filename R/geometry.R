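#' Task geometry for the circular point-to-point protocol
#'
#' The assessment protocol places `n_targets` targets equally spaced on a
#' circle around a central start position; one full *turn* visits every target
#' outward (center to target) and backward (target to center), i.e.
#' `2 * n_targets` point-to-point movements. The default geometry is eight
#' targets on a 14 cm radius.
#'
#' @param center Numeric length-2, workspace coordinates of the circle center
#'   in meters.
#' @param radius Center-to-target distance D in meters (default 0.14).
#' @param n_targets Number of targets on the circle (default 8).
#' @return An object of class `task_geometry`: a list with `center`, `radius`,
#'   `n_targets` and a tibble `targets` with columns `target` (1-based index),
#'   `angle` (rad, counter-clockwise from the +x axis), `x`, `y` (m).
#' @examples
#' geo <- task_geometry()
#' nrow(enumerate_turn(geo))  # 16 movements per full turn
#' @export
task_geometry <- function(center = c(0, 0), radius = 0.14, n_targets = 8L) {
  check_scalar_positive(radius, "radius")
  n_targets <- check_count(n_targets, "n_targets")
  stopifnot(is.numeric(center), length(center) == 2L, all(is.finite(center)))
  angle <- (seq_len(n_targets) - 1) * 2 * pi / n_targets
  targets <- tibble(
    target = seq_len(n_targets),
    angle = angle,
    x = center[1] + radius * cos(angle),
    y = center[2] + radius * sin(angle)
  )
  structure(
    list(center = as.numeric(center), radius = radius,
         n_targets = n_targets, targets = targets),
    class = "task_geometry"
  )
}

#' @export
print.task_geometry <- function(x, ...) {
  cat(sprintf("<task_geometry> %d targets on a %.3g m circle centered at (%g, %g)\n",
              x$n_targets, x$radius, x$center[1], x$center[2]))
  invisible(x)
}

#' Enumerate the movements of one full turn
#'
#' @param geometry A [task_geometry()].
#' @return A tibble with one row per movement (`2 * n_targets` rows) and
#'   columns `target`, `direction` (`"outward"` or `"backward"`).
#' @export
enumerate_turn <- function(geometry) {
  stopifnot(inherits(geometry, "task_geometry"))
  tidyr::expand_grid(target = seq_len(geometry$n_targets),
                     direction = c("outward", "backward"))
}

#' Longitudinal/transversal frame for a movement
#'
#' The longitudinal (L) axis is the unit vector along the *theoretical path*,
#' the straight line from the movement start towards its goal: center to
#' target for outward movements, target to center for backward ones. The
#' transversal (N) axis is L rotated by +90 degrees.
#'
#' @param geometry A [task_geometry()].
#' @param target Target index (1-based).
#' @param direction `"outward"` or `"backward"`.
#' @return A list of class `ln_frame` with `origin` (movement start, m),
#'   `L` and `N` unit vectors, and `length` (the theoretical path length, m).
#' @export
ln_frame_for <- function(geometry, target, direction = c("outward", "backward")) {
  stopifnot(inherits(geometry, "task_geometry"))
  direction <- match.arg(direction)
  if (!is.numeric(target) || length(target) != 1L ||
      !target %in% seq_len(geometry$n_targets)) {
    abort("Unknown target index.", class = "reachkin_invalid_argument")
  }
  tgt <- c(geometry$targets$x[target], geometry$targets$y[target])
  ctr <- geometry$center
  if (direction == "outward") {
    origin <- ctr
    L <- (tgt - ctr) / geometry$radius
  } else {
    origin <- tgt
    L <- (ctr - tgt) / geometry$radius
  }
  N <- c(-L[2], L[1])  # +90 degree rotation
  structure(list(origin = origin, L = L, N = N, length = geometry$radius),
            class = "ln_frame")
}

#' Construct a planar trajectory
#'
#' A trajectory is a tibble of time-stamped planar samples with movement
#' metadata carried as attributes, so it pipes through dplyr verbs while the
#' extraction functions can still recover its task context.
#'
#' @param t Sample times (s), strictly increasing, at least 3 samples.
#' @param x,y Planar coordinates (m).
#' @param meta Named list of metadata (`subject`, `group`, `timepoint`,
#'   `target`, `direction`, `repetition`); missing entries allowed.
#' @return A tibble of class `reach_trajectory` with columns `t`, `x`, `y`.
#' @export
trajectory <- function(t, x, y, meta = list()) {
  if (length(t) < 3L) {
    abort("A trajectory needs at least 3 samples.",
          class = "reachkin_invalid_argument")
  }
  if (any(!is.finite(t)) || any(!is.finite(x)) || any(!is.finite(y))) {
    abort("Trajectory samples must be finite.",
          class = "reachkin_invalid_argument")
  }
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1L
    abort(sprintf("Time must be strictly increasing; violated at row %d.", bad),
          class = "reachkin_format_error")
  }
  out <- tibble(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y))
  attr(out, "meta") <- meta
  class(out) <- c("reach_trajectory", class(out))
  out
}

#' @rdname trajectory
#' @param traj A `reach_trajectory`.
#' @export
trajectory_meta <- function(traj) attr(traj, "meta") %||% list()

#' Resample a trajectory onto a uniform time grid
#'
#' Linear interpolation onto `n_points` equally spaced times spanning the
#' original time range; the first and last samples are preserved exactly.
#'
#' @param traj A [trajectory()].
#' @param n_points Number of output samples (>= 2).
#' @return A resampled `reach_trajectory` with the same metadata.
#' @export
resample_uniform <- function(traj, n_points = 100L) {
  n_points <- check_count(n_points, "n_points", min = 2L)
  if (nrow(traj) < 2L) {
    abort("Need at least 2 samples to resample.",
          class = "reachkin_invalid_argument")
  }
  tt <- seq(traj$t[1], traj$t[nrow(traj)], length.out = n_points)
  out <- tibble(
    t = tt,
    x = approx(traj$t, traj$x, xout = tt, rule = 2)$y,
    y = approx(traj$t, traj$y, xout = tt, rule = 2)$y
  )
  attr(out, "meta") <- trajectory_meta(traj)
  class(out) <- c("reach_trajectory", class(out))
  out
}

#' Read and write trajectory CSV files
#'
#' The on-disk format is a plain CSV with columns `t_s,x_m,y_m` preceded by
#' `# key=value` metadata lines (subject, group, timepoint, target, direction,
#' repetition). A write/read round trip reproduces samples to better than
#' 1e-9 and the full metadata.
#'
#' @param path File path.
#' @return `read_trajectory_csv()` returns a `reach_trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "reachkin_format_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    abort("Empty trajectory file.", class = "reachkin_format_error")
  }
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(kv, 1, eq - 1))
      val <- trimws(substr(kv, eq + 1, nchar(kv)))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) {
    abort("Trajectory file has no data rows.", class = "reachkin_format_error")
  }
  hdr <- strsplit(body[1], ",")[[1]]
  if (!all(c("t_s", "x_m", "y_m") %in% hdr)) {
    abort("Trajectory CSV must have columns t_s,x_m,y_m.",
          class = "reachkin_format_error")
  }
  df <- readr::read_csv(I(paste(body, collapse = "\n")),
                        show_col_types = FALSE, progress = FALSE)
  bad <- which(diff(df$t_s) <= 0)
  if (length(bad) > 0L) {
    abort(sprintf("Time column not strictly increasing at row %d.", bad[1] + 1L),
          class = "reachkin_format_error")
  }
  trajectory(df$t_s, df$x_m, df$y_m, meta = meta)
}

#' @rdname read_trajectory_csv
#' @param traj A `reach_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  meta <- trajectory_meta(traj)
  hdr <- vapply(names(meta), function(k) sprintf("# %s=%s", k, meta[[k]]),
                character(1))
  rows <- sprintf("%.12g,%.12g,%.12g", traj$t, traj$x, traj$y)
  writeLines(c(hdr, "t_s,x_m,y_m", rows), path)
  invisible(path)
}
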