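# Programmatic fixtures shared across the suite.

straight_trajectory <- function(speed = 0.1, t_dur = 1, n = 201,
                                angle = 0, origin = c(0, 0), meta = list()) {
  tt <- seq(0, t_dur, length.out = n)
  trajectory(tt,
             origin[1] + speed * tt * cos(angle),
             origin[2] + speed * tt * sin(angle),
             meta = meta)
}

gaussian_speed_trajectory <- function(amps, times, sigmas, t_dur = 1,
                                      hz = 200, angle = 0, lateral = NULL,
                                      origin = c(0, 0), meta = list()) {
  tt <- seq(0, t_dur, by = 1 / hz)
  v <- rowSums(sapply(seq_along(amps), function(i) {
    amps[i] * exp(-((tt - times[i]) / (sqrt(2) * sigmas[i]))^2)
  }))
  xl <- pracma::cumtrapz(tt, v)[, 1]
  xn <- if (is.null(lateral)) rep(0, length(tt)) else lateral(tt)
  trajectory(tt,
             origin[1] + xl * cos(angle) - xn * sin(angle),
             origin[2] + xl * sin(angle) + xn * cos(angle),
             meta = meta)
}

rotate_trajectory <- function(traj, angle, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  xy <- cbind(traj$x, traj$y) %*% t(R)
  trajectory(traj$t, xy[, 1] + shift[1], xy[, 2] + shift[2],
             meta = trajectory_meta(traj))
}

rotate_frame <- function(frame, angle, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  structure(list(origin = as.numeric(R %*% frame$origin + shift),
                 L = as.numeric(R %*% frame$L),
                 N = as.numeric(R %*% frame$N),
                 length = frame$length),
            class = "ln_frame")
}

# Fraction of planted variables assigned to the majority factor of their block.
block_assignment_score <- function(assignment, block) {
  correct <- 0
  for (j in unique(block)) {
    fs <- assignment$factor[block == j]
    lab <- fs[fs != "shared"]
    maj <- if (length(lab) > 0) names(sort(table(lab), decreasing = TRUE))[1]
           else "shared"
    correct <- correct + sum(fs == maj)
  }
  correct / length(block)
}

quick_planar_spec <- function(...) {
  args <- utils::modifyList(
    list(mv_n = 0.005, cont_l = 1, cont_n = 1, ratio_amp_l = 0.9,
         ratio_amp_n = 0.1, ratio_npk = 1), list(...))
  do.call(planar_spec, args)
}
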