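# ggplot2 autoplot methods for the main result types.

#' @method autoplot reach_trajectory
#' @export
autoplot.reach_trajectory <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", title = "Endpoint path") +
    ggplot2::theme_minimal()
}

#' @method autoplot speed_profile
#' @export
autoplot.speed_profile <- function(object, ...) {
  axis <- attr(object, "axis")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "speed (m/s)",
                  title = sprintf("%s speed profile", axis)) +
    ggplot2::theme_minimal()
}

#' @method autoplot reach_cohort
#' @export
autoplot.reach_cohort <- function(object, ...) {
  df <- purrr::map_dfr(seq_along(object$trajectories), function(i) {
    tr <- object$trajectories[[i]]
    m <- trajectory_meta(tr)
    dplyr::mutate(as_tibble(tr), movement = i,
                  direction = m$direction %||% NA_character_)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$movement,
                                   colour = .data$direction)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", title = "Simulated cohort") +
    ggplot2::theme_minimal()
}

#' @method autoplot recovery_fa
#' @export
autoplot.recovery_fa <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$parameter,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(title = "Promax-rotated loadings") +
    ggplot2::theme_minimal()
}

#' @method autoplot timecourse_fit
#' @export
autoplot.timecourse_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$score)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(y = "factor score",
                  title = sprintf("Time course: %s fit", object$model)) +
    ggplot2::theme_minimal()
}
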