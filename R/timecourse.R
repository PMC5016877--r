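# Time-course fitting of factor scores along the rehabilitation sessions:
# straight line, exponential decay, or double-exponential decay, selected by
# the Bayesian Information Criterion.

fit_line <- function(s, y) {
  m <- lm(y ~ s)
  list(model = "line", coef = c(a = unname(coef(m)[1]), m = unname(coef(m)[2])),
       fitted = unname(stats::fitted(m)), rss = sum(stats::resid(m)^2),
       k = 2L)
}

fit_exp <- function(s, y, tau_starts = c(1, 5, 15)) {
  best <- NULL
  for (tau0 in tau_starts) {
    fit <- tryCatch({
      m <- minpack.lm::nlsLM(
        y ~ a + b * exp(-s / tau), start = list(a = mean(y), b = y[1] - mean(y),
                                                tau = tau0),
        lower = c(a = -Inf, b = -Inf, tau = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      co <- coef(m)
      list(model = "exponential",
           coef = c(a = unname(co[["a"]]), b = unname(co[["b"]]),
                    tau = unname(co[["tau"]])),
           fitted = unname(stats::fitted(m)),
           rss = sum(stats::resid(m)^2), k = 3L)
    }, error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$rss < best$rss)) best <- fit
  }
  best
}

fit_dexp <- function(s, y, tau_starts = c(1, 5, 15)) {
  pairs <- expand.grid(t1 = tau_starts, t2 = tau_starts)
  pairs <- pairs[pairs$t1 < pairs$t2, ]
  rng <- diff(range(y))
  best <- NULL
  for (i in seq_len(nrow(pairs))) {
    fit <- tryCatch({
      m <- minpack.lm::nlsLM(
        y ~ a + b * exp(-s / tau1) + c * exp(-s / tau2),
        start = list(a = mean(y), b = rng, c = rng / 2,
                     tau1 = pairs$t1[i], tau2 = pairs$t2[i]),
        lower = c(a = -Inf, b = -Inf, c = -Inf, tau1 = 1e-3, tau2 = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 300))
      co <- coef(m)
      tau <- sort(c(co[["tau1"]], co[["tau2"]]))
      list(model = "double_exponential",
           coef = c(a = unname(co[["a"]]),
                    b = unname(if (co[["tau1"]] <= co[["tau2"]]) co[["b"]] else co[["c"]]),
                    c = unname(if (co[["tau1"]] <= co[["tau2"]]) co[["c"]] else co[["b"]]),
                    tau1 = tau[1], tau2 = tau[2]),
           fitted = unname(stats::fitted(m)),
           rss = sum(stats::resid(m)^2), k = 5L)
    }, error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$rss < best$rss)) best <- fit
  }
  best
}

#' Fit and select the time course of a factor score
#'
#' Fits a straight line `a + m s`, an exponential decay
#' `a + b exp(-s / tau)`, and a double-exponential decay
#' `a + b exp(-s / tau1) + c exp(-s / tau2)` (`tau1 < tau2`) to per-session
#' scores and selects the best by BIC, computed as
#' `n log(RSS / n) + k log(n)` with `k` the number of fitted parameters.
#' Exponential fits use multi-start nonlinear least squares; fits that fail
#' to converge are dropped from the selection with a warning.
#'
#' @param data Data frame with session index and score columns, or a numeric
#'   vector of scores (sessions then default to `1:length`).
#' @param session,score Column names (defaults `"session"`, `"score"`).
#' @param tau_starts Multi-start time constants (sessions).
#' @return An object of class `timecourse_fit`: `model`, `coef`, `rss`,
#'   `bic`, `candidates` (tibble of all converged fits), `data`.
#' @export
fit_time_course <- function(data, session = "session", score = "score",
                            tau_starts = c(1, 5, 15)) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- tibble(session = seq_along(data), score = as.numeric(data))
    session <- "session"; score <- "score"
  }
  s <- as.numeric(data[[session]])
  y <- as.numeric(data[[score]])
  ok <- is.finite(s) & is.finite(y)
  s <- s[ok]; y <- y[ok]
  n <- length(y)
  if (n < 5L) {
    abort("Need at least 5 sessions to fit a time course.",
          class = "reachkin_insufficient_data")
  }
  fits <- list(fit_line(s, y), fit_exp(s, y, tau_starts),
               fit_dexp(s, y, tau_starts))
  dropped <- vapply(fits, is.null, logical(1))
  if (any(dropped[2:3])) {
    warn("Some exponential fits failed to converge and were dropped from BIC selection.")
  }
  fits <- fits[!dropped]
  bic <- vapply(fits, function(f) {
    rss <- max(f$rss, 1e-300)  # guard log of an exact fit
    n * log(rss / n) + f$k * log(n)
  }, numeric(1))
  cand <- tibble(
    model = vapply(fits, `[[`, character(1), "model"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    k = vapply(fits, function(f) as.numeric(f$k), numeric(1)),
    bic = bic)
  best <- fits[[which.min(bic)]]
  structure(list(model = best$model, coef = best$coef, rss = best$rss,
                 bic = min(bic), candidates = cand,
                 data = tibble(session = s, score = y),
                 fitted = best$fitted),
            class = "timecourse_fit")
}

#' @export
print.timecourse_fit <- function(x, ...) {
  cat(sprintf("<timecourse_fit> %s (BIC %.2f)\n", x$model, x$bic))
  print(round(x$coef, 4))
  invisible(x)
}

#' @method tidy timecourse_fit
#' @export
tidy.timecourse_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @method glance timecourse_fit
#' @export
glance.timecourse_fit <- function(x, ...) {
  tibble(model = x$model, rss = x$rss, bic = x$bic,
         n = nrow(x$data))
}

#' Average factor scores per session
#'
#' Averages each factor's scores across patients within a session, the panel
#' summarization used before time-course fitting.
#'
#' @param scores Data frame with a `session` column and one column per
#'   factor score.
#' @param session Session column name.
#' @return A tibble with one row per session, factors averaged.
#' @export
session_scores <- function(scores, session = "session") {
  scores <- as_tibble(scores)
  dplyr::summarise(dplyr::group_by(scores, !!rlang::sym(session)),
                   dplyr::across(dplyr::where(is.numeric), mean),
                   .groups = "drop")
}
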