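# Factor analysis of model-based parameter panels: maximum-likelihood
# extraction with promax (oblique) rotation, quantitative retention rules,
# and loading-threshold assignment of parameters to factors.

#' Factor analysis of a kinematic parameter panel
#'
#' Maximum-likelihood factor analysis with promax rotation on a panel of
#' observations x parameters. The number of retained factors is the smallest
#' k whose cumulative explained variance reaches `cum_pct` with every
#' retained factor individually explaining more than `ind_pct` of the total
#' variance (variance shares are sums of squared rotated loadings over the
#' number of variables; with an oblique rotation these are approximate
#' shares, reported as such). When no k up to `max_factors` satisfies the
#' rules the panel has no compact factor structure and the fit with the
#' best cumulative share is returned flagged.
#'
#' @param panel Data frame or matrix (observations x parameters); columns
#'   are standardized internally.
#' @param cum_pct Cumulative variance retention threshold (default 70).
#' @param ind_pct Individual variance retention threshold (default 5).
#' @param max_factors Largest k tried (default limited by the
#'   degrees-of-freedom bound).
#' @return An object of class `recovery_fa`: `loadings` (parameters x k),
#'   `variance_pct`, `cumulative_pct`, `scores` (regression scores),
#'   `n_factors`, `compact_structure`, `rotation`.
#' @export
run_factor_analysis <- function(panel, cum_pct = 70, ind_pct = 5,
                                max_factors = NULL) {
  panel <- as.data.frame(panel)
  num <- vapply(panel, is.numeric, logical(1))
  panel <- panel[num]
  p <- ncol(panel)
  n <- nrow(panel)
  const <- names(panel)[vapply(panel, function(x) sd(x) == 0, logical(1))]
  if (length(const) > 0L) {
    abort(sprintf("Constant column(s): %s", paste(const, collapse = ", ")),
          class = "reachkin_schema_error")
  }
  if (n < 3 * p) {
    abort(sprintf("Need at least 3x more observations (%d) than parameters (%d).",
                  n, p), class = "reachkin_invalid_argument")
  }
  # Ledermann bound on identifiable factor counts
  kmax_df <- floor((2 * p + 1 - sqrt(8 * p + 1)) / 2)
  kmax <- min(max_factors %||% kmax_df, kmax_df)
  x <- scale(as.matrix(panel))

  fit_k <- function(k) {
    fa <- tryCatch(
      factanal(x, factors = k, rotation = if (k > 1) "promax" else "none",
               scores = "regression"),
      error = function(e) NULL)
    if (is.null(fa)) return(NULL)
    L <- unclass(fa$loadings)
    shares <- 100 * colSums(L^2) / p
    ord <- order(shares, decreasing = TRUE)
    list(fa = fa, loadings = L[, ord, drop = FALSE],
         scores = fa$scores[, ord, drop = FALSE],
         shares = shares[ord])
  }

  best <- NULL
  chosen <- NULL
  for (k in seq_len(kmax)) {
    res <- fit_k(k)
    if (is.null(res)) next
    cum <- cumsum(res$shares)
    if (is.null(best) || max(cum) > max(cumsum(best$shares))) best <- res
    if (max(cum) >= cum_pct && all(res$shares > ind_pct)) {
      chosen <- res
      break
    }
  }
  if (is.null(chosen) && is.null(best)) {
    abort("Maximum-likelihood factor analysis failed for every factor count; try fewer factors or more observations.",
          class = "reachkin_convergence")
  }
  compact <- !is.null(chosen)
  res <- chosen %||% best
  k <- ncol(res$loadings)
  colnames(res$loadings) <- paste0("factor", seq_len(k))
  colnames(res$scores) <- paste0("factor", seq_len(k))
  structure(list(
    loadings = res$loadings,
    variance_pct = unname(res$shares),
    cumulative_pct = unname(cumsum(res$shares)),
    scores = res$scores,
    n_factors = k,
    compact_structure = compact,
    rotation = if (k > 1) "promax" else "none",
    n_obs = n
  ), class = "recovery_fa")
}

#' @export
print.recovery_fa <- function(x, ...) {
  cat(sprintf("<recovery_fa> %d factor(s) (%s), cumulative variance %.1f %%%s\n",
              x$n_factors, x$rotation, max(x$cumulative_pct),
              if (x$compact_structure) "" else " [no compact structure]"))
  print(round(x$loadings, 2))
  invisible(x)
}

#' Assign parameters to factors by loading threshold
#'
#' Each parameter is assigned to the factor on which its absolute loading is
#' largest, provided that loading exceeds `threshold`; otherwise it is
#' labelled `"shared"`.
#'
#' @param model A [run_factor_analysis()] fit.
#' @param threshold Absolute-loading threshold (default 0.6).
#' @return A tibble with `parameter`, `factor` (e.g. `"factor1"` or
#'   `"shared"`), `loading` (the maximal absolute loading, signed).
#' @export
assign_loadings <- function(model, threshold = 0.6) {
  stopifnot(inherits(model, "recovery_fa"))
  L <- model$loadings
  purrr::map_dfr(seq_len(nrow(L)), function(i) {
    j <- which.max(abs(L[i, ]))
    tibble(parameter = rownames(L)[i],
           factor = if (abs(L[i, j]) > threshold) colnames(L)[j] else "shared",
           loading = L[i, j])
  })
}

#' Simulate a parameter panel with planted factor structure
#'
#' Observations are generated from independent standard-normal factor scores:
#' each variable loads `loading` on exactly one of the block factors plus
#' independent Gaussian noise. Used to verify that extraction, rotation and
#' retention recover a known block structure.
#'
#' @param n Number of observations.
#' @param blocks List of integer vectors: variable indices per factor
#'   (default three blocks of sizes 4, 3, 3 over 10 variables).
#' @param loading Within-block loading (default 0.8).
#' @param noise_sd Residual standard deviation (default 0.3).
#' @return List: `panel` (tibble, variables `v1...`), `block` (integer vector
#'   giving each variable's generating factor).
#' @export
simulate_factor_panel <- function(n = 500L, blocks = list(1:4, 5:7, 8:10),
                                  loading = 0.8, noise_sd = 0.3) {
  p <- max(unlist(blocks))
  k <- length(blocks)
  f <- matrix(rnorm(n * k), n, k)
  block_of <- integer(p)
  x <- matrix(0, n, p)
  for (j in seq_len(k)) {
    for (v in blocks[[j]]) {
      block_of[v] <- j
      x[, v] <- loading * f[, j] + rnorm(n, sd = noise_sd)
    }
  }
  colnames(x) <- paste0("v", seq_len(p))
  list(panel = as_tibble(x), block = block_of)
}

#' @method tidy recovery_fa
#' @export
tidy.recovery_fa <- function(x, ...) {
  L <- x$loadings
  tidyr::pivot_longer(
    dplyr::mutate(as_tibble(L), parameter = rownames(L)),
    -"parameter", names_to = "factor", values_to = "loading")
}

#' @method glance recovery_fa
#' @export
glance.recovery_fa <- function(x, ...) {
  tibble(n_factors = x$n_factors,
         cumulative_pct = max(x$cumulative_pct),
         compact_structure = x$compact_structure,
         rotation = x$rotation, n_obs = x$n_obs)
}
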