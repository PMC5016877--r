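# Cohort-level machinery: empirical parameter distributions, cohort
# simulation, the one-parameter-at-a-time sensitivity scan, and fully
# synthetic ground-truth cohorts for testing the extraction pipeline.

model_param_fields <- c("npk", "mean_sigma", "t_dur", "mv", "mv_n",
                        "cont_l", "cont_n", "ratio_amp_l", "ratio_amp_n",
                        "ratio_npk")

#' Estimate empirical parameter distributions
#'
#' Pools extracted model-based parameter values per group x timepoint
#' (across repetitions, subjects and movement directions), keeping the raw
#' pools for resampling; no parametric family is fitted.
#'
#' @param param_table Data frame with the ten model-based parameter columns
#'   plus the grouping columns.
#' @param grouping Character vector of grouping columns (default
#'   `c("group", "timepoint")`).
#' @return An object of class `param_distributions`: list with `pools`
#'   (named list keyed by the grouping values, each a list of numeric
#'   vectors per field) and `summary` (tibble of per-key, per-field mean and
#'   deciles).
#' @export
estimate_distributions <- function(param_table,
                                   grouping = c("group", "timepoint")) {
  missing_cols <- setdiff(c(model_param_fields, grouping),
                          names(param_table))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Missing columns: %s", paste(missing_cols, collapse = ", ")),
          class = "reachkin_schema_error")
  }
  key <- do.call(paste, c(param_table[grouping], sep = "/"))
  pools <- lapply(split(param_table, key), function(df) {
    lapply(df[model_param_fields], as.numeric)
  })
  summary <- purrr::map_dfr(names(pools), function(k) {
    purrr::map_dfr(model_param_fields, function(f) {
      x <- pools[[k]][[f]]
      tibble(key = k, field = f, n = length(x), mean = mean(x),
             q10 = quantile(x, 0.1, names = FALSE),
             q50 = quantile(x, 0.5, names = FALSE),
             q90 = quantile(x, 0.9, names = FALSE))
    })
  })
  structure(list(pools = pools, grouping = grouping, summary = summary),
            class = "param_distributions")
}

pool_key <- function(dist, group, timepoint) {
  k <- paste(c(group, timepoint), collapse = "/")
  if (!k %in% names(dist$pools)) {
    abort(sprintf("No parameter pool for key '%s'.", k),
          class = "reachkin_invalid_argument")
  }
  k
}

specs_from_values <- function(vals, min_gap_factor = 2) {
  npk <- max(1L, as.integer(round(vals[["npk"]])))
  tang <- tangential_spec(npk, vals[["mean_sigma"]], vals[["t_dur"]],
                          vals[["mv"]])
  counts <- derive_ln_counts(max(vals[["ratio_npk"]], 1e-6), npk)
  plan <- planar_spec(
    mv_n = max(0, vals[["mv_n"]]),
    cont_l = min(max(0L, as.integer(round(vals[["cont_l"]]))),
                 counts[["npk_l"]], npk),
    cont_n = min(max(0L, as.integer(round(vals[["cont_n"]]))),
                 counts[["npk_n"]], npk),
    ratio_amp_l = max(0, vals[["ratio_amp_l"]]),
    ratio_amp_n = max(0, vals[["ratio_amp_n"]]),
    ratio_npk = max(vals[["ratio_npk"]], 1e-6)
  )
  if ((npk - 1) * min_gap_factor * vals[["mean_sigma"]] > vals[["t_dur"]]) {
    abort("Peak spacing constraint infeasible for the drawn parameters.",
          class = "reachkin_infeasible")
  }
  list(tangential = tang, planar = plan)
}

#' Draw a parameter set from empirical distributions
#'
#' Each field is drawn independently by resampling (with replacement) from
#' its pool; joint draws violating the peak-spacing feasibility constraint
#' are rejected and redrawn (up to `max_attempts`). Contributing-peak counts
#' are clipped to the drawn peak counts.
#'
#' @param dist A [estimate_distributions()] object.
#' @param group,timepoint Pool key values.
#' @param max_attempts Redraw budget for jointly infeasible draws.
#' @return List with `tangential` ([tangential_spec()]), `planar`
#'   ([planar_spec()]) and `values` (the drawn numbers, named).
#' @export
sample_params <- function(dist, group, timepoint = NULL,
                          max_attempts = 1000L) {
  stopifnot(inherits(dist, "param_distributions"))
  k <- pool_key(dist, group, timepoint)
  pool <- dist$pools[[k]]
  for (i in seq_len(max_attempts)) {
    vals <- vapply(model_param_fields, function(f) {
      x <- pool[[f]]
      if (length(x) == 1L) x else sample(x, 1L)
    }, numeric(1))
    specs <- tryCatch(specs_from_values(vals), reachkin_infeasible = function(e) NULL,
                      reachkin_invalid_argument = function(e) NULL)
    if (!is.null(specs)) return(c(specs, list(values = vals)))
  }
  abort("Could not draw a feasible parameter set: the peak-spacing constraint (npk, mean_sigma vs t_dur) is persistently binding.",
        class = "reachkin_infeasible")
}

#' Configuration of a synthetic ground-truth cohort
#'
#' Generating distributions (independent uniforms; integer-uniform for
#' counts) for every model-based parameter, with three presets reflecting
#' plausible study conditions: `"impaired"` (a severely affected early
#' timepoint: many submovements, long slow movements, large transversal
#' activity), `"recovered"` (late timepoint: few submovements, short faster
#' movements, small transversal activity), and `"well_separated"` (a
#' near-straight, identifiable regime used by the parameter-recovery
#' harness: widely spaced peaks, full longitudinal coupling, mean tangential
#' speed tied to path length over duration).
#'
#' @param profile Preset name.
#' @param ... Named overrides of individual entries (each a length-2 range
#'   `c(min, max)` or a single value for a point mass).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(profile = c("impaired", "recovered",
                                      "well_separated"), ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    impaired = list(
      npk = c(3L, 8L), t_dur = c(2, 6), mean_sigma = c(0.05, 0.09),
      mv = c(0.03, 0.08), mv_n = c(0.01, 0.03),
      ratio_amp_l = c(0.7, 1.0), ratio_amp_n = c(0.2, 0.5),
      ratio_npk = c(0.8, 1.2), cont_l = c(1L, 8L), cont_n = c(0L, 8L),
      tie_mv_to_path = FALSE, min_gap_factor = 2),
    recovered = list(
      npk = c(1L, 3L), t_dur = c(1, 2.5), mean_sigma = c(0.08, 0.15),
      mv = c(0.08, 0.15), mv_n = c(0.005, 0.015),
      ratio_amp_l = c(0.8, 1.1), ratio_amp_n = c(0.05, 0.2),
      ratio_npk = c(0.8, 1.2), cont_l = c(1L, 3L), cont_n = c(0L, 3L),
      tie_mv_to_path = FALSE, min_gap_factor = 2),
    well_separated = list(
      npk = c(1L, 3L), t_dur = c(2, 4), mean_sigma = c(0.06, 0.1),
      mv = NA, mv_n = c(0.001, 0.003),
      ratio_amp_l = c(0.9, 1.0), ratio_amp_n = c(0.02, 0.05),
      ratio_npk = 1, cont_l = NA, cont_n = c(0L, 3L),
      tie_mv_to_path = TRUE, min_gap_factor = 4)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown cohort_config entries: %s",
                  paste(bad, collapse = ", ")),
          class = "reachkin_invalid_argument")
  }
  cfg <- utils::modifyList(base, over)
  cfg$profile <- profile
  structure(cfg, class = "cohort_config")
}

draw_range <- function(r, integer = FALSE) {
  if (length(r) == 1L) return(r)
  if (integer) sample(seq.int(r[1], r[2]), 1L) else runif(1, r[1], r[2])
}

draw_config_values <- function(cfg, radius) {
  npk <- draw_range(cfg$npk, integer = TRUE)
  t_dur <- draw_range(cfg$t_dur)
  mean_sigma <- draw_range(cfg$mean_sigma)
  mv <- if (isTRUE(cfg$tie_mv_to_path)) radius / t_dur else draw_range(cfg$mv)
  cont_l <- if (length(cfg$cont_l) == 1L && is.na(cfg$cont_l)) npk else
    min(npk, draw_range(cfg$cont_l, integer = TRUE))
  cont_n <- min(npk, draw_range(cfg$cont_n, integer = TRUE))
  c(npk = npk, mean_sigma = mean_sigma, t_dur = t_dur, mv = mv,
    mv_n = draw_range(cfg$mv_n), cont_l = cont_l, cont_n = cont_n,
    ratio_amp_l = draw_range(cfg$ratio_amp_l),
    ratio_amp_n = draw_range(cfg$ratio_amp_n),
    ratio_npk = draw_range(cfg$ratio_npk))
}

draw_one <- function(source, geometry, group, timepoint, max_attempts = 1000L) {
  if (inherits(source, "param_distributions")) {
    return(sample_params(source, group, timepoint))
  }
  stopifnot(inherits(source, "cohort_config"))
  for (i in seq_len(max_attempts)) {
    vals <- draw_config_values(source, geometry$radius)
    specs <- tryCatch(
      specs_from_values(vals, min_gap_factor = source$min_gap_factor %||% 2),
      reachkin_infeasible = function(e) NULL)
    if (!is.null(specs)) return(c(specs, list(values = vals)))
  }
  abort("Infeasible cohort configuration: no valid draw in the attempt budget.",
        class = "reachkin_infeasible")
}

#' Simulate a cohort of point-to-point movements
#'
#' Draws one parameter set per movement (from empirical pools or a
#' [cohort_config()]) and simulates the movements cycling through the turn
#' structure (all targets, outward then backward). The generating parameters
#' are logged per movement as ground truth.
#'
#' @param source A [estimate_distributions()] object or a [cohort_config()].
#' @param n_movements Number of movements to simulate.
#' @param geometry A [task_geometry()].
#' @param group,timepoint Pool key (used when `source` is empirical).
#' @param seed Optional integer seed for reproducibility.
#' @param sampling_hz Simulation grid rate.
#' @return A list of class `reach_cohort`: `params` (tibble of generating
#'   values + `movement`, `target`, `direction`) and `trajectories` (list of
#'   `reach_trajectory`).
#' @export
simulate_cohort <- function(source, n_movements, geometry = task_geometry(),
                            group = NULL, timepoint = NULL, seed = NULL,
                            sampling_hz = 200) {
  if (!is.null(seed)) set.seed(seed)
  turn <- enumerate_turn(geometry)
  gap_factor <- if (inherits(source, "cohort_config"))
    source$min_gap_factor %||% 2 else 2
  rows <- vector("list", n_movements)
  trajs <- vector("list", n_movements)
  for (m in seq_len(n_movements)) {
    mv_row <- turn[((m - 1L) %% nrow(turn)) + 1L, ]
    draw <- draw_one(source, geometry, group, timepoint)
    traj <- simulate_movement(
      draw$tangential, draw$planar, geometry,
      target = mv_row$target, direction = mv_row$direction,
      meta = list(movement = m), sampling_hz = sampling_hz,
      min_gap_factor = gap_factor)
    rows[[m]] <- tibble(movement = m, target = mv_row$target,
                        direction = mv_row$direction, !!!as.list(draw$values))
    trajs[[m]] <- traj
  }
  structure(list(params = dplyr::bind_rows(rows), trajectories = trajs,
                 geometry = geometry),
            class = "reach_cohort")
}

#' Generate a fully synthetic ground-truth cohort
#'
#' Convenience wrapper around [simulate_cohort()] for a [cohort_config()]
#' source: parameters are drawn from the configured generating distributions
#' and the per-movement ground truth is returned alongside the trajectories.
#'
#' @param config A [cohort_config()].
#' @param n_movements Number of movements (default one full turn, 16).
#' @param geometry A [task_geometry()].
#' @param seed Optional seed.
#' @param sampling_hz Simulation grid rate.
#' @return A `reach_cohort` (see [simulate_cohort()]).
#' @export
generate_ground_truth_cohort <- function(config, n_movements = 16L,
                                         geometry = task_geometry(),
                                         seed = NULL, sampling_hz = 200) {
  stopifnot(inherits(config, "cohort_config"))
  simulate_cohort(config, n_movements, geometry, seed = seed,
                  sampling_hz = sampling_hz)
}

#' Extract model-based parameters from every movement of a cohort
#'
#' @param cohort A `reach_cohort`.
#' @param ... Passed to [extract_model_params()].
#' @return A tibble: one row per movement, metadata plus the ten parameters.
#' @export
extract_cohort_params <- function(cohort, ...) {
  stopifnot(inherits(cohort, "reach_cohort"))
  purrr::map_dfr(seq_along(cohort$trajectories), function(m) {
    traj <- cohort$trajectories[[m]]
    meta <- trajectory_meta(traj)
    frame <- ln_frame_for(cohort$geometry, meta$target, meta$direction)
    pars <- tryCatch(extract_model_params(traj, frame, ...),
                     reachkin_degenerate_movement = function(e) NULL)
    if (is.null(pars)) return(NULL)
    dplyr::bind_cols(tibble(movement = m, target = meta$target,
                            direction = meta$direction), pars)
  })
}

#' One-parameter-at-a-time sensitivity scan
#'
#' For each model-based parameter in turn, ten variations are taken across
#' its pool (quantiles over the central 90 percent) while the other
#' parameters stay at their pool means; a small batch of movements is
#' simulated per variation and compared (E_RS) against a reference batch
#' simulated at the all-means parameter set. Infeasible cells are flagged and
#' the scan continues.
#'
#' @param dist A [estimate_distributions()] object.
#' @param group,timepoint Pool key.
#' @param geometry A [task_geometry()].
#' @param n_per_cell Movements per variation (default 4).
#' @param probs Quantile positions of the ten variations.
#' @param seed Optional seed.
#' @return A tibble with one row per (parameter, variation): `parameter`,
#'   `decile`, `value`, `feasible`, `e_rs`, `mean_npk`, `mean_mv`, `mean_md`,
#'   `mean_mv_tangential` (mean speed of the tangential-stage profiles, the
#'   level at which the MV parameter acts).
#' @export
sensitivity_scan <- function(dist, group = NULL, timepoint = NULL,
                             geometry = task_geometry(), n_per_cell = 4L,
                             probs = seq(0.05, 0.95, length.out = 10L),
                             seed = NULL) {
  stopifnot(inherits(dist, "param_distributions"))
  if (!is.null(seed)) set.seed(seed)
  k <- pool_key(dist, group, timepoint)
  pool <- dist$pools[[k]]
  means <- vapply(pool, mean, numeric(1))
  turn <- enumerate_turn(geometry)

  simulate_batch <- function(vals) {
    specs <- specs_from_values(vals)
    lapply(seq_len(n_per_cell), function(m) {
      row <- turn[((m - 1L) %% nrow(turn)) + 1L, ]
      simulate_movement(specs$tangential, specs$planar, geometry,
                        target = row$target, direction = row$direction)
    })
  }
  batch_summary <- function(trajs) {
    pars <- purrr::map_dfr(trajs, function(tr) {
      meta <- trajectory_meta(tr)
      frame <- ln_frame_for(geometry, meta$target, meta$direction)
      dplyr::bind_cols(extract_model_params(tr, frame),
                       tibble(md = mean_deviation(tr, frame)))
    })
    # Mean speed of the generated tangential-stage profiles: trajectory-level
    # speed is pinned to D / t_dur through MV_L, so the MV parameter is only
    # observable at this stage.
    mv_tang <- vapply(trajs, function(tr) {
      subs <- attr(tr, "model")$tangential
      prof <- evaluate_profile(subs, time_grid(attr(subs, "t_dur"), 200))
      trapz_mean(prof$t, prof$v)
    }, numeric(1))
    list(mean_npk = mean(pars$npk), mean_mv = mean(pars$mv),
         mean_md = mean(pars$md), mean_mv_tangential = mean(mv_tang))
  }

  ref <- simulate_batch(means)
  purrr::map_dfr(model_param_fields, function(f) {
    qs <- quantile(pool[[f]], probs, names = FALSE)
    purrr::map_dfr(seq_along(qs), function(d) {
      vals <- means
      vals[[f]] <- qs[d]
      out <- tibble(parameter = f, decile = d, value = qs[d],
                    feasible = TRUE, e_rs = NA_real_, mean_npk = NA_real_,
                    mean_mv = NA_real_, mean_md = NA_real_,
                    mean_mv_tangential = NA_real_)
      res <- tryCatch({
        trajs <- simulate_batch(vals)
        sm <- batch_summary(trajs)
        ers <- real_sim_distance(ref, trajs)$pooled
        list(sm = sm, ers = ers)
      }, error = function(e) NULL)
      if (is.null(res)) {
        out$feasible <- FALSE
      } else {
        out$e_rs <- res$ers
        out$mean_npk <- res$sm$mean_npk
        out$mean_mv <- res$sm$mean_mv
        out$mean_md <- res$sm$mean_md
        out$mean_mv_tangential <- res$sm$mean_mv_tangential
      }
      out
    })
  })
}

#' @export
print.reach_cohort <- function(x, ...) {
  cat(sprintf("<reach_cohort> %d movements on %d targets\n",
              length(x$trajectories), x$geometry$n_targets))
  print(utils::head(x$params))
  invisible(x)
}
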