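toy_param_table <- function(groups = "subacute", timepoints = "T0",
                            n = 10L, seed = 1L) {
  set.seed(seed)
  purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(timepoints, function(tp) {
      tibble::tibble(
        group = g, timepoint = tp,
        npk = sample(2:4, n, replace = TRUE),
        mean_sigma = runif(n, 0.05, 0.09),
        t_dur = runif(n, 1.5, 3),
        mv = runif(n, 0.05, 0.1),
        mv_n = runif(n, 0.003, 0.01),
        cont_l = sample(1:2, n, replace = TRUE),
        cont_n = sample(0:2, n, replace = TRUE),
        ratio_amp_l = runif(n, 0.8, 1.0),
        ratio_amp_n = runif(n, 0.1, 0.3),
        ratio_npk = runif(n, 0.9, 1.1))
    })
  })
}

test_that("empirical distributions pool values per group and timepoint", {
  tab <- toy_param_table()
  dist <- estimate_distributions(tab)
  expect_length(dist$pools, 1L)
  expect_length(dist$pools[[1]]$mv, 10L)
  two <- estimate_distributions(toy_param_table(groups = c("subacute", "chronic")))
  expect_length(two$pools, 2L)
  expect_false(identical(two$pools[[1]]$mv, two$pools[[2]]$mv))
  # a pool of 1..10 is kept verbatim, so its deciles are its values
  tab10 <- tab
  tab10$mv <- 1:10
  d10 <- estimate_distributions(tab10)
  expect_identical(sort(d10$pools[[1]]$mv), as.numeric(1:10))
  expect_equal(d10$summary$q50[d10$summary$field == "mv"], 5.5)
  expect_error(estimate_distributions(tab[-3]),
               class = "reachkin_schema_error")
})

test_that("parameter draws resample the pools reproducibly", {
  tab <- toy_param_table()
  dist <- estimate_distributions(tab)
  set.seed(17)
  draw <- sample_params(dist, "subacute", "T0")
  expect_true(draw$values[["mv"]] %in% tab$mv)
  expect_true(draw$values[["npk"]] %in% tab$npk)
  set.seed(17)
  draw2 <- sample_params(dist, "subacute", "T0")
  expect_identical(draw$values, draw2$values)
  # singleton pools give a deterministic parameter set
  single <- estimate_distributions(toy_param_table(n = 1L))
  s1 <- sample_params(single, "subacute", "T0")
  s2 <- sample_params(single, "subacute", "T0")
  expect_identical(s1$values, s2$values)
  expect_error(sample_params(dist, "nope", "T0"),
               class = "reachkin_invalid_argument")
})

test_that("cohort simulation follows the turn structure deterministically", {
  cfg <- cohort_config("recovered")
  coh <- generate_ground_truth_cohort(cfg, n_movements = 16L, seed = 18)
  expect_length(coh$trajectories, 16L)
  expect_equal(nrow(dplyr::distinct(coh$params[c("target", "direction")])),
               16L)
  coh2 <- generate_ground_truth_cohort(cfg, n_movements = 16L, seed = 18)
  expect_identical(coh$params, coh2$params)
  expect_identical(coh$trajectories[[5]]$x, coh2$trajectories[[5]]$x)
  # point-mass config: every movement shares one generating parameter set
  pm <- cohort_config("recovered", npk = 2L, t_dur = 1.8, mean_sigma = 0.1,
                      mv = 0.1, mv_n = 0.008, ratio_amp_l = 0.9,
                      ratio_amp_n = 0.1, ratio_npk = 1, cont_l = 1L,
                      cont_n = 1L)
  cpm <- generate_ground_truth_cohort(pm, n_movements = 4L, seed = 19)
  expect_equal(nrow(dplyr::distinct(cpm$params[reachkin:::model_param_fields])),
               1L)
})

test_that("impaired and recovered presets separate as expected", {
  imp <- generate_ground_truth_cohort(cohort_config("impaired"),
                                      n_movements = 12L, seed = 20)
  rec <- generate_ground_truth_cohort(cohort_config("recovered"),
                                      n_movements = 12L, seed = 20)
  ext_i <- extract_cohort_params(imp)
  ext_r <- extract_cohort_params(rec)
  expect_gt(mean(ext_i$npk), mean(ext_r$npk))
  expect_gt(mean(imp$params$t_dur), mean(rec$params$t_dur))
  # extracted durations shift downward between the presets
  expect_gt(median(ext_i$t_dur), median(ext_r$t_dur))
})

test_that("cohorts written to disk round trip through the CSV reader", {
  coh <- generate_ground_truth_cohort(cohort_config("recovered"),
                                      n_movements = 4L, seed = 21)
  dir <- withr::local_tempdir()
  man <- reachkin:::write_cohort_dir(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_trajectory_csv(man$file[2])
  expect_equal(back$x, coh$trajectories[[2]]$x, tolerance = 1e-9)
})

test_that("the sensitivity scan varies one parameter at a time", {
  tab <- toy_param_table(n = 8L, seed = 5L)
  # narrow, fast configuration: small movements
  tab$npk <- pmin(tab$npk, 2L)
  tab$t_dur <- runif(8, 1, 1.5)
  dist <- estimate_distributions(tab)
  scan <- sensitivity_scan(dist, "subacute", "T0", n_per_cell = 1L, seed = 22)
  expect_equal(nrow(scan), 10L * 10L)
  expect_setequal(unique(scan$parameter), reachkin:::model_param_fields)
  expect_true(all(scan$feasible))
  # variation values span each pool's quantiles monotonically
  for (f in unique(scan$parameter)) {
    vals <- scan$value[scan$parameter == f]
    expect_true(all(diff(vals) >= 0))
  }
  # varying MV moves the tangential-stage mean speed monotonically
  mv_rows <- scan[scan$parameter == "mv", ]
  expect_true(all(diff(mv_rows$mean_mv_tangential) >= -1e-6))
  expect_equal(mv_rows$mean_mv_tangential, mv_rows$value, tolerance = 1e-3)
  # constant pools: all ten variations of each parameter are identical
  const <- toy_param_table(n = 1L)
  const <- const[rep(1, 6), ]
  dconst <- estimate_distributions(const)
  scan_c <- sensitivity_scan(dconst, "subacute", "T0", n_per_cell = 1L,
                             seed = 23)
  spread <- tapply(scan_c$value, scan_c$parameter, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("extracted pools reproduce the generating means within 2 SE", {
  coh <- generate_ground_truth_cohort(cohort_config("well_separated"),
                                      n_movements = 60L, seed = 45)
  ext <- extract_cohort_params(coh)
  m <- dplyr::inner_join(coh$params, ext, by = "movement",
                         suffix = c("_gen", "_ext"))
  for (f in c("mv", "t_dur", "npk")) {
    gen <- m[[paste0(f, "_gen")]]
    est <- m[[paste0(f, "_ext")]]
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - mean(gen)), 2 * se + 1e-12)
  }
})
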