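test_that("longitudinal/transversal peak counts derive from the ratio", {
  expect_equal(derive_ln_counts(1.0, 4), c(npk_l = 4L, npk_n = 4L))
  expect_equal(derive_ln_counts(0.75, 4), c(npk_l = 3L, npk_n = 3L))
  expect_equal(derive_ln_counts(0.1, 2), c(npk_l = 1L, npk_n = 1L))
})

test_that("coupled peak times coincide with tangential peaks", {
  set.seed(5)
  tt <- assign_ln_peak_times(c(0.3, 0.7), npk_x = 2, cont_x = 2,
                             t_dur = 1, mean_sigma = 0.05)
  expect_equal(sort(tt), c(0.3, 0.7))
  free <- assign_ln_peak_times(c(0.3, 0.7), npk_x = 2, cont_x = 0,
                               t_dur = 1, mean_sigma = 0.05)
  expect_length(free, 2)
  expect_gte(min(diff(sort(free))), 0.1)
  one <- assign_ln_peak_times(0.5, npk_x = 1, cont_x = 1, t_dur = 1,
                              mean_sigma = 0.05)
  expect_equal(as.numeric(one), 0.5)
})

test_that("planar synthesis couples peaks and favours longitudinal compliance", {
  set.seed(6)
  spec <- tangential_spec(3, 0.06, 2, 0.08)
  tang <- synthesize_tangential(spec)
  ps <- quick_planar_spec(cont_l = 3, cont_n = 1, mv_n = 0.01,
                          ratio_amp_n = 0.3)
  pl <- synthesize_planar(tang$submovements, ps, mv_l = 0.07)
  # full coupling: every longitudinal peak time is a tangential peak time
  expect_true(all(pl$subs_l$t_i %in% tang$submovements$t_i))
  # the alpha = 0.8 weighting keeps the longitudinal residual tighter
  set.seed(60)
  wins <- replicate(50, {
    tg <- synthesize_tangential(spec)
    r <- synthesize_planar(tg$submovements, ps, mv_l = 0.07)$residuals
    r["longitudinal"] <= r["transversal"]
  })
  expect_gte(mean(wins), 0.9)
})

test_that("a zero transversal target admits the all-zero transversal solution", {
  set.seed(7)
  spec <- tangential_spec(2, 0.07, 1.5, 0.08)
  tang <- synthesize_tangential(spec)
  ps <- quick_planar_spec(mv_n = 0, ratio_amp_n = 0, cont_n = 0)
  pl <- synthesize_planar(tang$submovements, ps, mv_l = 0.09)
  expect_true(all(pl$v_n$v == 0))
  expect_equal(unname(pl$residuals["transversal"]), 0)
})

test_that("path integration matches closed forms and is linear", {
  tt <- seq(0, 2, by = 1 / 200)
  vc <- speed_profile(tt, rep(0.05, length(tt)), axis = "longitudinal")
  v0 <- speed_profile(tt, rep(0, length(tt)), axis = "transversal")
  p <- integrate_to_path(vc, v0)
  expect_equal(p$x_l[length(tt)], 0.05 * 2, tolerance = 1e-9)
  expect_true(all(p$x_n == 0))
  # sine profile scaled to mean mv_l: closed-form integral mv_l * T
  mv_l <- 0.07
  vs <- speed_profile(tt, mv_l * pi / 2 * sin(pi * tt / 2),
                      axis = "longitudinal")
  ps <- integrate_to_path(vs, v0)
  expect_lt(abs(ps$x_l[length(tt)] - mv_l * 2), 1e-6)
  # linearity
  va <- speed_profile(tt, 3 * vs$v, axis = "longitudinal")
  pa <- integrate_to_path(va, v0)
  expect_equal(pa$x_l, 3 * ps$x_l, tolerance = 1e-12)
  expect_error(integrate_to_path(vc, speed_profile(tt[-1], rep(0, length(tt) - 1),
                                                   axis = "transversal")),
               class = "reachkin_invalid_argument")
})

test_that("workspace placement is isometric", {
  geo <- task_geometry()
  tt <- seq(0, 1, by = 0.01)
  path <- structure(tibble::tibble(t = tt, x_l = 0.14 * tt, x_n = 0 * tt),
                    class = c("path_ln", "tbl_df", "tbl", "data.frame"))
  tr1 <- place_in_workspace(path, ln_frame_for(geo, 1, "outward"))
  expect_equal(tr1$y, rep(0, length(tt)), tolerance = 1e-12)
  expect_equal(max(tr1$x), 0.14, tolerance = 1e-12)
  tr3 <- place_in_workspace(path, ln_frame_for(geo, 3, "outward"))
  expect_equal(tr3$x, rep(0, length(tt)), tolerance = 1e-12)
  # pairwise distances preserved
  d1 <- sqrt(diff(tr1$x)^2 + diff(tr1$y)^2)
  d3 <- sqrt(diff(tr3$x)^2 + diff(tr3$y)^2)
  expect_equal(d1, d3, tolerance = 1e-12)
})

test_that("simulated movements separate healthy-like from impaired-like specs", {
  geo <- task_geometry()
  healthy_t <- tangential_spec(1, 0.12, 1.2, 0.12)
  healthy_p <- quick_planar_spec(mv_n = 0.0005, ratio_amp_n = 0.005,
                                 cont_n = 0, cont_l = 1)
  impaired_t <- tangential_spec(6, 0.06, 4, 0.05)
  impaired_p <- quick_planar_spec(mv_n = 0.02, ratio_amp_n = 0.5,
                                  cont_l = 4, cont_n = 3)
  frame <- ln_frame_for(geo, 1, "outward")
  set.seed(8)
  md_h <- replicate(20, mean_deviation(
    simulate_movement(healthy_t, healthy_p, geo), frame))
  md_i <- replicate(20, mean_deviation(
    simulate_movement(impaired_t, impaired_p, geo), frame))
  expect_lt(median(md_h), 0.002)
  expect_gt(mean(md_i > md_h), 0.9)
  # determinism
  set.seed(9)
  a <- simulate_movement(healthy_t, healthy_p, geo)
  set.seed(9)
  b <- simulate_movement(healthy_t, healthy_p, geo)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
})
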