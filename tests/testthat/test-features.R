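test_that("tangential speed recovers known motions", {
  tr <- straight_trajectory(speed = 0.1)
  v <- tangential_speed(tr)
  expect_equal(v$v[2:(length(v$v) - 1)], rep(0.1, length(v$v) - 2),
               tolerance = 1e-6)
  still <- trajectory(seq(0, 1, 0.01), rep(0.2, 101), rep(0.3, 101))
  expect_true(all(abs(tangential_speed(still)$v) < 1e-12))
  # circular motion: speed r * omega
  tt <- seq(0, 1, by = 1 / 500)
  circ <- trajectory(tt, 0.1 * cos(2 * pi * tt), 0.1 * sin(2 * pi * tt))
  vc <- tangential_speed(circ)
  expect_equal(vc$v[5:(length(tt) - 5)],
               rep(0.1 * 2 * pi, length(tt) - 9), tolerance = 1e-4)
  expect_error(tangential_speed(trajectory(0:2, 0:2, 0:2)[1:2, ]),
               class = "reachkin_invalid_argument")
})

test_that("velocity decomposition satisfies the Pythagorean identity", {
  geo <- task_geometry()
  frame <- ln_frame_for(geo, 2, "outward")
  # motion along L only
  tr_l <- straight_trajectory(angle = geo$targets$angle[2])
  d <- decompose_ln(tr_l, frame)
  expect_true(all(abs(d$v_n$v) < 1e-9))
  # motion at 45 degrees to the frame
  tr45 <- straight_trajectory(angle = geo$targets$angle[2] + pi / 4)
  d45 <- decompose_ln(tr45, frame)
  mid <- 50:150
  expect_equal(d45$v_l$v[mid], d45$v_t$v[mid] / sqrt(2), tolerance = 1e-6)
  expect_equal(abs(d45$v_n$v[mid]), d45$v_t$v[mid] / sqrt(2), tolerance = 1e-6)
  # identity on a random trajectory
  set.seed(10)
  tt <- seq(0, 1, 0.005)
  rnd <- trajectory(tt, cumsum(rnorm(length(tt), sd = 1e-3)),
                    cumsum(rnorm(length(tt), sd = 1e-3)))
  dr <- decompose_ln(rnd, frame)
  expect_equal(dr$v_l$v^2 + dr$v_n$v^2, dr$v_t$v^2, tolerance = 1e-9)
})

test_that("peak detection applies the 10 percent rule per polarity", {
  tt <- seq(0, 1, by = 1 / 500)
  v <- 1.0 * exp(-((tt - 0.3) / (sqrt(2) * 0.05))^2) +
       0.05 * exp(-((tt - 0.7) / (sqrt(2) * 0.05))^2)
  pk <- detect_peaks(speed_profile(tt, v))
  expect_identical(nrow(pk), 1L)  # 0.05 < 10 % of 1.0
  v2 <- exp(-((tt - 0.35) / (sqrt(2) * 0.05))^2) +
        exp(-((tt - 0.65) / (sqrt(2) * 0.05))^2)  # 6 sigma apart
  expect_identical(nrow(detect_peaks(speed_profile(tt, v2))), 2L)
  signed <- speed_profile(
    tt, exp(-((tt - 0.3) / (sqrt(2) * 0.05))^2) -
        0.8 * exp(-((tt - 0.7) / (sqrt(2) * 0.05))^2),
    axis = "longitudinal")
  pks <- detect_peaks(signed)
  expect_identical(sum(pks$polarity == "pos"), 1L)
  expect_identical(sum(pks$polarity == "neg"), 1L)
  expect_lt(pks$amplitude[pks$polarity == "neg"], 0)
  # all-zero profile: empty set
  expect_identical(nrow(detect_peaks(speed_profile(tt, rep(0, length(tt))))), 0L)
})

test_that("raising the peak threshold never increases the peak count", {
  set.seed(11)
  tt <- seq(0, 2, by = 1 / 200)
  for (i in 1:10) {
    npk <- sample(2:5, 1)
    times <- sort(runif(npk, 0.2, 1.8))
    amps <- runif(npk, 0.2, 1)
    v <- rowSums(sapply(seq_len(npk), function(j)
      amps[j] * exp(-((tt - times[j]) / (sqrt(2) * 0.05))^2)))
    prof <- speed_profile(tt, v)
    counts <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8),
                     function(f) nrow(detect_peaks(prof, f)), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("per-peak Gaussian fits recover sigma", {
  tt <- seq(0, 1, by = 1 / 500)
  one <- speed_profile(tt, 0.5 * exp(-((tt - 0.5) / (sqrt(2) * 0.08))^2))
  f1 <- fit_mean_sigma(one, detect_peaks(one))
  expect_equal(f1$mean_sigma, 0.08, tolerance = 1e-4)
  tt2 <- seq(0, 3, by = 1 / 500)
  two <- speed_profile(tt2,
    0.5 * exp(-((tt2 - 0.8) / (sqrt(2) * 0.06))^2) +
    0.5 * exp(-((tt2 - 2.2) / (sqrt(2) * 0.10))^2))
  f2 <- fit_mean_sigma(two, detect_peaks(two))
  expect_equal(f2$mean_sigma, 0.08, tolerance = 1e-3)
  expect_equal(sort(f2$sigmas), c(0.06, 0.10), tolerance = 1e-3)
  # 1 percent additive noise: sigma within 5 percent in most runs
  set.seed(12)
  errs <- replicate(50, {
    noisy <- speed_profile(tt, 0.5 * exp(-((tt - 0.5) / (sqrt(2) * 0.08))^2) +
                             rnorm(length(tt), sd = 0.005))
    pk <- detect_peaks(noisy)
    abs(fit_mean_sigma(noisy, pk[which.max(pk$amplitude), ])$mean_sigma - 0.08) / 0.08
  })
  expect_lt(median(errs), 0.05)
})

test_that("contributing peaks are counted inside sigma windows", {
  pk_t <- structure(tibble::tibble(time = c(0.3, 0.7), amplitude = c(1, 1),
                                   polarity = "pos"),
                    class = c("peak_set", "tbl_df", "tbl", "data.frame"))
  pk_x <- structure(tibble::tibble(time = c(0.31, 0.5), amplitude = c(0.5, 0.4),
                                   polarity = "pos"),
                    class = c("peak_set", "tbl_df", "tbl", "data.frame"))
  expect_identical(contributing_peaks(pk_x, pk_t, 0.1), 1L)
  expect_identical(contributing_peaks(pk_t, pk_t, 0.1), 2L)
  empty <- pk_x[0, ]
  expect_identical(contributing_peaks(empty, pk_t, 0.1), 0L)
})

test_that("mean deviation measures lateral departure from the path", {
  geo <- task_geometry()
  frame <- ln_frame_for(geo, 1, "outward")
  on_path <- straight_trajectory()
  expect_equal(mean_deviation(on_path, frame), 0, tolerance = 1e-12)
  offset <- trajectory(on_path$t, on_path$x, on_path$y + 0.01)
  expect_equal(mean_deviation(offset, frame), 0.01, tolerance = 1e-12)
  # semicircular detour: mean |r sin(u)| over u in [0, pi] = 2 r / pi
  u <- seq(0, pi, length.out = 2001)
  semi <- trajectory(u, 0.07 - 0.07 * cos(u), 0.05 * sin(u))
  expect_equal(mean_deviation(semi, frame), 2 * 0.05 / pi, tolerance = 1e-2)
})

test_that("model parameters are recovered from a degenerate straight movement", {
  geo <- task_geometry()
  frame <- ln_frame_for(geo, 1, "outward")
  tr <- gaussian_speed_trajectory(0.3, 0.5, 0.1)
  mp <- extract_model_params(tr, frame)
  expect_identical(mp$npk, 1L)
  expect_identical(mp$cont_n, 0L)
  expect_equal(mp$ratio_amp_n, 0)
  expect_lt(mp$mv_n, 1e-9)
  expect_equal(mp$mean_sigma, 0.1, tolerance = 0.01)
})

test_that("extracted parameters are invariant to rotation and translation", {
  set.seed(13)
  geo <- task_geometry()
  spec <- tangential_spec(3, 0.06, 2, 0.08)
  ps <- quick_planar_spec(cont_l = 3, cont_n = 1, mv_n = 0.01,
                          ratio_amp_n = 0.3)
  tr <- simulate_movement(spec, ps, geo, target = 1)
  frame <- ln_frame_for(geo, 1, "outward")
  mp <- extract_model_params(tr, frame)
  ep <- extract_evaluation_params(tr, frame)
  ang <- 2 * pi / 3; shift <- c(0.4, -0.2)
  mp_r <- extract_model_params(rotate_trajectory(tr, ang, shift),
                               rotate_frame(frame, ang, shift))
  ep_r <- extract_evaluation_params(rotate_trajectory(tr, ang, shift),
                                    rotate_frame(frame, ang, shift))
  expect_equal(as.data.frame(mp_r), as.data.frame(mp), tolerance = 1e-9)
  expect_equal(as.data.frame(ep_r), as.data.frame(ep), tolerance = 1e-9)
  # exact duplicate gives identical parameters
  expect_identical(as.data.frame(extract_evaluation_params(tr, frame)),
                   as.data.frame(ep))
})

test_that("evaluation parameters report missing polarity classes as NA", {
  geo <- task_geometry()
  frame <- ln_frame_for(geo, 1, "outward")
  tr <- gaussian_speed_trajectory(0.3, 0.5, 0.1)
  ep <- extract_evaluation_params(tr, frame)
  expect_identical(ep$npk_l_pos, 1L)
  expect_identical(ep$npk_l_neg, 0L)
  expect_true(is.na(ep$a_l_neg))
  expect_true(is.na(ep$overlap))  # single submovement: no adjacent pair
  # motion is purely longitudinal, so mv_l equals the mean tangential speed
  v <- tangential_speed(tr)
  expect_equal(ep$mv_l, reachkin:::trapz_mean(v$t, v$v), tolerance = 1e-9)
})
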