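test_that("depth and intensity formulas match hand-evaluated cases", {
  # half-height reading: elevation at a equals half the peak elevation
  obs <- observation_pair(T_max = 31, T_a = 29, a = 0.017, T_env = 27)
  expect_equal(depth_from_temps(obs), 0.017)

  # clinical-style numbers: Te 20, Tmax 35.2, local 33.4 at 1 cm
  obs2 <- observation_pair(35.2, 33.4, 0.01, 20)
  expect_equal(depth_from_temps(obs2), 0.01 * sqrt(13.4 / 1.8))
  expect_equal(depth_from_temps(obs2), 0.0272845, tolerance = 1e-5)
  expect_equal(intensity_from_temps(obs2, 8.77), 1.247054, tolerance = 1e-5)
})

test_that("noiseless round trip recovers depth and intensity to 1e-10", {
  cases <- random_sources(1000, seed = 42, R_zero = TRUE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    src <- heat_source(cs$Q, cs$d, 0)
    t_peak <- oracle_surface_temp(cs$Q, cs$d, 0, 8.77, 27, 0)
    t_a <- oracle_surface_temp(cs$Q, cs$d, 0, 8.77, 27, cs$a)
    obs <- observation_pair(t_peak, t_a, cs$a, 27)
    expect_lt(abs(depth_from_temps(obs) - cs$d) / cs$d, 1e-10)
    expect_lt(abs(intensity_from_temps(obs, 8.77) - cs$Q) / cs$Q, 1e-10)
  }
})

test_that("with a finite radius the depth formula returns the effective depth", {
  cases <- random_sources(200, seed = 7, R_zero = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    src <- heat_source(cs$Q, cs$d, cs$R)
    obs <- observation_pair(surface_temperature(src, tp_default, 0),
                            surface_temperature(src, tp_default, cs$a),
                            cs$a, 27)
    expect_equal(depth_from_temps(obs), cs$d + cs$R, tolerance = 1e-10)
  }
})

test_that("estimates are identical for every offset on noiseless data", {
  src <- heat_source(0.2, 0.018, 0.004)
  for (a in c(0.005, 0.01, 0.02, 0.05)) {
    obs <- observation_pair(surface_temperature(src, tp_default, 0),
                            surface_temperature(src, tp_default, a), a, 27)
    expect_equal(depth_from_temps(obs), 0.022, tolerance = 1e-12)
    expect_equal(intensity_from_temps(obs, 8.77), 0.2, tolerance = 1e-12)
  }
})

test_that("radius from intensity follows cube-root scaling", {
  expect_equal(radius_from_intensity(700 * 1e-6, 700, 1e-6), 1)
  expect_equal(radius_from_intensity(0, 700), 0)
  expect_equal(radius_from_intensity(0.1, 700, 1e-6), 5.2276, tolerance = 1e-3)
  expect_equal(radius_from_intensity(8 * 0.05, 700),
               2 * radius_from_intensity(0.05, 700))
  expect_error(radius_from_intensity(0.1, -700), "positive")
  expect_error(radius_from_intensity(0.1, 700, 0), "positive")
})

test_that("intensity-free radius equals the intensity route exactly", {
  cases <- random_sources(200, seed = 11, R_zero = TRUE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    t_peak <- oracle_surface_temp(cs$Q, cs$d, 0, 8.77, 27, 0)
    t_a <- oracle_surface_temp(cs$Q, cs$d, 0, 8.77, 27, cs$a)
    obs <- observation_pair(t_peak, t_a, cs$a, 27)
    d_eff <- depth_from_temps(obs)
    r_direct <- radius_depth_relation(t_a, 27, cs$a, d_eff, 8.77, 700)
    r_via_q <- radius_from_intensity(intensity_from_temps(obs, 8.77), 700, 1e-6)
    expect_equal(r_direct, r_via_q, tolerance = 1e-14)
    # the cubed radius times q_m * 1e-6 returns the intensity
    expect_equal(r_direct^3 * 700 * 1e-6, cs$Q, tolerance = 1e-10)
  }
  expect_equal(radius_depth_relation(27, 27, 0.01, 0.01, 8.77, 700), 0)
  expect_error(radius_depth_relation(26, 27, 0.01, 0.01, 8.77, 700), "ambient")
})

test_that("localization round-trips a noiseless profile and grid exactly", {
  prof <- surface_profile(src_point, tp_default, seq(-0.05, 0.05, by = 0.0025))
  r <- localize_from_thermogram(prof, tp_default)
  expect_equal(r$d_eff, 0.014, tolerance = 1e-12)
  expect_equal(r$Q, 0.1, tolerance = 1e-12)
  expect_equal(r$d, max(r$d_eff - r$R, 0))

  g <- generate_synthetic_thermogram(src_point, tp_default, c(41, 41), 0.0025)
  rg <- localize_from_thermogram(g, tp_default)
  expect_equal(rg$d_eff, 0.014, tolerance = 1e-12)
  expect_equal(rg$Q, 0.1, tolerance = 1e-12)

  # both radius routes agree through the localization surface too
  rg19 <- localize_from_thermogram(g, tp_default,
                                   radius_method = "eq_radius_intensity")
  expect_equal(rg19$R, rg$R, tolerance = 1e-10)
})

test_that("flat input reports no source; boundary peak is flagged", {
  flat <- thermogram_grid(matrix(27, 9, 9), 0.005, T_env = 27)
  expect_error(localize_from_thermogram(flat, tp_default), "no source detected")

  # hotspot centered on the grid edge
  g <- generate_synthetic_thermogram(src_point, tp_default, c(21, 21), 0.005,
                                     center = c(0, 0.05))
  r <- localize_from_thermogram(g, tp_default)
  expect_true(any(grepl("boundary", r$warnings)))
})

test_that("noisy-grid estimates stay within the expected error magnitudes", {
  noiseless <- localize_from_thermogram(
    generate_synthetic_thermogram(src_point, tp_default, c(41, 41), 0.0025),
    tp_default)
  errs <- t(sapply(1:100, function(s) {
    g <- generate_synthetic_thermogram(
      src_point, tp_default, c(41, 41), 0.0025,
      noise = noise_spec("elevation_percent", 0.10, seed = s))
    r <- localize_from_thermogram(g, tp_default)
    c(d = abs(r$d_eff - 0.014) / 0.014, Q = abs(r$Q - 0.1) / 0.1,
      R = abs(r$R - noiseless$R) / noiseless$R)
  }))
  # 10% elevation noise: depth and intensity within tens of percent,
  # radius (cube-root damped) within ~10%
  expect_lt(max(errs[, "d"]), 0.30)
  expect_lt(max(errs[, "Q"]), 0.30)
  expect_lt(max(errs[, "R"]), 0.10)
  expect_lt(median(errs[, "d"]), 0.10)
})

test_that("observation pairs reject degenerate temperature orderings", {
  expect_error(observation_pair(30, 30, 0.01, 27), "exceed")
  expect_error(observation_pair(30, 27, 0.01, 27), "ambient")
  expect_error(observation_pair(30, 29, 0, 27), "positive")
})
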