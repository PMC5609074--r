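cfg_small <- surrogate_config(training_set_size = 60, seed = 2,
                              max_epochs = 600, n_starts = 1)

test_that("training-set sampling is seeded, bounded and reproducible", {
  d1 <- sample_training_data(cfg_small, tp_default)
  d2 <- sample_training_data(cfg_small, tp_default)
  expect_identical(d1, d2)
  rg <- cfg_small$parameter_ranges
  expect_true(all(d1$params[, "Q"] >= rg$Q[1] & d1$params[, "Q"] <= rg$Q[2]))
  expect_true(all(d1$params[, "d"] >= rg$d[1] & d1$params[, "d"] <= rg$d[2]))
  expect_true(all(d1$temps >= d1$T_env_C))       # forward-model positivity

  # degenerate ranges: the single forward profile of that source
  cfg1 <- surrogate_config(training_set_size = 1,
                           parameter_ranges = list(Q = c(0.1, 0.1),
                                                   d = c(0.014, 0.014),
                                                   R = c(0, 0)), seed = 1)
  d <- sample_training_data(cfg1, tp_default)
  expect_equal(as.numeric(d$temps),
               surface_temperature(src_point, tp_default, cfg1$offsets))

  expect_error(surrogate_config(parameter_ranges = list(Q = c(-0.1, 0.5),
                                                        d = c(0.005, 0.04),
                                                        R = c(0, 0.01))),
               "negative")
  expect_error(surrogate_config(parameter_ranges = list(Q = c(0.1, 0.5),
                                                        d = c(0, 0),
                                                        R = c(0, 0.01))),
               "effective depth")
})

test_that("training is deterministic and fits constant targets exactly", {
  m1 <- train_surrogate(sample_training_data(cfg_small, tp_default), cfg_small)
  m2 <- train_surrogate(sample_training_data(cfg_small, tp_default), cfg_small)
  expect_identical(m1$final_loss, m2$final_loss)
  expect_identical(m1$W1, m2$W1)

  # constant target: every sample is the same source
  cfgc <- surrogate_config(training_set_size = 40,
                           parameter_ranges = list(Q = c(0.1, 0.1),
                                                   d = c(0.014, 0.014),
                                                   R = c(0, 0)),
                           seed = 3, max_epochs = 400, n_starts = 1)
  mc <- train_surrogate(sample_training_data(cfgc, tp_default), cfgc)
  pred <- predict(mc, c(0.1, 0.014, 0))
  truth <- surface_temperature(src_point, tp_default, cfgc$offsets)
  expect_lt(sqrt(mean((pred[1, ] - truth)^2)), 1e-3)
  expect_lt(mc$val_rmse_peak, 1e-3)
})

test_that("default training reaches the held-out peak accuracy threshold", {
  cfg <- surrogate_config()            # 500 samples, 10 hidden units, seed 1
  mod <- train_surrogate(sample_training_data(cfg, tp_default), cfg)
  expect_lt(mod$val_rmse_peak, 0.05)
  expect_true(mod$converged)
})

test_that("surrogate models serialize to JSON and reload bit-exactly", {
  mod <- train_surrogate(sample_training_data(cfg_small, tp_default), cfg_small)
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate(mod, path)
  mod2 <- read_surrogate(path)
  probe <- rbind(c(0.1, 0.014, 0), c(0.3, 0.02, 0.005), c(0.05, 0.01, 0.001))
  expect_identical(predict(mod2, probe), predict(mod, probe))
  expect_identical(mod2$W1, mod$W1)
  expect_identical(mod2$seed, mod$seed)
})

test_that("refinement is a fixed point at the truth and never hurts", {
  cfg <- surrogate_config(training_set_size = 300, seed = 4, max_epochs = 2000)
  mod <- train_surrogate(sample_training_data(cfg, tp_default), cfg)
  truth <- heat_source(0.35, 0.02, 0.005)
  obs <- surface_profile(truth, tp_default, cfg$offsets)

  r <- refine_parameters(truth, obs, mod, tp_default)
  expect_lte(r$mismatch_optimized, r$mismatch_initial)
  expect_lt(abs(r$optimized$Q - truth$Q) / truth$Q, 0.02)
  expect_lt(abs(r$optimized$d - truth$d) / truth$d, 0.02)
  expect_lt(r$peak_discrepancy, 0.05)

  # misspecified starts: mismatch still never increases
  for (s in 1:5) {
    init <- thermoloc:::with_seed(s, heat_source(0.35 * runif(1, 0.9, 1.1),
                                                 0.02 * runif(1, 0.9, 1.1),
                                                 0.005))
    ri <- refine_parameters(init, obs, mod, tp_default)
    expect_lte(ri$mismatch_optimized, ri$mismatch_initial)
  }

  # starting outside the training box flags extrapolation
  expect_warning(refine_parameters(heat_source(0.8, 0.02, 0.005), obs, mod,
                                   tp_default), "extrapolation")
})

test_that("peak discrepancy grows with source intensity", {
  # surrogate absolute error grows with the modelled temperature, so refining
  # a hot source leaves a larger model-vs-surrogate peak gap than a faint one;
  # averaged over independently trained surrogates to smooth training noise
  pd <- sapply(6:8, function(s) {
    cfg <- surrogate_config(training_set_size = 300, seed = s,
                            max_epochs = 2000)
    mod <- train_surrogate(sample_training_data(cfg, tp_default), cfg)
    sapply(c(0.05, 0.45), function(Q) {
      truth <- heat_source(Q, 0.02, 0.005)
      init <- heat_source(Q * 1.02, 0.02 * 1.01, 0.005)  # same fractional offset
      obs <- surface_profile(truth, tp_default, cfg$offsets)
      refine_parameters(init, obs, mod, tp_default)$peak_discrepancy
    })
  })
  expect_gt(mean(pd[2, ]), mean(pd[1, ]))
})
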