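test_that("simulation is deterministic and exact at zero noise", {
  truth <- c(A = 1.2, B = 1.3, C = 2.2, AB = -1.4, BC = -2.0)
  y0 <- simulate_responses(fx$design, truth, "sqrt", 0, seed = 3)
  mu <- drop(model_matrix(fx$design, names(truth)) %*% truth)
  expect_equal(y0, mu^2, tolerance = 1e-12)
  y1 <- simulate_responses(fx$design, truth, "sqrt", 0.05, seed = 3)
  y2 <- simulate_responses(fx$design, truth, "sqrt", 0.05, seed = 3)
  expect_identical(y1, y2)
  y3 <- simulate_responses(fx$design, truth, "sqrt", 0.05, seed = 4)
  expect_false(identical(y1, y3))
})

test_that("noiseless simulation round-trips coefficients on every transform", {
  truth <- c(A = 1.1, B = 0.9, C = 1.8, AB = -0.6, AC = 0.4, BC = -0.7)
  for (nm in c("identity", "sqrt", "ln", "inverse", "inverse_sqrt")) {
    y <- simulate_responses(fx$design, truth, nm, 0, seed = 0)
    fit <- scheffe_fit(fx$design, y, names(truth), nm)
    expect_equal(unname(fit$coefficients), unname(truth), tolerance = 1e-8,
                 info = nm)
  }
})

test_that("refits of noisy simulations recover coefficients with small bias", {
  cfg <- nanoemulsion_sim_config()
  truth <- cfg$responses$ic50_mgml$coefficients
  lin <- truth[c("A", "B", "C")]
  est <- matrix(0, 200, 3)
  for (r in 1:200) {
    y <- simulate_responses(fx$design, truth, "sqrt", 0.04, seed = 5000 + r)
    f <- scheffe_fit(fx$design, y, names(truth), "sqrt")
    est[r, ] <- f$coefficients[c("A", "B", "C")]
  }
  bias <- colMeans(est) - lin
  expect_true(all(abs(bias) < 0.02))
})

test_that("increasing noise never increases expected R-squared", {
  truth <- c(A = 1.2, B = 1.3, C = 2.2, AB = -1.4, BC = -2.0)
  mean_r2 <- sapply(c(0.02, 0.1, 0.3), function(s) {
    mean(sapply(1:30, function(r) {
      y <- simulate_responses(fx$design, truth, "identity", s,
                              seed = 100 * s + r)
      scheffe_fit(fx$design, y, names(truth))$r2
    }))
  })
  expect_true(all(diff(mean_r2) < 0))
})

test_that("interaction retention under a linear truth respects the alpha budget", {
  # simulating from a linear-only surface, backward elimination should
  # retain interactions in at most alpha * (candidate interactions) of
  # runs, plus Monte-Carlo margin
  truth <- c(A = 1, B = 2, C = 3)
  retained <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    y <- simulate_responses(fx$design, truth, "identity", 0.05,
                            seed = 1000 + r)
    f <- reduce_model(fx$design, y, terms_rc, "identity", alpha = 0.05)
    if (length(f$terms) > 3) retained <- retained + 1
  }
  expect_lte(retained / n_rep, 0.05 * 6 + 0.10)
})

test_that("the calibrated study emulation matches the real signal-to-noise", {
  cfg <- nanoemulsion_sim_config()
  real_fits <- nanoemulsion_fits()
  sim <- simulate_study(cfg, seed = 9)
  expect_identical(names(sim), names(cfg$responses))
  # mean simulated R2 within a point of the real fit's R2 per response
  for (nm in names(sim)) {
    rc <- cfg$responses[[nm]]
    r2s <- sapply(1:40, function(r) {
      y <- simulate_responses(cfg$design, rc$coefficients, rc$transform,
                              rc$noise_sd, seed = 200 + r)
      scheffe_fit(cfg$design, y, names(rc$coefficients), rc$transform)$r2
    })
    expect_lt(abs(mean(r2s) - real_fits[[nm]]$r2), 0.02, label = nm)
  }
})

test_that("the bundled study fixture is internally consistent", {
  expect_equal(nrow(fx$responses), 17)
  # landmark runs
  expect_equal(fx$responses$d32_um[6], 4.67)
  expect_equal(fx$responses$ic50_mgml[6], 15.789)
  expect_equal(fx$responses$d32_um[3], 0.505)
  expect_equal(as.numeric(fx$design$blends[6, ]), c(0, 0, 1))
  expect_equal(as.numeric(fx$design$blends[3, ]), c(1, 4, 1) / 6,
               tolerance = 1e-5)
  expect_equal(sum(fx$optimal_blend), 1, tolerance = 1e-4)
  # column checksums guard the transcription
  expect_equal(sum(fx$responses$d32_um), 31.384, tolerance = 1e-9)
  expect_equal(sum(fx$responses$ic50_mgml), 169.718, tolerance = 1e-9)
  expect_equal(sum(fx$responses$bsubtilis_cfu), 75.685e5, tolerance = 1e-9)
  expect_equal(sum(fx$responses$ecoli_cfu), 291.852e6, tolerance = 1e-9)
})
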