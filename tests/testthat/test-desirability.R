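test_that("Derringer-Suich ramps hit their boundary values", {
  g <- desirability_goal("minimize", L = 1, U = 5)
  expect_equal(desirability_value(5, g), 0)   # at the upper bound
  expect_equal(desirability_value(1, g), 1)   # at the target
  expect_equal(desirability_value(3, g), 0.5) # linear midpoint, w = 1
  expect_equal(desirability_value(0.2, g), 1) # saturates below the range
  expect_equal(desirability_value(9, g), 0)

  gm <- desirability_goal("maximize", L = 0, U = 10)
  expect_equal(desirability_value(10, gm), 1)
  expect_equal(desirability_value(0, gm), 0)
  expect_equal(desirability_value(5, gm), 0.5)

  gw <- desirability_goal("minimize", L = 0, U = 1, weight = 2)
  expect_equal(desirability_value(0.5, gw), 0.25)

  expect_error(desirability_value(1, desirability_goal("minimize", L = 2,
                                                       T = 2, U = 2)),
               "degenerate")
  expect_error(desirability_goal("minimize", L = 5, U = 1), "L <= T")
})

test_that("overall desirability is a weighted geometric mean with veto", {
  expect_equal(overall_desirability(c(0.9, 0, 0.8)), 0)
  expect_equal(overall_desirability(c(1, 1, 1)), 1)
  expect_equal(overall_desirability(c(1, 1, 0.925, 0.985)),
               (0.925 * 0.985)^(1 / 4), tolerance = 1e-12)
  ds <- c(0.3, 0.6, 0.9)
  expect_lte(overall_desirability(ds), max(ds))
  # importance weighting
  expect_equal(overall_desirability(c(0.5, 1), importances = c(2, 1)),
               (0.5^2)^(1 / 3), tolerance = 1e-12)
})

test_that("a monotone single-response surface is optimized at its vertex", {
  truth <- c(A = 5, B = 3, C = 1)  # strictly decreasing toward vertex C
  y <- simulate_responses(simplex7, truth, "identity", 0, seed = 1)
  fit <- scheffe_fit(simplex7, y, names(truth))
  opt <- optimize_desirability(list(y = fit),
                               list(y = desirability_goal("minimize")),
                               grid_step = 0.05)
  expect_equal(as.numeric(opt$blend), c(0, 0, 1), tolerance = 1e-6)
  expect_equal(opt$D, 1, tolerance = 1e-9)
})

test_that("grid refinement and polishing never worsen the optimum", {
  fits <- nanoemulsion_fits()
  goals <- lapply(stats::setNames(names(fits), names(fits)),
                  function(n) desirability_goal("minimize"))
  d_coarse <- optimize_desirability(fits, goals, grid_step = 0.05,
                                    polish = FALSE)$D
  d_mid <- optimize_desirability(fits, goals, grid_step = 0.02,
                                 polish = FALSE)$D
  d_fine <- optimize_desirability(fits, goals, grid_step = 0.005,
                                  polish = FALSE)$D
  expect_gte(d_mid, d_coarse - 1e-12)
  expect_gte(d_fine, d_mid - 1e-12)
  d_polished <- optimize_desirability(fits, goals, grid_step = 0.05)$D
  expect_gte(d_polished, d_coarse - 1e-12)
})

test_that("the optimum is equivariant under component relabeling", {
  fx2 <- nanoemulsion_runs()
  perm <- c(2, 3, 1)
  d_perm <- mixture_design(fx2$design$blends[, perm],
                           names = fx2$design$names[perm])
  specs <- nanoemulsion_models()
  relabel <- function(terms, perm) {
    # remap component letters under the permutation, then re-canonicalize
    q <- 3
    tl <- parse_terms(terms, q)
    inv <- order(perm)
    vapply(tl, function(t) {
      idx <- sort(inv[t$idx])
      al <- component_alias(q)
      if (t$kind == "cubic_diff") {
        i <- inv[t$idx[1]]; j <- inv[t$idx[2]]
        if (i < j) sprintf("%s%s(%s-%s)", al[i], al[j], al[i], al[j])
        else sprintf("%s%s(%s-%s)", al[j], al[i], al[j], al[i])
      } else paste(al[idx], collapse = "")
    }, "")
  }
  # cubic_diff sign flips under swapped indices, but the fitted surface and
  # hence the desirability optimum are unchanged
  fits1 <- nanoemulsion_fits()
  fits2 <- lapply(stats::setNames(names(specs), names(specs)), function(nm)
    scheffe_fit(d_perm, fx2$responses[[nm]], relabel(specs[[nm]]$terms, perm),
                specs[[nm]]$transform))
  goals <- lapply(stats::setNames(names(fits1), names(fits1)),
                  function(n) desirability_goal("minimize"))
  o1 <- optimize_desirability(fits1, goals, grid_step = 0.02, polish = FALSE)
  o2 <- optimize_desirability(fits2, goals, grid_step = 0.02, polish = FALSE)
  expect_equal(o1$D, o2$D, tolerance = 1e-9)
  expect_equal(as.numeric(o1$blend[perm]), as.numeric(o2$blend),
               tolerance = 1e-9)
})

test_that("an infeasible goal set is flagged", {
  fits <- nanoemulsion_fits()["d32_um"]
  goals <- list(d32_um = desirability_goal("minimize", L = -2, T = -2,
                                           U = -1))
  expect_warning(optimize_desirability(fits, goals, grid_step = 0.1,
                                       polish = FALSE), "no feasible")
})

test_that("the ternary export grid carries predictions and desirabilities", {
  fits <- nanoemulsion_fits()[c("d32_um", "ic50_mgml")]
  goals <- lapply(stats::setNames(names(fits), names(fits)),
                  function(n) desirability_goal("minimize"))
  g <- desirability_grid(fits, goals, grid_step = 0.1)
  expect_true(all(c("EO_CU", "EO_CA", "EO_CO", "yhat_d32_um", "d_d32_um",
                    "yhat_ic50_mgml", "d_ic50_mgml", "D") %in% names(g)))
  expect_true(all(g$D >= 0 & g$D <= 1))
  expect_true(all(abs(rowSums(g[, 1:3]) - 1) < 1e-9))
})
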