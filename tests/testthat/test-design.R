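test_that("blends validate, renormalize, and reject bad sums", {
  b <- blend(c(0.333333, 0.333333, 0.333333))
  expect_equal(sum(b), 1, tolerance = 1e-15)
  expect_error(blend(c(0.5, 0.52)), "sum")
  expect_error(blend(c(-0.1, 1.1)), "non-negative")
  expect_error(blend(1), "at least 2")
})

test_that("replicate groups recover the bundled study's pure-error structure", {
  expect_equal(nrow(fx$design$blends), 17)
  expect_true(all(abs(rowSums(fx$design$blends) - 1) < 1e-12))
  expect_equal(pure_error_df(fx$design), 5)
  grp_sizes <- table(fx$design$replicate_groups)
  expect_equal(sort(as.integer(grp_sizes[grp_sizes > 1])), c(2, 2, 4))
  # residual df under the 8-term droplet-size model: n - p = 17 - 8
  expect_equal(17 - 8, 9)
})

test_that("candidate sets enumerate the lattice plus centroid and axial points", {
  cs <- candidate_set(3, c(0, 1))
  expect_equal(nrow(cs$blends), 7)  # 3 vertices + centroid + 3 axial
  vertices <- diag(3)
  for (i in 1:3)
    expect_true(any(apply(cs$blends, 1, function(r)
      max(abs(r - vertices[i, ])) < 1e-9)))

  # the design lattice of the bundled study contains all 12 distinct blends
  cs2 <- candidate_set(3, c(0, 1/3, 1/2, 2/3, 1))
  distinct <- unique(round(fx$design$blends, 6))
  expect_equal(nrow(distinct), 12)
  for (i in seq_len(nrow(distinct)))
    expect_true(any(apply(cs2$blends, 1, function(r)
      max(abs(r - distinct[i, ])) < 1e-5)),
      info = paste("missing blend", i))

  # two components: centroid duplicates the 50/50 lattice point
  cs3 <- candidate_set(2, c(0, 1/2, 1))
  expect_equal(nrow(cs3$blends), 3)

  expect_error(candidate_set(3, numeric(0)), "empty lattice")
  expect_error(candidate_set(3, c(0.2, 0.5)), "0 and 1")
})

test_that("I-criterion matches hand linear algebra and detects rank deficiency", {
  vertices <- mixture_design(diag(3))
  # X'X = I at the three vertices under the linear model; f(x) has unit
  # norm on the vertex grid, so the average scaled prediction variance is 1
  expect_equal(i_criterion(vertices, c("A", "B", "C"), diag(3)), 1)

  single <- mixture_design(rbind(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2)))
  expect_error(i_criterion(single, c("A", "B", "C")), "rank-deficient")
})

test_that("I-criterion is stable under evaluation-grid refinement", {
  d <- mixture_design(rbind(diag(3), c(0.5, 0.5, 0), c(0.5, 0, 0.5),
                            c(0, 0.5, 0.5), c(1, 1, 1) / 3))
  coarse <- i_criterion(d, terms_q, simplex_grid(3, 0.025))
  fine <- i_criterion(d, terms_q, simplex_grid(3, 0.01))
  expect_lt(abs(coarse - fine) / fine, 0.05)
})

test_that("point exchange is deterministic, saturating, and beats random subsets", {
  cs <- candidate_set(3, c(0, 1/3, 1/2, 2/3, 1))
  terms <- scheffe_terms(3, "special-cubic")
  d1 <- coordinate_exchange(cs, 12, terms, n_starts = 2, seed = 7)
  d2 <- coordinate_exchange(cs, 12, terms, n_starts = 2, seed = 7)
  expect_identical(d1$blends, d2$blends)

  # saturated selection returns every candidate
  dall <- coordinate_exchange(cs, nrow(cs$blends), terms, n_starts = 1,
                              seed = 0)
  expect_equal(nrow(dall$blends), nrow(cs$blends))
  sort_rows <- function(m) m[do.call(order, as.data.frame(m)), ]
  expect_equal(sort_rows(dall$blends), sort_rows(cs$blends),
               ignore_attr = TRUE)

  # better than a modest random-subset baseline (full 1000-subset
  # comparison runs in the acceptance suite)
  g <- simplex_grid(3, 0.02)
  set.seed(11)
  rand <- replicate(50, {
    rows <- sample.int(nrow(cs$blends), 12)
    tryCatch(i_criterion(mixture_design(cs$blends[rows, , drop = FALSE]),
                         terms, g),
             error = function(e) Inf)
  })
  expect_lte(attr(d1, "criterion"), min(rand) + 1e-9)

  expect_error(coordinate_exchange(cs, 3, terms), "at least")
})

test_that("replicate augmentation books pure-error df correctly", {
  distinct <- mixture_design(unique(round(fx$design$blends, 6)))
  expect_equal(pure_error_df(distinct), 0)
  aug <- augment_replicates(distinct, 17)
  expect_equal(nrow(aug$blends), 17)
  expect_equal(pure_error_df(aug), 5)
  # centroid replicated first
  expect_true(any(apply(aug$blends[13:17, , drop = FALSE], 1, function(r)
    max(abs(r - 1/3)) < 1e-9)))

  expect_identical(augment_replicates(distinct, nrow(distinct$blends)),
                   distinct)

  # k duplicates of one blend raise pure-error df by exactly k
  for (k in c(1, 3)) {
    d <- mixture_design(rbind(distinct$blends,
                              distinct$blends[rep(4, k), , drop = FALSE]))
    expect_equal(pure_error_df(d), k)
  }
  expect_error(augment_replicates(distinct, 5), "smaller")
})
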