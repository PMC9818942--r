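# Sliding-window parametric maps, weighting operators and stacks.

test_that("the delta map recovers the generating dispersion", {
  fld <- simulate_model_field("riig", list(alpha = 2, beta = 0, delta = 1),
                              size = 64, seed = 7)
  pm <- parameter_map(fld, "riig", window = 13, stride = 4)
  expect_equal(dim(pm$values), c(64, 64))
  rel <- abs(pm$values - 1)
  expect_lt(stats::median(rel), 0.25)
  expect_true(all(pm$values > 0))
})

test_that("maps at different strides agree exactly on shared centers", {
  fld <- simulate_model_field("riig", list(alpha = 2, beta = 0, delta = 1),
                              size = 32, seed = 8)
  p1 <- parameter_map(fld, "riig", window = 13, stride = 1)
  p4 <- parameter_map(fld, "riig", window = 13, stride = 4)
  g <- seq(1, 32, by = 4)
  expect_identical(p1$values[g, g], p4$values[g, g])
})

test_that("a flat sub-band yields the documented fallback and mask", {
  flat <- matrix(0.5, 20, 20)
  pm <- parameter_map(flat, "riig", window = 13, stride = 4)
  expect_true(all(!pm$converged))
  expect_equal(unique(as.vector(pm$values)), sqrt(0.25 / 2))
  pmn <- parameter_map(flat, "nakagami", window = 13, stride = 4)
  expect_true(all(!pmn$converged))
  expect_equal(unique(as.vector(pmn$values)), 100)
})

test_that("parameter_map validates its arguments", {
  x <- matrix(runif(400), 20, 20)
  expect_error(parameter_map(x, "riig", window = 12), "odd")
  expect_error(parameter_map(x, "riig", window = 3), "at least 5")
  expect_error(parameter_map(matrix(1, 8, 8), "riig", window = 13),
               "smaller than the window")
})

test_that("nakagami and nig maps carry their mapped parameters", {
  fld <- simulate_model_field("nakagami", list(m = 1, omega = 2),
                              size = 24, seed = 3)
  pm <- parameter_map(fld, "nakagami", window = 13, stride = 6)
  expect_equal(stats::median(pm$values), 1, tolerance = 0.35)
  pn <- parameter_map(fld, "nig", window = 13, stride = 12)
  expect_true(all(pn$values > 0))
})

test_that("multiplicative weighting is the rescaled product", {
  set.seed(2)
  sb <- matrix(rnorm(900), 30, 30)
  ones <- matrix(1, 30, 30)
  w <- multiplicative_weight(sb, ones)
  a <- abs(sb)
  expect_equal(w, (a - min(a)) / (max(a) - min(a)), tolerance = 1e-12)
  expect_equal(multiplicative_weight(matrix(0, 5, 5), matrix(0, 5, 5)),
               matrix(0, 5, 5))
  pm <- matrix(runif(900), 30, 30)
  prod_oracle <- abs(sb) * pm
  w2 <- multiplicative_weight(sb, pm)
  expect_equal(w2, (prod_oracle - min(prod_oracle)) /
                 diff(range(prod_oracle)), tolerance = 1e-12)
  expect_error(multiplicative_weight(sb, matrix(1, 4, 4)), "shape")
})

test_that("correlated weighting is windowed Pearson with exact bounds", {
  set.seed(4)
  sb <- matrix(rnorm(1600), 40, 40)
  expect_true(all(correlated_weight(sb, sb)$values == 1))
  expect_true(all(correlated_weight(sb, -sb)$values == -1))
  ind <- correlated_weight(sb, matrix(rnorm(1600), 40, 40))
  expect_lt(abs(mean(ind$values)), 0.05)
  # bounds on fuzzed heavy-tailed inputs
  for (s in 1:10) {
    set.seed(s)
    a <- matrix(stats::rcauchy(400), 20, 20)
    b <- matrix(stats::rcauchy(400), 20, 20)
    v <- correlated_weight(a, b)$values
    expect_true(all(v >= -1 & v <= 1))
  }
  expect_error(correlated_weight(sb, matrix(1, 4, 4)), "shape")
})

test_that("correlated weighting is invariant to positive affine maps", {
  set.seed(6)
  a <- matrix(rnorm(900), 30, 30)
  b <- matrix(rnorm(900), 30, 30)
  base <- correlated_weight(a, b)$values
  expect_lt(max(abs(correlated_weight(3 * a + 2, b)$values - base)), 1e-10)
  expect_lt(max(abs(correlated_weight(a, 0.5 * b - 7)$values - base)), 1e-10)
})

test_that("zero-variance correlation windows map to zero", {
  a <- matrix(1, 20, 20)
  b <- matrix(runif(400), 20, 20)
  expect_true(all(correlated_weight(a, b)$values == 0))
})

test_that("build_stack yields a bounded 224x224x6 stack", {
  img <- speckle_fixture(seed = 4, size = 128)
  st <- build_stack(img, "contourlet", stride = 8, label = "benign",
                    source_id = "img1")
  expect_equal(dim(st$channels), c(224, 224, 6))
  expect_true(all(st$channels >= -1 & st$channels <= 1))
  expect_equal(st$label, "benign")
  expect_equal(vapply(st$keys, format, character(1))[1], "P2D4#0")
  expect_error(build_stack(img, "contourlet",
                           keys = contourlet_default_keys()[1:5]),
               "length 6")
})

test_that("multiplicative stacks live in the unit interval", {
  img <- speckle_fixture(seed = 6, size = 128)
  st <- build_stack(img, "contourlet", stride = 16,
                    weighting = "multiplicative")
  expect_true(all(st$channels >= 0 & st$channels <= 1))
})
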