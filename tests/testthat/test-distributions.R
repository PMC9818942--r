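# Nakagami and NIG models, and pp-plot goodness of fit.

test_that("Nakagami density normalizes and moment fit inverts Rayleigh", {
  I <- stats::integrate(function(r) dnaka(r, 1.7, 2.3), 0, Inf,
                        rel.tol = 1e-9)$value
  expect_equal(I, 1, tolerance = 1e-6)
  # complex-Gaussian envelope is Rayleigh, i.e. Nakagami with m = 1
  set.seed(5)
  env <- sqrt(stats::rnorm(10000)^2 + stats::rnorm(10000)^2)
  fit <- nakagami_fit(env)
  expect_equal(fit$params$m, 1, tolerance = 0.05)
  expect_equal(fit$params$omega, mean(env^2))
  expect_error(nakagami_fit(rep(1, 50)), class = "cwriig_degenerate_error")
})

test_that("Nakagami sampler matches its analytic CDF", {
  x <- rnaka(10000, 2.5, 1.2, seed = 3)
  ks <- suppressWarnings(stats::ks.test(x, function(q) pnaka(q, 2.5, 1.2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("NIG density normalizes and rejects invalid parameters", {
  I <- stats::integrate(function(x) dnig(x, 2, 0, 1, 0), -Inf, Inf,
                        rel.tol = 1e-9)$value
  expect_equal(I, 1, tolerance = 1e-4)
  expect_error(dnig(0, 2, 2, 1), "alpha")
  expect_error(nig_fit(rep(3, 50)), class = "cwriig_degenerate_error")
})

test_that("NIG fit finds near-zero skewness on symmetric data", {
  x <- rnig(5000, 2, 0, 1, 0, seed = 4)
  fit <- nig_fit(x)
  # rough CI: beta-hat within a few standard errors of zero
  expect_lt(abs(fit$params$beta), 0.3)
  expect_true(abs(fit$params$mu) < 0.2)
})

test_that("pp-plot is self-consistent and ranks the true model first", {
  x <- rriig(10000, 3, 0, 0.8, seed = 5)
  fit <- riig_fit(x)
  pp <- pp_plot_data(x, list(riig = fit))
  expect_true(all(pp$points$p_model >= 0 & pp$points$p_model <= 1))
  expect_lt(pp$mad["riig"], 0.02)
  # RiIG-simulated data: RiIG fit tracks the empirical CDF more closely
  # than the Nakagami fit
  pp2 <- pp_plot_data(x, list(riig = fit, nakagami = nakagami_fit(x)))
  expect_lt(pp2$mad["riig"], pp2$mad["nakagami"])
})

test_that("pp-plot handles an empty model list and short samples", {
  out <- pp_plot_data(rriig(500, 2, 0, 1, seed = 1), list())
  expect_equal(nrow(out$points), 0)
  expect_length(out$mad, 0)
  expect_error(pp_plot_data(runif(50), list(f = function(q) q)),
               "at least 100")
})
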