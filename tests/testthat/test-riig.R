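# RiIG density, sampler and maximum-likelihood fitting.

test_that("the density vanishes at the origin and rejects bad input", {
  expect_equal(driig(0, 2, 0, 1), 0)
  expect_equal(driig(0, 4, -1, 0.5), 0)
  expect_error(driig(-1, 2, 0, 1), "nonnegative")
  expect_error(driig(1, 2, 3, 1), "alpha")
  expect_error(driig(1, 2, 0, -1), "delta")
})

test_that("the density integrates to one over a parameter grid", {
  for (a in c(1, 2, 4)) {
    for (b in c(-1, 0, 1)) {
      if (abs(b) >= a) next
      for (d in c(0.5, 1, 2)) {
        I <- stats::integrate(function(r) driig(r, a, b, d), 0, Inf,
                              rel.tol = 1e-8)$value
        expect_equal(I, 1, tolerance = 1e-4,
                     label = sprintf("integral at (%g,%g,%g)", a, b, d))
      }
    }
  }
})

test_that("the skewness term is even in beta through I0", {
  r <- seq(0.01, 8, length.out = 50)
  expect_identical(driig(r, 2, 1, 1), driig(r, 2, -1, 1))
})

test_that("K_{3/2} matches its closed form", {
  x <- exp(seq(log(1e-3), log(50), length.out = 200))
  closed <- sqrt(pi / (2 * x)) * exp(-x) * (1 + 1 / x)
  expect_lt(max(abs(besselK(x, 1.5) - closed) / closed), 1e-10)
})

test_that("density shape follows the parameters", {
  r <- seq(0.001, 10, length.out = 4000)
  # steeper (higher peak) with increasing alpha
  peaks <- vapply(c(1, 2, 4), function(a) max(driig(r, a, 0, 1)), numeric(1))
  expect_true(all(diff(peaks) > 0))
  # mode moves right as beta grows at fixed alpha, delta
  modes <- vapply(c(0, 1, 2), function(b) r[which.max(driig(r, 3, b, 1))],
                  numeric(1))
  expect_true(all(diff(modes) > 0))
})

test_that("the sampler is reproducible and matches the numeric CDF", {
  x1 <- rriig(1000, 2, 0, 1, seed = 4)
  x2 <- rriig(1000, 2, 0, 1, seed = 4)
  expect_identical(x1, x2)
  expect_true(all(x1 >= 0))
  expect_error(rriig(0, 2, 0, 1), "positive")
  for (p in list(c(2, 0, 1), c(3, 1.5, 0.7))) {
    x <- rriig(10000, p[1], p[2], p[3], seed = 1)
    ks <- suppressWarnings(
      stats::ks.test(x, function(q) priig(q, p[1], p[2], p[3])))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("maximum likelihood recovers delta within 10% (median of 5 seeds)", {
  errs <- vapply(1:5, function(s) {
    fit <- riig_fit(rriig(5000, 2, 0, 1, seed = s))
    abs(fit$params$delta - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("the fitted likelihood is no worse than the truth's", {
  x <- rriig(2000, 2, 0.5, 1, seed = 7)
  fit <- riig_fit(x)
  ll_true <- sum(driig(x, 2, 0.5, 1, log = TRUE))
  expect_gte(fit$loglik, ll_true - 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$params$gamma,
               sqrt(fit$params$alpha^2 - fit$params$beta^2))
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(riig_fit(rep(2, 100)), class = "cwriig_degenerate_error")
  expect_error(riig_fit(runif(10)), "at least 30")
})

test_that("the compiled window fitter agrees with the reference fitter", {
  set.seed(11)
  x <- rriig(169, 2, 0, 1)
  fr <- riig_fit(x)
  fc <- .riig_fit_cpp(x, 300)
  expect_equal(fc$loglik, fr$loglik, tolerance = 1e-3)
  expect_equal(fc$delta, fr$params$delta, tolerance = 0.05)
})

test_that("fit results tabulate for CSV export", {
  fits <- list(riig_fit(rriig(200, 2, 0, 1, seed = 1)),
               nakagami_fit(rnaka(200, 1, 2, seed = 2)))
  tab <- fits_as_table(fits, keys = c("P2D8", "P2D8"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$model, c("riig", "nakagami"))
  expect_true(all(c("alpha", "delta", "m", "loglik", "converged") %in%
                    names(tab)))
  expect_true(is.na(tab$m[1]) && !is.na(tab$m[2]))
})
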