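#' Nakagami distribution
#'
#' Density, sampler and moment fit for the Nakagami envelope model
#' \deqn{p(r) = \frac{2 m^m}{\Gamma(m)\,\omega^m} r^{2m-1}
#'   e^{-m r^2/\omega},\qquad r \ge 0,}
#' with shape `m` and spread `omega` (\eqn{\omega = E[r^2]}). Fully
#' developed speckle (complex-Gaussian scatterers) gives a Rayleigh
#' envelope, i.e. `m = 1`.
#'
#' @param r nonnegative quantiles.
#' @param m shape (`>= 0.5` for a physical envelope).
#' @param omega spread (`> 0`).
#' @param log return log-density?
#' @export
dnaka <- function(r, m, omega, log = FALSE) {
  if (m <= 0 || omega <= 0) stop("invalid Nakagami parameters", call. = FALSE)
  if (any(r < 0)) stop("r must be nonnegative", call. = FALSE)
  ld <- log(2) + m * log(m / omega) - lgamma(m) + (2 * m - 1) * log(r) -
    m * r^2 / omega
  ld[r == 0] <- if (m > 0.5) -Inf else ld[r == 0]
  if (log) ld else exp(ld)
}

#' @rdname dnaka
#' @param q quantiles.
#' @export
pnaka <- function(q, m, omega) {
  stats::pgamma(pmax(q, 0)^2, shape = m, rate = m / omega)
}

#' @rdname dnaka
#' @param n number of draws.
#' @param seed optional integer seed.
#' @export
rnaka <- function(n, m, omega, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sqrt(stats::rgamma(n, shape = m, rate = m / omega))
}

#' @rdname dnaka
#' @param samples nonnegative sample vector.
#' @details The fit uses the inverse normalized-variance moment estimator
#'   conventional in Nakagami parametric imaging:
#'   \eqn{\hat m = [E(r^2)]^2 / \mathrm{Var}(r^2)},
#'   \eqn{\hat\omega = E(r^2)}. `m` estimates are capped at 100 (a window
#'   that uniform approaches the deterministic limit).
#' @export
nakagami_fit <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  .check_degenerate(samples)
  i2 <- samples^2
  omega <- mean(i2)
  v <- stats::var(i2)
  m <- min(max(omega^2 / max(v, 1e-300), 0.5), 100)
  params <- list(m = m, omega = omega)
  ll <- sum(dnaka(samples, m, omega, log = TRUE))
  structure(list(params = params, loglik = ll, converged = TRUE,
                 n = length(samples), model = "nakagami"),
            class = "cwriig_fit")
}

#' Normal inverse Gaussian (NIG) distribution
#'
#' Density, sampler and maximum-likelihood fit for the NIG law on the real
#' line,
#' \deqn{p(x) = \frac{\alpha\delta}{\pi}
#'   \frac{K_1\!\big(\alpha\sqrt{\delta^2 + (x-\mu)^2}\big)}
#'        {\sqrt{\delta^2 + (x-\mu)^2}}
#'   e^{\delta\gamma + \beta (x-\mu)},\qquad
#'   \gamma = \sqrt{\alpha^2 - \beta^2}.}
#' The fit maximizes the likelihood from a moment initialization
#' (symmetric case: \eqn{\mathrm{Var} = \delta/\alpha}, excess kurtosis
#' \eqn{3/(\delta\alpha)}).
#'
#' @param x quantiles.
#' @param alpha,beta,delta,mu NIG parameters (`alpha > abs(beta)`,
#'   `delta > 0`).
#' @param log return log-density?
#' @export
dnig <- function(x, alpha, beta, delta, mu = 0, log = FALSE) {
  if (!is.finite(alpha) || alpha <= 0 || delta <= 0 || abs(beta) >= alpha) {
    stop("invalid NIG parameters: need alpha > |beta| and delta > 0",
         call. = FALSE)
  }
  gamma_ <- sqrt(alpha^2 - beta^2)
  s <- alpha * sqrt(delta^2 + (x - mu)^2)
  logk <- log(besselK(s, 1, expon.scaled = TRUE)) - s
  ld <- log(alpha) + log(delta) - log(pi) + delta * gamma_ +
    beta * (x - mu) + logk - 0.5 * log(delta^2 + (x - mu)^2)
  if (log) ld else exp(ld)
}

#' @rdname dnig
#' @param n number of draws.
#' @param seed optional integer seed.
#' @export
rnig <- function(n, alpha, beta, delta, mu = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gamma_ <- sqrt(alpha^2 - beta^2)
  z <- .rinvgauss(n, mean = delta / gamma_, shape = delta^2)
  mu + beta * z + sqrt(z) * stats::rnorm(n)
}

#' @rdname dnig
#' @param q quantiles.
#' @param n_grid CDF grid resolution.
#' @export
pnig <- function(q, alpha, beta, delta, mu = 0, n_grid = 8192) {
  sdv <- sqrt(delta * alpha^2 / max(alpha^2 - beta^2, 1e-12)^1.5)
  lo <- min(q[is.finite(q)], mu - 12 * sdv)
  hi <- max(q[is.finite(q)], mu + 12 * sdv)
  grid <- seq(lo, hi, length.out = n_grid)
  dens <- dnig(grid, alpha, beta, delta, mu)
  h <- grid[2] - grid[1]
  cdf <- c(0, cumsum((dens[-1] + dens[-n_grid]) / 2 * h))
  cdf <- pmin(cdf / max(cdf[n_grid], 1), 1)
  stats::approx(grid, cdf, xout = pmin(pmax(q, lo), hi), rule = 2)$y
}

#' @rdname dnig
#' @param samples numeric sample vector.
#' @param control passed to [stats::optim()].
#' @export
nig_fit <- function(samples, control = list(maxit = 100, factr = 1e10)) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 4) stop("need at least 4 samples", call. = FALSE)
  .check_degenerate(samples)
  mu0 <- mean(samples)
  v <- stats::var(samples)
  ek <- max(mean((samples - mu0)^4) / v^2 - 3, 0.05)
  delta0 <- sqrt(3 * v / ek)
  alpha0 <- min(max(delta0 / v, 1e-3), 450)
  nll <- function(par) {
    beta <- par[2]
    alpha <- abs(beta) + exp(par[1])
    delta <- exp(par[3])
    if (!is.finite(alpha) || alpha > 500 || delta > 1e3) return(1e10)
    ll <- sum(dnig(samples, alpha, beta, delta, par[4], log = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
  }
  par0 <- c(log(alpha0), 0, log(max(delta0, 1e-5)), mu0)
  opt <- tryCatch(
    stats::optim(par0, nll, method = "L-BFGS-B",
                 lower = c(log(1e-6), -500, log(1e-6), mu0 - 10 * sqrt(v)),
                 upper = c(log(500), 500, log(1e3), mu0 + 10 * sqrt(v)),
                 control = control),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) {
    params <- list(alpha = alpha0, beta = 0, delta = max(delta0, 1e-5),
                   mu = mu0)
    conv <- FALSE
    ll <- tryCatch(sum(dnig(samples, params$alpha, params$beta,
                            params$delta, params$mu, log = TRUE)),
                   error = function(e) NA_real_)
  } else {
    params <- list(alpha = abs(opt$par[2]) + exp(opt$par[1]),
                   beta = opt$par[2], delta = exp(opt$par[3]),
                   mu = opt$par[4])
    conv <- opt$convergence == 0
    ll <- -opt$value
  }
  params$gamma <- sqrt(params$alpha^2 - params$beta^2)
  structure(list(params = params, loglik = ll, converged = conv,
                 n = length(samples), model = "nig"),
            class = "cwriig_fit")
}

#' Tabulate fit results
#'
#' Flattens one or more `cwriig_fit` objects into a data.frame suitable
#' for CSV export: one row per fit with `key`, `model`, the parameters
#' (`alpha`, `beta`, `delta`, `mu`, `m`, `omega`; absent ones `NA`),
#' `loglik`, `converged` and `n`.
#'
#' @param fits a `cwriig_fit` or list of them.
#' @param keys optional character labels (e.g. sub-band keys), recycled.
#' @return data.frame.
#' @export
fits_as_table <- function(fits, keys = NULL) {
  if (inherits(fits, "cwriig_fit")) fits <- list(fits)
  if (is.null(keys)) keys <- sprintf("fit%d", seq_along(fits))
  keys <- rep_len(keys, length(fits))
  cols <- c("alpha", "beta", "delta", "mu", "m", "omega")
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    p <- stats::setNames(rep(NA_real_, length(cols)), cols)
    p[intersect(names(f$params), cols)] <-
      unlist(f$params[intersect(names(f$params), cols)])
    cbind(data.frame(key = keys[i], model = f$model),
          as.data.frame(as.list(p)),
          data.frame(loglik = f$loglik, converged = f$converged, n = f$n))
  })
  do.call(rbind, rows)
}

# CDF function of a cwriig_fit object.
.fit_cdf <- function(fit) {
  p <- fit$params
  switch(fit$model,
    riig = function(q) priig(q, p$alpha, p$beta, p$delta),
    nakagami = function(q) pnaka(q, p$m, p$omega),
    nig = function(q) pnig(q, p$alpha, p$beta, p$delta, p$mu),
    stop("unknown model: ", fit$model, call. = FALSE))
}

#' Percentile-percentile (pp) plot data
#'
#' For each candidate model, pairs the empirical quantile levels of the
#' sample (`(i - 0.5)/n` at the order statistics) with the model CDF
#' evaluated at the same points, plus the mean absolute deviation (MAD)
#' of the pairs from the diagonal. Points on the diagonal indicate a good
#' fit; the model ranking by MAD reproduces the usual visual pp-plot
#' comparison of empirical against fitted CDFs.
#'
#' @param samples numeric vector (at least 100 values).
#' @param models named list of `cwriig_fit` objects and/or CDF functions.
#' @return List with `points` (data.frame: `model`, `p_empirical`,
#'   `p_model`) and `mad` (named numeric).
#' @export
pp_plot_data <- function(samples, models) {
  if (length(models) == 0) {
    return(list(points = data.frame(model = character(),
                                    p_empirical = numeric(),
                                    p_model = numeric()),
                mad = stats::setNames(numeric(0), character(0))))
  }
  samples <- sort(samples[is.finite(samples)])
  n <- length(samples)
  if (n < 100) stop("need at least 100 samples", call. = FALSE)
  p_emp <- (seq_len(n) - 0.5) / n
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  pts <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    cdf <- if (inherits(m, "cwriig_fit")) .fit_cdf(m) else match.fun(m)
    data.frame(model = nm, p_empirical = p_emp, p_model = cdf(samples))
  })
  pts <- do.call(rbind, pts)
  mad <- vapply(split(abs(pts$p_model - pts$p_empirical), pts$model), mean,
                numeric(1))[names(models)]
  list(points = pts, mad = mad)
}
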