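#' Rician inverse Gaussian (RiIG) distribution
#'
#' The RiIG law models ultrasound envelope amplitudes as a Rice
#' distribution whose underlying variance is mixed over an inverse
#' Gaussian: with mixing variable \eqn{z \sim IG(\delta, \gamma)} (density
#' \eqn{\delta e^{\delta\gamma} z^{-3/2} \exp\{-(\delta^2/z +
#' \gamma^2 z)/2\} / \sqrt{2\pi}}) the envelope is Rice with noncentrality
#' \eqn{\beta z} and per-component variance \eqn{z}. Marginalizing gives
#' the closed form
#' \deqn{p(r) = \sqrt{2/\pi}\, \alpha^{3/2} \delta e^{\delta\gamma}\,
#'   r\, (\delta^2 + r^2)^{-3/4}\,
#'   K_{3/2}\!\big(\alpha\sqrt{\delta^2 + r^2}\big)\, I_0(\beta r)}
#' with \eqn{\gamma = \sqrt{\alpha^2 - \beta^2}}. \eqn{\alpha > |\beta|}
#' controls steepness, \eqn{\beta} skewness, \eqn{\delta > 0} dispersion.
#' Evaluation is carried out in log space with exponentially scaled Bessel
#' functions, so large arguments (\eqn{\alpha\delta} of several hundred)
#' do not overflow.
#'
#' @param r nonnegative quantiles.
#' @param alpha,beta,delta RiIG parameters (`alpha > abs(beta)`,
#'   `delta > 0`).
#' @param log return log-density?
#' @return Density values (zero at the origin).
#' @export
driig <- function(r, alpha, beta, delta, log = FALSE) {
  .check_riig(alpha, beta, delta)
  if (any(r < 0)) stop("r must be nonnegative", call. = FALSE)
  gamma_ <- sqrt(alpha^2 - beta^2)
  s <- alpha * sqrt(delta^2 + r^2)
  # besselK(expon.scaled): K(x) = scaled * exp(-x); besselI: I(x) = scaled * exp(x)
  logk <- log(besselK(s, 1.5, expon.scaled = TRUE)) - s
  logi <- log(besselI(abs(beta) * r, 0, expon.scaled = TRUE)) + abs(beta) * r
  ld <- 0.5 * log(2 / pi) + 1.5 * log(alpha) + log(delta) + delta * gamma_ +
    log(r) - 0.75 * log(delta^2 + r^2) + logk + logi
  ld[r == 0] <- -Inf
  if (log) ld else exp(ld)
}

.check_riig <- function(alpha, beta, delta) {
  if (!is.finite(alpha) || !is.finite(beta) || !is.finite(delta) ||
      alpha <= 0 || delta <= 0 || abs(beta) >= alpha) {
    stop("invalid RiIG parameters: need alpha > |beta| and delta > 0",
         call. = FALSE)
  }
}

#' @rdname driig
#' @param q quantiles for the distribution function.
#' @param n_grid resolution of the internal cumulative-trapezoid grid used
#'   to evaluate the (non-closed-form) CDF.
#' @export
priig <- function(q, alpha, beta, delta, n_grid = 8192) {
  .check_riig(alpha, beta, delta)
  hi <- max(q[is.finite(q)], .riig_upper(alpha, beta, delta))
  grid <- seq(0, hi, length.out = n_grid)
  dens <- driig(grid, alpha, beta, delta)
  h <- grid[2] - grid[1]
  cdf <- c(0, cumsum((dens[-1] + dens[-n_grid]) / 2 * h))
  cdf <- pmin(cdf / max(cdf[n_grid], 1), 1)  # guard tiny tail truncation
  out <- stats::approx(grid, cdf, xout = pmin(pmax(q, 0), hi), rule = 2)$y
  out[q <= 0] <- 0
  out
}

# A generous upper support bound: mean + 12 sd of the mixed Rice.
.riig_upper <- function(alpha, beta, delta) {
  gamma_ <- sqrt(alpha^2 - beta^2)
  ez <- delta / gamma_
  vz <- delta / gamma_^3
  m2 <- beta^2 * (ez^2 + vz) + 2 * ez
  max(10 * sqrt(m2), delta * 5, 1e-3)
}

#' @rdname driig
#' @param n number of draws.
#' @param seed optional integer seed (uses the global RNG stream when
#'   `NULL`).
#' @export
rriig <- function(n, alpha, beta, delta, seed = NULL) {
  .check_riig(alpha, beta, delta)
  if (length(n) != 1 || !is.finite(n) || n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  gamma_ <- sqrt(alpha^2 - beta^2)
  z <- .rinvgauss(n, mean = delta / gamma_, shape = delta^2)
  re <- beta * z + sqrt(z) * stats::rnorm(n)
  im <- sqrt(z) * stats::rnorm(n)
  sqrt(re^2 + im^2)
}

# Inverse Gaussian sampler (Michael, Schucany & Haas transformation).
.rinvgauss <- function(n, mean, shape) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Fit the RiIG distribution by maximum likelihood
#'
#' Maximizes the RiIG log-likelihood over \eqn{(\alpha, \beta, \delta)}
#' by bounded quasi-Newton optimization in the reparametrization
#' \eqn{(\log(\alpha - |\beta|), \beta, \log\delta)}, initialized from the
#' second and fourth sample moments of the symmetric
#' (\eqn{\beta = 0}) case: \eqn{m_4/(2 m_2^2) = 1 + 1/(\delta\gamma)} and
#' \eqn{m_2 = 2\delta/\gamma}. If optimization fails the moment estimates
#' are returned with `converged = FALSE`; a degenerate (all-equal) sample
#' is an error.
#'
#' @param samples nonnegative numeric vector, at least `min_n` values.
#' @param min_n minimum sample count (default 30).
#' @param control passed to [stats::optim()] (`method = "L-BFGS-B"`).
#' @return A `cwriig_fit` object: list with `params`
#'   (`alpha`, `beta`, `delta`, `gamma`), `loglik`, `converged`, `n`,
#'   `model = "riig"`.
#' @export
riig_fit <- function(samples, min_n = 30,
                     control = list(maxit = 60, factr = 1e10)) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < min_n) {
    stop("need at least ", min_n, " finite samples", call. = FALSE)
  }
  if (any(samples < 0)) stop("samples must be nonnegative", call. = FALSE)
  .check_degenerate(samples)
  init <- .riig_moment_init(samples)
  nll <- function(par) {
    beta <- par[2]
    alpha <- abs(beta) + exp(par[1])
    delta <- exp(par[3])
    if (!is.finite(alpha) || alpha > 500 || delta > 1e3) return(1e10)
    ll <- sum(driig(samples, alpha, beta, delta, log = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
  }
  par0 <- c(log(max(init$alpha - abs(init$beta), 1e-4)), init$beta,
            log(init$delta))
  opt <- tryCatch(
    stats::optim(par0, nll, method = "L-BFGS-B",
                 lower = c(log(1e-6), -500, log(1e-6)),
                 upper = c(log(500), 500, log(1e3)),
                 control = control),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) {
    params <- list(alpha = init$alpha, beta = init$beta, delta = init$delta)
    conv <- FALSE
    ll <- tryCatch(sum(driig(samples, params$alpha, params$beta,
                             params$delta, log = TRUE)),
                   error = function(e) NA_real_)
  } else {
    params <- list(alpha = abs(opt$par[2]) + exp(opt$par[1]),
                   beta = opt$par[2], delta = exp(opt$par[3]))
    conv <- opt$convergence == 0
    ll <- -opt$value
  }
  params$gamma <- sqrt(params$alpha^2 - params$beta^2)
  structure(list(params = params, loglik = ll, converged = conv,
                 n = length(samples), model = "riig"),
            class = "cwriig_fit")
}

.check_degenerate <- function(samples) {
  if (stats::sd(samples) < 1e-12 * (abs(mean(samples)) + 1e-300)) {
    stop(structure(class = c("cwriig_degenerate_error", "error", "condition"),
                   list(message = "degenerate (all-equal) sample",
                        call = NULL)))
  }
}

# Moment initialization under beta = 0 (see riig_fit details).
.riig_moment_init <- function(samples) {
  m2 <- mean(samples^2)
  m4 <- mean(samples^4)
  r <- m4 / (2 * m2^2)
  dg <- 1 / max(r - 1, 0.02)           # delta * gamma
  delta <- sqrt(max(m2 * dg / 2, 1e-10))
  gamma_ <- dg / delta
  list(alpha = min(max(gamma_, 1e-3), 450), beta = 0,
       delta = min(max(delta, 1e-5), 990))
}

#' @export
print.cwriig_fit <- function(x, ...) {
  cat("<", x$model, " fit: ",
      paste(names(x$params),
            sprintf("%.4g", unlist(x$params)), sep = "=", collapse = " "),
      "; loglik=", sprintf("%.4g", x$loglik),
      "; converged=", x$converged, "; n=", x$n, ">\n", sep = "")
  invisible(x)
}
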