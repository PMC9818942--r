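# Sliding-window parametric imaging and sub-band weighting.

.coeffs <- function(x) {
  if (inherits(x, "subband_image")) x$coeffs
  else if (inherits(x, c("parametric_image", "cw_image"))) x$values
  else if (is.matrix(x)) x
  else stop("expected a subband_image / parametric_image / matrix",
            call. = FALSE)
}

.key_of <- function(x) {
  if (inherits(x, "subband_image")) x$key
  else if (inherits(x, c("parametric_image", "cw_image"))) x$source_key
  else NULL
}

# Symmetric (reflect without repeating the edge sample's neighbor twice;
# classic half-sample symmetric) padding by h on every side.
.pad_symmetric <- function(x, h) {
  n1 <- nrow(x); n2 <- ncol(x)
  idx <- function(n) {
    i <- c(h:1, 1:n, n:(n - h + 1))
    pmin(pmax(i, 1), n)
  }
  x[idx(n1), idx(n2)]
}

#' Sliding-window parametric image
#'
#' Slides a square window over a sub-band coefficient image, fits the
#' chosen envelope model to the absolute coefficient values in each
#' window, and writes the mapped parameter at the window center: the RiIG
#' dispersion \eqn{\delta}, the Nakagami shape \eqn{m}, or the NIG
#' steepness \eqn{\alpha}. Borders are handled by symmetric padding so the
#' map has the same extent as the sub-band. With `stride > 1` the fit is
#' computed on the stride grid and remaining pixels take the value of the
#' nearest computed center, so maps at different strides agree exactly on
#' the shared grid points.
#'
#' Windows on which the fit degenerates (all-equal values) or fails to
#' converge carry a documented moment fallback (RiIG:
#' \eqn{\delta = \sqrt{E[r^2]/2}}; Nakagami: capped \eqn{m}; NIG:
#' \eqn{\alpha} at its upper bound) and are flagged in the `converged`
#' matrix.
#'
#' @param subband `subband_image` or numeric matrix, at least
#'   `window` x `window`.
#' @param model `"riig"`, `"nakagami"` or `"nig"`.
#' @param window odd window side, at least 5 (default 13).
#' @param stride positive integer step between fitted centers.
#' @param control optimizer control for the Nakagami/NIG likelihood fits.
#' @param max_evals likelihood-evaluation budget per window for the RiIG
#'   simplex fitter (compiled fast path; same likelihood and moment
#'   initialization as [riig_fit()]).
#' @return A `parametric_image`: list with `values` (matrix, same extent
#'   as the input), `converged` (logical matrix), `source_key`, `window`,
#'   `stride`, `model`.
#' @export
parameter_map <- function(subband, model = c("riig", "nakagami", "nig"),
                          window = 13, stride = 1,
                          control = list(maxit = 30, factr = 1e11),
                          max_evals = 120) {
  model <- match.arg(model)
  x <- abs(.coeffs(subband))
  if (window %% 2 == 0 || window < 5) {
    stop("window must be odd and at least 5", call. = FALSE)
  }
  if (nrow(x) < window || ncol(x) < window) {
    stop("sub-band (", nrow(x), "x", ncol(x),
         ") is smaller than the window", call. = FALSE)
  }
  if (stride < 1) stop("stride must be positive", call. = FALSE)
  h <- (window - 1) / 2
  xp <- .pad_symmetric(x, h)
  n1 <- nrow(x); n2 <- ncol(x)
  g1 <- unique(c(seq(1, n1, by = stride), n1))
  g2 <- unique(c(seq(1, n2, by = stride), n2))

  if (model == "riig") {
    res <- .riig_map_cpp(xp, window, as.integer(g1), as.integer(g2),
                         as.integer(max_evals))
    vals <- res$values
    conv <- res$converged
  } else {
    # All windows of the grid as columns of one matrix.
    woff <- as.vector(outer(seq_len(window), (seq_len(window) - 1) * nrow(xp),
                            "+")) - 1
    vals <- matrix(NA_real_, length(g1), length(g2))
    conv <- matrix(FALSE, length(g1), length(g2))
    for (j in seq_along(g2)) {
      base <- (g2[j] - 1) * nrow(xp)
      for (i in seq_along(g1)) {
        w <- xp[base + (g1[i] - 1) + woff + 1]
        fit <- .window_fit(w, model, control)
        vals[i, j] <- fit$value
        conv[i, j] <- fit$converged
      }
    }
  }
  # Fill every pixel from the nearest computed center.
  near1 <- vapply(seq_len(n1), function(i) which.min(abs(g1 - i)), integer(1))
  near2 <- vapply(seq_len(n2), function(j) which.min(abs(g2 - j)), integer(1))
  structure(list(values = vals[near1, near2, drop = FALSE],
                 converged = conv[near1, near2, drop = FALSE],
                 source_key = .key_of(subband), window = window,
                 stride = stride, model = model),
            class = "parametric_image")
}

.window_fit <- function(w, model, control) {
  fb <- .window_fallback(w, model)
  fit <- tryCatch(
    switch(model,
      riig = riig_fit(w, min_n = min(30, length(w)), control = control),
      nakagami = nakagami_fit(w),
      nig = nig_fit(w, control = control)),
    cwriig_degenerate_error = function(e) NULL,
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    value <- if (!is.null(fit)) .mapped_param(fit) else fb
    if (!is.finite(value)) value <- fb
    list(value = value, converged = FALSE)
  } else {
    list(value = .mapped_param(fit), converged = TRUE)
  }
}

.mapped_param <- function(fit) {
  switch(fit$model, riig = fit$params$delta, nakagami = fit$params$m,
         nig = fit$params$alpha)
}

.window_fallback <- function(w, model) {
  m2 <- mean(w^2)
  switch(model,
    riig = max(sqrt(m2 / 2), 1e-6),
    nakagami = 100,
    nig = 500)
}

#' Multiplicative sub-band weighting
#'
#' Weights a sub-band by elementwise multiplication of its absolute
#' coefficients with the parametric image, then min-max rescales to
#' `[0, 1]` (the comparison path to correlated weighting).
#'
#' @param subband `subband_image` or matrix.
#' @param pmap `parametric_image` or matrix of the same extent.
#' @return Numeric matrix in `[0, 1]`.
#' @export
multiplicative_weight <- function(subband, pmap) {
  x <- abs(.coeffs(subband)); p <- .coeffs(pmap)
  if (!all(dim(x) == dim(p))) {
    stop("sub-band and parametric image shapes differ", call. = FALSE)
  }
  w <- x * p
  rng <- range(w)
  if (rng[2] > rng[1]) (w - rng[1]) / (rng[2] - rng[1]) else w * 0
}

# Local box sums over a (2h+1)^2 window with symmetric padding, via
# 2-D cumulative sums.
.box_sum <- function(x, h) {
  xp <- .pad_symmetric(x, h)
  cs <- apply(apply(xp, 2, cumsum), 1, cumsum)  # transposed cumsum matrix
  cs <- t(cs)
  Z <- matrix(0, nrow(cs) + 1, ncol(cs) + 1)
  Z[-1, -1] <- cs
  n1 <- nrow(x); n2 <- ncol(x); w <- 2 * h + 1
  i1 <- (1:n1); i2 <- (1:n2)
  Z[i1 + w, i2 + w] - Z[i1, i2 + w] - Z[i1 + w, i2] + Z[i1, i2]
}

#' Correlated sub-band weighting
#'
#' At every pixel, computes the Pearson correlation between the window of
#' the sub-band coefficient image and the co-located window of its
#' parametric image, yielding the correlated-weighted image whose values
#' are bounded in \eqn{[-1, 1]}. Windows in which either side has zero
#' variance map to 0. Symmetric padding keeps the output extent equal to
#' the input.
#'
#' @param subband `subband_image` or matrix.
#' @param pmap `parametric_image` or matrix of the same extent.
#' @param window odd correlation window side (default 13, mirroring the
#'   parameter-map window).
#' @return A `cw_image`: list with `values` (matrix in `[-1, 1]`),
#'   `source_key`, `window`.
#' @export
correlated_weight <- function(subband, pmap, window = 13) {
  x <- .coeffs(subband); p <- .coeffs(pmap)
  if (!all(dim(x) == dim(p))) {
    stop("sub-band and parametric image shapes differ", call. = FALSE)
  }
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  h <- (window - 1) / 2
  n <- window^2
  sx <- .box_sum(x, h); sp <- .box_sum(p, h)
  sxx <- .box_sum(x * x, h); spp <- .box_sum(p * p, h)
  sxp <- .box_sum(x * p, h)
  vx <- n * sxx - sx^2
  vp <- n * spp - sp^2
  # Guard round-off: variances are nonnegative up to cancellation error.
  tolx <- 1e-10 * pmax(n * sxx, 1e-300)
  tolp <- 1e-10 * pmax(n * spp, 1e-300)
  num <- n * sxp - sx * sp
  den <- sqrt(pmax(vx, 0) * pmax(vp, 0))
  r <- ifelse(vx <= tolx | vp <= tolp | den == 0, 0, num / den)
  r <- pmin(pmax(r, -1), 1)
  structure(list(values = r, source_key = .key_of(subband), window = window),
            class = "cw_image")
}

#' Build a six-channel classification stack
#'
#' Runs the image-level pipeline for one B-mode image: multiresolution
#' decomposition, selection of the six default sub-bands (or caller-given
#' keys), sliding-window parametric mapping per band, correlated (or
#' multiplicative) weighting, bilinear resize of each weighted band to
#' `size` x `size`, and stacking in key order.
#'
#' @param image numeric matrix (B-mode image, values in `[0, 1]`).
#' @param transform `"contourlet"` or `"curvelet"`.
#' @param model envelope model for the parametric maps.
#' @param keys list of six `subband_key`s or strings; defaults to the
#'   transform's six-band selection.
#' @param window sliding-window side for mapping and correlation.
#' @param stride parameter-map stride.
#' @param weighting `"correlated"` (values in `[-1, 1]`) or
#'   `"multiplicative"` (values in `[0, 1]`).
#' @param size output channel extent (default 224).
#' @param label optional class label stored with the stack.
#' @param source_id optional originating-image identifier.
#' @param control optimizer control for the window fits.
#' @return A `subband_stack`: list with `channels`
#'   (`size` x `size` x 6 array), `keys`, `label`, `source_id`.
#' @export
build_stack <- function(image, transform = c("contourlet", "curvelet"),
                        model = c("riig", "nakagami", "nig"), keys = NULL,
                        window = 13, stride = 1,
                        weighting = c("correlated", "multiplicative"),
                        size = 224, label = NA_character_, source_id = NULL,
                        control = list(maxit = 30, factr = 1e11)) {
  transform <- match.arg(transform)
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  if (is.null(keys)) {
    keys <- if (transform == "contourlet") contourlet_default_keys()
            else curvelet_default_keys()
  }
  if (length(keys) != 6) stop("keys must have length 6", call. = FALSE)
  dec <- if (transform == "contourlet") contourlet_decompose(image)
         else curvelet_decompose(image)
  bands <- select_subbands(dec, keys)
  channels <- array(NA_real_, c(size, size, 6))
  for (i in seq_along(bands)) {
    pmap <- parameter_map(bands[[i]], model, window = window,
                          stride = stride, control = control)
    # The sub-band enters both weighting paths as its coefficient
    # magnitude (the envelope the models are fitted to); curvelet bands
    # already are magnitudes, contourlet bands are rectified here.
    wimg <- if (weighting == "correlated") {
      correlated_weight(abs(bands[[i]]$coeffs), pmap,
                        window = window)$values
    } else {
      multiplicative_weight(bands[[i]], pmap)
    }
    channels[, , i] <- resize_bilinear(wimg, size)
  }
  structure(list(channels = channels, keys = bands |>
                   lapply(function(b) b$key),
                 label = label, source_id = source_id),
            class = "subband_stack")
}
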