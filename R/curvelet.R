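#' Curvelet decomposition
#'
#' Second-generation curvelet transform built from a polar-like tiling of
#' the 2-D frequency plane: Meyer-type smooth radial windows split the
#' spectrum into dyadic scale annuli and raised-cosine angular windows
#' split each annulus into wedges. The squared window magnitudes sum to
#' exactly one over the whole plane, so the transform is a tight frame:
#' coefficient energy equals image energy (Parseval) and the adjoint is the
#' inverse. Wedge coefficients are complex; coarser scales are spectrally
#' decimated. A scale may expose several angular trees (for example 16-,
#' 32- and 64-wedge splittings of the finest annulus); the first count per
#' scale is the primary tree used for Parseval and reconstruction, each
#' tree being an exact angular partition on its own.
#'
#' Scale numbering follows the coarse-to-fine convention used by the
#' sub-band keys `S2A16 ... S5A64`: scale 1 is the isotropic coarse band,
#' scale `n_scales` the finest annulus (which also covers the spectrum
#' corners).
#'
#' @param image numeric matrix; both dimensions divisible by
#'   `2^(n_scales - 1)`.
#' @param n_scales total number of scales including the coarse band
#'   (at least 2).
#' @param angles_per_scale list of integer vectors, one per detail scale
#'   `2..n_scales`; every angle count must be divisible by 4.
#' @return Object of class `curvelet_decomposition` with elements `coarse`
#'   (complex matrix), `scales` (named list `"2"`..`"<n_scales>"`, each a
#'   named list of angular trees, each tree a list of complex wedge
#'   matrices), `dim`, `n_scales`, `angles_per_scale`.
#' @seealso [curvelet_reconstruct()], [select_subbands()],
#'   [curvelet_default_keys()]
#' @export
curvelet_decompose <- function(image, n_scales = 5,
                               angles_per_scale = list(16, 32, 32, c(64, 16, 32))) {
  image <- as_gray_image(image, normalize = FALSE)
  n1 <- nrow(image); n2 <- ncol(image)
  if (n_scales < 2) stop("n_scales must be at least 2", call. = FALSE)
  if (length(angles_per_scale) != n_scales - 1) {
    stop("angles_per_scale must have one entry per detail scale (",
         n_scales - 1, ")", call. = FALSE)
  }
  for (a in unlist(angles_per_scale)) {
    if (a %% 4 != 0) stop("angle counts must be divisible by 4, got ", a,
                          call. = FALSE)
  }
  if (n1 %% 2^(n_scales - 1) != 0 || n2 %% 2^(n_scales - 1) != 0) {
    stop("image dimensions must be divisible by 2^(n_scales-1) = ",
         2^(n_scales - 1), call. = FALSE)
  }
  X <- stats::fft(image)
  S <- n_scales

  scales <- list()
  for (s in 2:S) {
    m1 <- n1 / 2^(S - s); m2 <- n2 / 2^(S - s)
    Sc <- .crop_spectrum(X, m1, m2)
    W <- .curvelet_radial(m1, m2, s, S)
    trees <- list()
    for (A in angles_per_scale[[s - 1]]) {
      wedges <- vector("list", A)
      Vs <- .curvelet_angular(m1, m2, A)
      for (a in seq_len(A)) {
        wedges[[a]] <- .band_from_spectrum(Sc * (W * Vs[[a]]), n1, n2)
      }
      trees[[as.character(A)]] <- wedges
    }
    scales[[as.character(s)]] <- trees
  }

  mc1 <- n1 / 2^(S - 1); mc2 <- n2 / 2^(S - 1)
  Phi1 <- .curvelet_lowpass(mc1, mc2, S)
  coarse <- .band_from_spectrum(.crop_spectrum(X, mc1, mc2) * Phi1, n1, n2)

  structure(list(coarse = coarse, scales = scales, dim = c(n1, n2),
                 n_scales = S, angles_per_scale = angles_per_scale),
            class = "curvelet_decomposition")
}

# Meyer auxiliary polynomial: smooth, nu(0)=0, nu(1)=1, nu(t)+nu(1-t)=1.
.meyer_nu <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
}

# Smooth radial step: 1 for rho <= b/2, 0 for rho >= b, Meyer transition.
.radial_phi <- function(rho, b) {
  a <- b / 2
  out <- numeric(length(rho))
  out[rho <= a] <- 1
  tr <- rho > a & rho < b
  out[tr] <- cos(pi / 2 * .meyer_nu((rho[tr] - a) / (b - a)))
  out
}

# Radial window of detail scale s on its crop grid. Window arguments use
# frequencies normalized by the ORIGINAL image size; because crops shrink
# in step with the scale, the normalized index k/m on the crop equals
# k/n * 2^(S-s), so rho can be computed locally.
.curvelet_radial <- function(m1, m2, s, S) {
  g <- .freq_grid(m1, m2)
  rho <- 2 * sqrt((g$k1 / m1)^2 + (g$k2 / m2)^2) / 2^(S - s)
  b_s <- 2^(-(S - s))      # outer support edge of scale s
  phi_s  <- if (s == S) rep(1, length(rho)) else .radial_phi(rho, b_s)
  phi_sm <- .radial_phi(rho, b_s / 2)
  matrix(sqrt(pmax(phi_s^2 - phi_sm^2, 0)), m1, m2)
}

.curvelet_lowpass <- function(m1, m2, S) {
  g <- .freq_grid(m1, m2)
  rho <- 2 * sqrt((g$k1 / m1)^2 + (g$k2 / m2)^2) / 2^(S - 1)
  matrix(.radial_phi(rho, 2^(-(S - 1))), m1, m2)
}

# A overlapping raised-cosine angular windows over [0, 2pi) with
# sum-of-squares exactly 1 (Meyer complementarity in each overlap).
.curvelet_angular <- function(m1, m2, A) {
  g <- .freq_grid(m1, m2)
  theta <- atan2(g$k1 / m1, g$k2 / m2) %% (2 * pi)
  delta <- 2 * pi / A
  lapply(seq_len(A) - 1L, function(a) {
    d <- abs((theta - a * delta + pi) %% (2 * pi) - pi) / delta
    matrix(ifelse(d < 1, cos(pi / 2 * .meyer_nu(d)), 0), m1, m2)
  })
}

#' Reconstruct an image from a curvelet decomposition
#'
#' Applies the adjoint of [curvelet_decompose()] using the coarse band and
#' the primary angular tree of each detail scale; for a tight frame the
#' adjoint is the inverse, so the round trip is exact up to FFT round-off.
#'
#' @param dec a `curvelet_decomposition`.
#' @return Real matrix with the original spatial extent.
#' @export
curvelet_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "curvelet_decomposition"))
  n1 <- dec$dim[1]; n2 <- dec$dim[2]
  S <- dec$n_scales
  Xhat <- matrix(0i, n1, n2)
  for (s in 2:S) {
    tree <- dec$scales[[as.character(s)]][[1]]
    A <- length(tree)
    m1 <- nrow(tree[[1]]); m2 <- ncol(tree[[1]])
    W <- .curvelet_radial(m1, m2, s, S)
    Vs <- .curvelet_angular(m1, m2, A)
    Ssum <- matrix(0i, m1, m2)
    for (a in seq_len(A)) {
      Ssum <- Ssum + .spectrum_from_band(tree[[a]], n1, n2) * (W * Vs[[a]])
    }
    Xhat <- Xhat + .pad_spectrum(Ssum, n1, n2)
  }
  mc1 <- nrow(dec$coarse); mc2 <- ncol(dec$coarse)
  Phi1 <- .curvelet_lowpass(mc1, mc2, S)
  Xhat <- Xhat +
    .pad_spectrum(.spectrum_from_band(dec$coarse, n1, n2) * Phi1, n1, n2)
  Re(stats::fft(Xhat, inverse = TRUE)) / (n1 * n2)
}

#' Total coefficient energy of a curvelet decomposition
#'
#' Sum of squared coefficient magnitudes over the coarse band and the
#' primary angular tree of each detail scale. For any input this equals
#' the image energy `sum(x^2)` up to floating-point round-off (tight
#' frame).
#'
#' @param dec a `curvelet_decomposition`.
#' @return Scalar energy.
#' @export
curvelet_energy <- function(dec) {
  stopifnot(inherits(dec, "curvelet_decomposition"))
  e <- sum(Mod(dec$coarse)^2)
  for (s in 2:dec$n_scales) {
    tree <- dec$scales[[as.character(s)]][[1]]
    e <- e + sum(vapply(tree, function(w) sum(Mod(w)^2), numeric(1)))
  }
  e
}
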