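#' Contourlet decomposition
#'
#' Decomposes a grayscale image into a multiscale, multidirectional
#' representation: a pyramid of square frequency annuli (one per pyramidal
#' level, spectrally decimated so level \eqn{l} is sampled on a grid
#' \eqn{2^{l-1}} times smaller than the input per axis), each annulus split
#' into directional wedge sub-bands by an exact binary partition of the DFT
#' plane. A pyramidal level may expose several directional trees (for
#' example 4- and 8-direction decompositions of the same level-2 annulus),
#' which is how both the `P2D4` and `P2D8` sub-bands of the default
#' six-band selection coexist. The partition is exact, so reconstruction is
#' perfect up to FFT round-off, directional bands of a constant image are
#' identically zero, and the map is linear in the input.
#'
#' @param image numeric matrix, the input image. Both dimensions must be
#'   divisible by `2^length(directions_per_level)`.
#' @param directions_per_level list with one element per pyramidal level
#'   (level 1 = finest annulus, level `L` = coarsest before the lowpass);
#'   each element is an integer vector of directional counts (powers of 2)
#'   to expose at that level. The first count of each level is the primary
#'   tree used for reconstruction.
#' @return An object of class `contourlet_decomposition` with elements
#'   `lowpass` (real matrix), `levels` (per level, a named list of trees;
#'   each tree a list of real directional sub-band matrices), `dim`,
#'   `n_levels` and `directions_per_level`.
#' @seealso [contourlet_reconstruct()], [select_subbands()],
#'   [contourlet_default_keys()]
#' @examples
#' x <- matrix(runif(64 * 64), 64, 64)
#' dec <- contourlet_decompose(x, list(4, c(4, 8)))
#' max(abs(contourlet_reconstruct(dec) - x)) < 1e-8
#' @export
contourlet_decompose <- function(image,
                                 directions_per_level = list(4, c(4, 8), c(8, 16), c(16, 32))) {
  image <- as_gray_image(image, normalize = FALSE)
  n1 <- nrow(image); n2 <- ncol(image)
  L <- length(directions_per_level)
  if (L < 1) stop("directions_per_level must name at least one level", call. = FALSE)
  for (d in unlist(directions_per_level)) {
    if (!.is_pow2(d)) {
      stop("direction counts must be powers of 2, got ", d, call. = FALSE)
    }
  }
  if (n1 %% 2^L != 0 || n2 %% 2^L != 0) {
    stop("image dimensions (", n1, "x", n2, ") must be divisible by 2^levels = ",
         2^L, call. = FALSE)
  }
  if (min(n1, n2) / 2^L < 2) {
    stop("image too small for ", L, " pyramid levels", call. = FALSE)
  }
  X <- stats::fft(image)

  levels <- vector("list", L)
  for (l in seq_len(L)) {
    m1 <- n1 / 2^(l - 1); m2 <- n2 / 2^(l - 1)
    S <- .crop_spectrum(X, m1, m2)
    ring <- .contourlet_ring(m1, m2, outermost = (l == 1))
    trees <- list()
    for (D in directions_per_level[[l]]) {
      wd <- .wedge_assignment(m1, m2, D)
      bands <- vector("list", D)
      for (d in seq_len(D) - 1L) {
        mask <- ring & (wd == d)
        Sd <- S
        Sd[!mask] <- 0i
        bands[[d + 1L]] <- Re(.band_from_spectrum(Sd, n1, n2))
      }
      trees[[as.character(D)]] <- bands
    }
    levels[[l]] <- trees
  }

  mlow1 <- n1 / 2^L; mlow2 <- n2 / 2^L
  Slow <- .crop_spectrum(X, mlow1, mlow2)
  g <- .freq_grid(mlow1, mlow2)
  inner <- g$k1 > -mlow1 / 2 & g$k1 < mlow1 / 2 &
           g$k2 > -mlow2 / 2 & g$k2 < mlow2 / 2
  Slow[!inner] <- 0i
  lowpass <- Re(.band_from_spectrum(Slow, n1, n2))

  structure(list(lowpass = lowpass, levels = levels, dim = c(n1, n2),
                 n_levels = L, directions_per_level = directions_per_level),
            class = "contourlet_decomposition")
}

# Strict-interior box {max-norm < m/4 per axis}; used both as the lowpass
# support and as the hole of each annulus. Strict interiors keep every
# conjugate index pair intact on the decimated grid, which is what makes
# all directional bands exactly real-valued.
.box_interior <- function(m1, m2) {
  g <- .freq_grid(m1, m2)
  h1 <- m1 / 4; h2 <- m2 / 4
  g$k1 > -h1 & g$k1 < h1 & g$k2 > -h2 & g$k2 < h2
}

.contourlet_ring <- function(m1, m2, outermost) {
  if (outermost) {
    # Outermost annulus also owns the Nyquist shell of the full grid.
    !.box_interior(m1, m2)
  } else {
    g <- .freq_grid(m1, m2)
    h1 <- m1 / 2; h2 <- m2 / 2
    inside <- g$k1 > -h1 & g$k1 < h1 & g$k2 > -h2 & g$k2 < h2
    inside & !.box_interior(m1, m2)
  }
}

# Assign every frequency bin to one of D directional wedges covering
# [0, pi). Each conjugate pair is assigned through a canonical
# representative so wedge masks are exactly Hermitian-symmetric.
.wedge_assignment <- function(m1, m2, D) {
  g <- .freq_grid(m1, m2)
  # Conjugate partner of each bin on this grid (Nyquist rows are self-paired
  # modulo the grid). Both members of a pair share one canonical
  # representative, so they always land in the same wedge and every wedge
  # mask is exactly Hermitian-symmetric.
  p1 <- ifelse(g$k1 == -m1 / 2, -m1 / 2, -g$k1)
  p2 <- ifelse(g$k2 == -m2 / 2, -m2 / 2, -g$k2)
  use_p <- (p1 < g$k1) | (p1 == g$k1 & p2 < g$k2)
  c1 <- ifelse(use_p, p1, g$k1)
  c2 <- ifelse(use_p, p2, g$k2)
  theta <- atan2(c1 / m1, c2 / m2) %% pi
  d <- floor(theta / pi * D)
  matrix(pmin(pmax(d, 0), D - 1), m1, m2)
}

#' Reconstruct an image from a contourlet decomposition
#'
#' Inverts [contourlet_decompose()]. For each pyramidal level the primary
#' (first) directional tree is used; every tree of a level is an exact
#' partition of the same annulus, so any one suffices.
#'
#' @param dec a `contourlet_decomposition`.
#' @return Real matrix with the original spatial extent.
#' @export
contourlet_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "contourlet_decomposition"))
  n1 <- dec$dim[1]; n2 <- dec$dim[2]
  Xhat <- matrix(0i, n1, n2)
  for (l in seq_len(dec$n_levels)) {
    tree <- dec$levels[[l]][[1]]
    m1 <- n1 / 2^(l - 1); m2 <- n2 / 2^(l - 1)
    Ssum <- matrix(0i, m1, m2)
    for (band in tree) {
      if (nrow(band) != m1 || ncol(band) != m2) {
        stop("inconsistent band shape at level ", l, call. = FALSE)
      }
      Ssum <- Ssum + .spectrum_from_band(band, n1, n2)
    }
    Xhat <- Xhat + .pad_spectrum(Ssum, n1, n2)
  }
  Xhat <- Xhat + .pad_spectrum(.spectrum_from_band(dec$lowpass, n1, n2), n1, n2)
  Re(stats::fft(Xhat, inverse = TRUE)) / (n1 * n2)
}
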