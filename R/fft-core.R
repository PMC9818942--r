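# Shared spectral machinery for the multiresolution transforms.
#
# Both decompositions tile the 2-D DFT plane and store each tile on the
# smallest dyadic grid that contains its support (spectral decimation).
# Coefficients carry a unitary normalization so that summed squared
# magnitudes over a complete tiling equal the image energy.

# Signed DFT frequency indices for an even length n: 0..n/2-1, -n/2..-1.
.fidx <- function(n) {
  k <- 0:(n - 1)
  k[k >= n / 2] <- k[k >= n / 2] - n
  k
}

# Extract the central (signed index in [-m/2, m/2-1]) block of a spectrum,
# preserving signed indices. m1/m2 must divide the original dimensions.
.crop_spectrum <- function(X, m1, m2) {
  i1 <- (.fidx(m1) %% nrow(X)) + 1
  i2 <- (.fidx(m2) %% ncol(X)) + 1
  X[i1, i2, drop = FALSE]
}

# Adjoint of .crop_spectrum: place an m1 x m2 block back into an n1 x n2
# zero spectrum at the same signed indices.
.pad_spectrum <- function(S, n1, n2) {
  Z <- matrix(0i, n1, n2)
  i1 <- (.fidx(nrow(S)) %% n1) + 1
  i2 <- (.fidx(ncol(S)) %% n2) + 1
  Z[i1, i2] <- S
  Z
}

# Cropped masked spectrum -> spatial coefficients, unitary scaling.
.band_from_spectrum <- function(S, n1, n2) {
  m1 <- nrow(S); m2 <- ncol(S)
  stats::fft(S, inverse = TRUE) / sqrt(as.numeric(m1) * m2 * n1 * n2)
}

# Spatial coefficients -> cropped spectrum (inverse of .band_from_spectrum).
.spectrum_from_band <- function(band, n1, n2) {
  m1 <- nrow(band); m2 <- ncol(band)
  stats::fft(band) * sqrt(as.numeric(n1) * n2 / (m1 * m2))
}

# Matrices of signed frequency indices on an m1 x m2 grid.
.freq_grid <- function(m1, m2) {
  list(k1 = matrix(.fidx(m1), m1, m2),
       k2 = matrix(.fidx(m2), m1, m2, byrow = TRUE))
}

.is_pow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
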