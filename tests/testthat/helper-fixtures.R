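# Shared fixtures, all generated in code.

rand_image <- function(n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

speckle_fixture <- function(seed = 2, size = 128) {
  cfg <- benign_config(seed = seed)
  cfg$size <- as.integer(size)
  simulate_speckle(cfg)
}

# Stack with class-dependent channel means on a noise floor; linearly
# separable by construction.
toy_stack <- function(label, i, mu = 0.15, sd = 0.3) {
  sign <- if (label == "malignant") 1 else -1
  set.seed(1000 + i + 7000 * (label == "malignant"))
  structure(list(channels = array(stats::rnorm(224 * 224 * 6, sign * mu, sd),
                                  c(224, 224, 6)),
                 label = label, source_id = paste0(label, "_", i)),
            class = "subband_stack")
}

toy_stacks <- function(n_per_class, mu = 0.15, sd = 0.3) {
  c(lapply(seq_len(n_per_class), function(i) toy_stack("benign", i, mu, sd)),
    lapply(seq_len(n_per_class), function(i) toy_stack("malignant", i, mu, sd)))
}

# Minimal uncompressed 8-bit grayscale BMP writer (for reader tests).
write_bmp_fixture <- function(img, path) {
  h <- nrow(img); w <- ncol(img)
  stride <- ((w + 3) %/% 4) * 4
  pixel_bytes <- stride * h
  offset <- 14 + 40 + 4 * 256
  filesize <- offset + pixel_bytes
  le <- function(x, n) as.raw((x %/% 256^(0:(n - 1))) %% 256)
  header <- c(charToRaw("BM"), le(filesize, 4), le(0, 4), le(offset, 4),
              le(40, 4), le(w, 4), le(h, 4), le(1, 2), le(8, 2), le(0, 4),
              le(pixel_bytes, 4), le(2835, 4), le(2835, 4), le(256, 4),
              le(0, 4))
  pal <- as.raw(as.vector(rbind(0:255, 0:255, 0:255, rep(0, 256))))
  rows <- lapply(h:1, function(r) {
    v <- as.integer(round(pmin(pmax(img[r, ], 0), 1) * 255))
    as.raw(c(v, rep(0, stride - w)))
  })
  writeBin(c(header, pal, unlist(rows)), path)
  invisible(path)
}
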