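# Multiresolution transforms: perfect reconstruction, tight-frame
# energy, directional zero-DC, linearity, and sub-band addressing.

test_that("contourlet round trip is exact on random images", {
  for (seed in 1:3) {
    x <- rand_image(64, seed)
    dec <- contourlet_decompose(x, list(4, c(4, 8)))
    expect_lt(max(abs(contourlet_reconstruct(dec) - x)), 1e-8)
  }
  x <- rand_image(128, 9)
  dec <- contourlet_decompose(x)  # default 4-level, multi-tree config
  expect_lt(max(abs(contourlet_reconstruct(dec) - x)), 1e-8)
})

test_that("contourlet round trip recovers an impulse", {
  x <- matrix(0, 64, 64); x[20, 41] <- 1
  dec <- contourlet_decompose(x, list(4, 8))
  expect_lt(max(abs(contourlet_reconstruct(dec) - x)), 1e-8)
})

test_that("all-zero decomposition reconstructs to the zero image", {
  dec <- contourlet_decompose(matrix(0, 64, 64), list(4, 8))
  expect_equal(max(abs(contourlet_reconstruct(dec))), 0)
})

test_that("constant image has zero directional bands, lowpass keeps energy", {
  x <- matrix(0.7, 64, 64)
  dec <- contourlet_decompose(x, list(4, c(4, 8)))
  expect_lt(max(abs(unlist(dec$levels))), 1e-10)
  expect_equal(sum(dec$lowpass^2), sum(x^2), tolerance = 1e-12)
  cdec <- curvelet_decompose(x, 3, list(8, 16))
  wmax <- max(vapply(unlist(cdec$scales, recursive = FALSE), function(tree) {
    max(vapply(tree, function(w) max(Mod(w)), numeric(1)))
  }, numeric(1)))
  expect_lt(wmax, 1e-10)
  expect_equal(sum(Mod(cdec$coarse)^2), sum(x^2), tolerance = 1e-12)
})

test_that("curvelet is a tight frame (Parseval) with exact round trip", {
  x <- rand_image(128, 4)
  dec <- curvelet_decompose(x)
  defect <- abs(curvelet_energy(dec) / sum(x^2) - 1)
  expect_lt(defect, 1e-6)
  expect_lt(max(abs(curvelet_reconstruct(dec) - x)), 1e-6)
  # impulse and speckle inputs
  imp <- matrix(0, 64, 64); imp[5, 50] <- 1
  d2 <- curvelet_decompose(imp, 3, list(8, 16))
  expect_lt(max(abs(curvelet_reconstruct(d2) - imp)), 1e-6)
})

test_that("zero curvelet coefficients give the zero image", {
  dec <- curvelet_decompose(matrix(0, 64, 64), 3, list(8, 16))
  expect_equal(max(abs(curvelet_reconstruct(dec))), 0)
})

test_that("both decompositions are linear in the input", {
  x <- rand_image(64, 5); y <- rand_image(64, 6)
  mix <- contourlet_decompose(2 * x - 0.5 * y, list(4, 8))
  dx <- contourlet_decompose(x, list(4, 8))
  dy <- contourlet_decompose(y, list(4, 8))
  b <- function(d) d$levels[[2]][[1]][[3]]
  expect_lt(max(abs(b(mix) - 2 * b(dx) + 0.5 * b(dy))), 1e-10)
  cmix <- curvelet_decompose(2 * x - 0.5 * y, 3, list(8, 8))
  cx <- curvelet_decompose(x, 3, list(8, 8))
  cy <- curvelet_decompose(y, 3, list(8, 8))
  w <- function(d) d$scales[["3"]][[1]][[2]]
  expect_lt(max(abs(w(cmix) - 2 * w(cx) + 0.5 * w(cy))), 1e-10)
})

test_that("the six default sub-band keys resolve with descending extents", {
  img <- speckle_fixture(seed = 3, size = 128)
  dec <- contourlet_decompose(img)
  bands <- select_subbands(dec, contourlet_default_keys())
  expect_length(bands, 6)
  expect_equal(vapply(bands, function(b) format(b$key), character(1)),
               c("P2D4#0", "P2D8#0", "P3D8#0", "P3D16#0", "P4D16#0",
                 "P4D32#0"))
  expect_equal(vapply(bands, function(b) b$shape[1], numeric(1)),
               c(64, 64, 32, 32, 16, 16))
  cdec <- curvelet_decompose(img)
  cbands <- select_subbands(cdec, curvelet_default_keys())
  expect_length(cbands, 6)
  expect_true(all(vapply(cbands, function(b) min(b$coeffs) >= 0, logical(1))))
  expect_equal(vapply(cbands, function(b) b$shape[1], numeric(1)),
               c(16, 32, 64, 128, 128, 128))
})

test_that("unresolvable keys raise a key error naming the key", {
  dec <- contourlet_decompose(rand_image(64, 1), list(4, 8))
  expect_error(select_subbands(dec, list("P9D4")), "P9D4",
               class = "cwriig_key_error")
  expect_error(select_subbands(dec, list("P2D32")), "P2D32",
               class = "cwriig_key_error")
  expect_error(select_subbands(dec, list(subband_key("curvelet", 2, 16, 0))),
               class = "cwriig_key_error")
})

test_that("invalid decomposition arguments are rejected", {
  x <- rand_image(64, 1)
  expect_error(contourlet_decompose(x, list(4, 6)), "power")
  expect_error(contourlet_decompose(rand_image(24, 1), list(4, 8, 8, 8)),
               "divisible")
  expect_error(contourlet_decompose(rand_image(16, 1), list(4, 8, 8, 8)),
               "too small")
  expect_error(curvelet_decompose(x, 3, list(8, 10)), "divisible by 4")
  expect_error(curvelet_decompose(x, 1, list()), "at least 2")
})

test_that("subband keys parse and format round trip", {
  k <- parse_subband_key("S5A64#12")
  expect_equal(k$transform, "curvelet")
  expect_equal(k$level, 5)
  expect_equal(k$n_directions, 64)
  expect_equal(k$index, 12)
  expect_equal(format(parse_subband_key("P2D8")), "P2D8#0")
  expect_error(parse_subband_key("X2D8"), "cannot parse")
  expect_error(subband_key("contourlet", 2, 8, 8), "index")
})

test_that("decompositions persist to the binary container and sidecar", {
  dec <- contourlet_decompose(rand_image(64, 8), list(4, 8))
  path <- tempfile(fileext = ".bin")
  save_decomposition(dec, path)
  expect_true(file.exists(path))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$class, "contourlet_decomposition")
  expect_true("P2D8#0" %in% names(meta$arrays))
  nums <- file.info(path)$size / 8
  expect_equal(nums, sum(vapply(meta$arrays, function(a) {
    prod(unlist(a$shape)) * (1 + isTRUE(a$complex))
  }, numeric(1))))
})
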