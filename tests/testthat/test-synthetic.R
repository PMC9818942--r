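# Synthetic speckle generator and model-law fields.

test_that("background envelope is Rayleigh (fully developed speckle)", {
  img <- speckle_fixture(seed = 2)
  env <- attr(img, "envelope")
  mask <- attr(img, "lesion_mask")
  bg <- env[!mask][1:10000]
  sigma <- sqrt(mean(bg^2) / 2)
  ks <- suppressWarnings(
    stats::ks.test(bg, function(q) 1 - exp(-q^2 / (2 * sigma^2))))
  expect_gt(ks$p.value, 0.01)
})

test_that("a contrast-1 smooth lesion is indistinguishable from background", {
  cfg <- speckle_config(lesion_contrast = 1, boundary_irregularity = 0,
                        seed = 3)
  img <- simulate_speckle(cfg)
  env <- attr(img, "envelope"); mask <- attr(img, "lesion_mask")
  ks <- suppressWarnings(stats::ks.test(env[mask], env[!mask]))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulation is reproducible and properly normalized", {
  a <- simulate_speckle(benign_config(seed = 7))
  b <- simulate_speckle(benign_config(seed = 7))
  expect_identical(as.numeric(a), as.numeric(b))
  expect_equal(range(a), c(0, 1))
  expect_false(identical(as.numeric(a),
                         as.numeric(simulate_speckle(benign_config(seed = 8)))))
})

test_that("configs are validated", {
  expect_error(speckle_config(size = 32), "at least 64")
  expect_error(speckle_config(lesion_contrast = 0), "contrast")
  expect_error(speckle_config(boundary_irregularity = -1), "irregularity")
  expect_error(speckle_config(scatterer_density = 0), "density")
})

test_that("datasets are balanced with unique sources and images", {
  ds <- make_dataset(5, seed = 2)
  expect_length(ds, 10)
  labels <- vapply(ds, function(s) s$label, character(1))
  expect_equal(sum(labels == "benign"), 5)
  expect_equal(sum(labels == "malignant"), 5)
  ids <- vapply(ds, function(s) s$source_id, character(1))
  expect_equal(anyDuplicated(ids), 0)
  sums <- vapply(ds, function(s) sum(s$image), numeric(1))
  expect_equal(anyDuplicated(sums), 0)
  expect_error(make_dataset(0), "at least 1")
})

test_that("model-law fields are seeded and feed the moment fitters", {
  f1 <- simulate_model_field("rayleigh", list(sigma = 1), 64, seed = 5)
  f2 <- simulate_model_field("rayleigh", list(sigma = 1), 64, seed = 5)
  expect_identical(f1$coeffs, f2$coeffs)
  fit <- nakagami_fit(as.vector(f1$coeffs))
  expect_equal(fit$params$m, 1, tolerance = 0.06)
  expect_error(simulate_model_field("rayleigh", list(sigma = -1), 16),
               "sigma")
})

test_that("datasets round-trip through PNG files and the manifest", {
  ds <- make_dataset(2, seed = 4)
  dir <- tempfile("ds")
  manifest <- write_dataset(ds, dir)
  tab <- utils::read.csv(manifest)
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$label, c("benign", "malignant"))
  img <- read_gray_image(file.path(dir, tab$file[1]))
  expect_equal(dim(img), dim(ds[[1]]$image))
  expect_lt(max(abs(img - ds[[1]]$image)), 1 / 255)
  unlink(dir, recursive = TRUE)
})
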