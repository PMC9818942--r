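# Seeded synthetic-data generators: fully developed speckle with an
# elliptical lesion, two-class datasets, and i.i.d. model-law fields.

#' Speckle simulation configuration
#'
#' Parameters of the synthetic B-mode generator. The scatterer field is
#' complex circular Gaussian (fully developed speckle), modulated by an
#' elliptical lesion whose boundary radius is perturbed sinusoidally, then
#' convolved with a Gaussian point-spread function and envelope-detected.
#'
#' @param size image side in pixels (at least 64).
#' @param scatterer_density mean scatterers per pixel squared; scales the
#'   local scatterer variance.
#' @param psf_sigma Gaussian PSF standard deviation in pixels.
#' @param lesion_axes semi-axes of the lesion ellipse as fractions of
#'   `size`.
#' @param lesion_contrast interior echogenicity relative to background
#'   (amplitude ratio; 1 = no lesion contrast, smaller = hypoechoic).
#' @param boundary_irregularity amplitude of the sinusoidal boundary
#'   perturbation relative to the local radius (0 = smooth ellipse).
#' @param n_lobes number of boundary perturbation lobes.
#' @param class_label `"benign"` or `"malignant"`.
#' @param log_compression dynamic-range compression strength `a` in
#'   `log(1 + a * envelope) / log(1 + a)`.
#' @param seed integer seed making the image reproducible.
#' @return A `speckle_config` list.
#' @export
speckle_config <- function(size = 128, scatterer_density = 1,
                           psf_sigma = 1.5, lesion_axes = c(0.30, 0.26),
                           lesion_contrast = 0.55,
                           boundary_irregularity = 0.05, n_lobes = 5,
                           class_label = c("benign", "malignant"),
                           log_compression = 30, seed = 1) {
  class_label <- match.arg(class_label)
  cfg <- list(size = as.integer(size), scatterer_density = scatterer_density,
              psf_sigma = psf_sigma, lesion_axes = lesion_axes,
              lesion_contrast = lesion_contrast,
              boundary_irregularity = boundary_irregularity,
              n_lobes = as.integer(n_lobes), class_label = class_label,
              log_compression = log_compression, seed = as.integer(seed))
  .check_speckle_config(cfg)
  structure(cfg, class = "speckle_config")
}

.check_speckle_config <- function(cfg) {
  if (cfg$size < 64) stop("size must be at least 64", call. = FALSE)
  if (cfg$scatterer_density <= 0) stop("scatterer_density must be positive",
                                       call. = FALSE)
  if (cfg$lesion_contrast <= 0) stop("lesion_contrast must be positive",
                                     call. = FALSE)
  if (cfg$boundary_irregularity < 0) {
    stop("boundary_irregularity must be nonnegative", call. = FALSE)
  }
  invisible(cfg)
}

#' Default class configurations
#'
#' Benign lesions: near-circular, smooth margin, mildly hypoechoic.
#' Malignant lesions: eccentric, irregular (spiculated-like) margin,
#' markedly hypoechoic. These emulate the qualitative sonographic
#' contrast between the two classes.
#'
#' @param seed integer seed.
#' @rdname speckle_config
#' @export
benign_config <- function(seed = 1) {
  speckle_config(class_label = "benign", lesion_axes = c(0.30, 0.26),
                 lesion_contrast = 0.55, boundary_irregularity = 0.05,
                 seed = seed)
}

#' @rdname speckle_config
#' @export
malignant_config <- function(seed = 1) {
  speckle_config(class_label = "malignant", lesion_axes = c(0.36, 0.20),
                 lesion_contrast = 0.30, boundary_irregularity = 0.35,
                 seed = seed)
}

#' Simulate a speckle image
#'
#' Draws a complex circular-Gaussian scatterer field, scales its local
#' standard deviation by `lesion_contrast` inside the (perturbed) lesion
#' ellipse, convolves with a Gaussian PSF (periodic, via FFT), takes the
#' envelope (modulus), applies logarithmic dynamic-range compression, and
#' min-max normalizes to `[0, 1]`. Because the pre-envelope field is
#' complex Gaussian at every pixel, background envelope amplitudes are
#' exactly Rayleigh-distributed (fully developed speckle).
#'
#' @param config a `speckle_config`.
#' @return `size` x `size` matrix in `[0, 1]` with attributes `envelope`
#'   (pre-compression envelope), `lesion_mask` (logical matrix), `label`
#'   and `config`.
#' @export
simulate_speckle <- function(config) {
  if (!inherits(config, "speckle_config")) {
    config <- do.call(speckle_config, config)
  }
  .check_speckle_config(config)
  n <- config$size
  set.seed(config$seed)
  mask <- .lesion_mask(config)
  sd_field <- sqrt(config$scatterer_density) *
    ifelse(mask, config$lesion_contrast, 1)
  field <- matrix(complex(real = stats::rnorm(n * n),
                          imaginary = stats::rnorm(n * n)), n, n) * sd_field
  # Gaussian PSF, periodic convolution in the frequency domain.
  g <- .freq_grid(n, n)
  H <- exp(-2 * pi^2 * config$psf_sigma^2 * ((g$k1 / n)^2 + (g$k2 / n)^2))
  env <- Mod(stats::fft(stats::fft(field) * H, inverse = TRUE) / (n * n))
  a <- config$log_compression
  img <- log1p(a * env) / log1p(a)
  rng <- range(img)
  img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  attr(img, "envelope") <- env
  attr(img, "lesion_mask") <- mask
  attr(img, "label") <- config$class_label
  attr(img, "config") <- config
  img
}

# Elliptical lesion mask with sinusoidal boundary perturbation; lobe phase
# and orientation come from the config RNG stream.
.lesion_mask <- function(config) {
  n <- config$size
  phase <- stats::runif(1, 0, 2 * pi)
  rot <- stats::runif(1, 0, pi)
  cx <- n / 2 + stats::runif(1, -0.05, 0.05) * n
  cy <- n / 2 + stats::runif(1, -0.05, 0.05) * n
  xs <- matrix(seq_len(n) - cx, n, n)
  ys <- matrix(seq_len(n) - cy, n, n, byrow = TRUE)
  xr <- cos(rot) * xs + sin(rot) * ys
  yr <- -sin(rot) * xs + cos(rot) * ys
  ax <- config$lesion_axes[1] * n
  ay <- config$lesion_axes[2] * n
  rho <- sqrt((xr / ax)^2 + (yr / ay)^2)
  theta <- atan2(yr / ay, xr / ax)
  bound <- 1 + config$boundary_irregularity *
    sin(config$n_lobes * theta + phase)
  rho <= bound
}

#' Generate a balanced two-class dataset
#'
#' Simulates `n_per_class` benign and `n_per_class` malignant speckle
#' images with per-image seeds derived from `seed`, unique `source_id`s
#' and the class configurations as templates (each image re-seeds its
#' template).
#'
#' @param n_per_class images per class (at least 1).
#' @param benign_cfg,malignant_cfg class templates
#'   (see [benign_config()]).
#' @param seed integer master seed.
#' @return List of samples; each a list with `image` (matrix), `label`,
#'   `source_id` and `config`.
#' @export
make_dataset <- function(n_per_class, benign_cfg = benign_config(),
                         malignant_cfg = malignant_config(), seed = 1) {
  if (n_per_class < 1) stop("n_per_class must be at least 1", call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 2 * n_per_class)
  out <- vector("list", 2 * n_per_class)
  for (i in seq_len(2 * n_per_class)) {
    benign <- i <= n_per_class
    cfg <- if (benign) benign_cfg else malignant_cfg
    cfg$seed <- seeds[i]
    img <- simulate_speckle(cfg)
    out[[i]] <- list(image = img, label = cfg$class_label,
                     source_id = sprintf("%s_%04d", cfg$class_label,
                                         if (benign) i else i - n_per_class),
                     config = cfg)
  }
  out
}

#' Simulate an i.i.d. model-law field
#'
#' Pixel field with independent draws from a named envelope law; a test
#' fixture for the sliding-window parametric maps.
#'
#' @param law `"riig"`, `"nakagami"` or `"rayleigh"`.
#' @param params named list of the law's parameters (`alpha`, `beta`,
#'   `delta` for RiIG; `m`, `omega` for Nakagami; `sigma` for Rayleigh).
#' @param size field side in pixels.
#' @param seed integer seed.
#' @return A `subband_image` whose `coeffs` hold the field.
#' @export
simulate_model_field <- function(law = c("riig", "nakagami", "rayleigh"),
                                 params, size, seed = 1) {
  law <- match.arg(law)
  set.seed(seed)
  n <- size * size
  x <- switch(law,
    riig = rriig(n, params$alpha, params$beta, params$delta),
    nakagami = rnaka(n, params$m, params$omega),
    rayleigh = {
      if (is.null(params$sigma) || params$sigma <= 0) {
        stop("rayleigh needs sigma > 0", call. = FALSE)
      }
      params$sigma * sqrt(-2 * log(stats::runif(n)))
    })
  structure(list(key = NULL, coeffs = matrix(x, size, size),
                 shape = c(size, size)),
            class = "subband_image")
}

#' Write a dataset to disk
#'
#' Writes each image as an 8-bit grayscale PNG plus a CSV manifest with
#' `source_id`, `label`, `seed` and a config hash.
#'
#' @param dataset result of [make_dataset()].
#' @param dir output directory (created if missing).
#' @return Path to the manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset, function(s) {
    file <- file.path(dir, paste0(s$source_id, ".png"))
    write_gray_image(s$image, file)
    cfg <- s$config
    hash <- sum(utf8ToInt(paste(unlist(cfg), collapse = ","))) %% 1e9
    data.frame(source_id = s$source_id, label = s$label, file = basename(file),
               seed = cfg$seed, config_hash = hash)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
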