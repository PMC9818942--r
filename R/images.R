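#' Coerce to a grayscale image matrix
#'
#' Accepts a numeric matrix (kept as is) or an H x W x 3/4 array (converted
#' to luminance, 0.299 R + 0.587 G + 0.114 B). With `normalize = TRUE` the
#' result is min-max rescaled to `[0, 1]` (a constant image maps to 0).
#'
#' @param x matrix or array.
#' @param normalize rescale to `[0, 1]`?
#' @return Numeric matrix.
#' @export
as_gray_image <- function(x, normalize = TRUE) {
  if (is.array(x) && length(dim(x)) == 3) {
    if (dim(x)[3] >= 3) {
      x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    } else {
      x <- x[, , 1]
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric matrix or an RGB(A) array", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("image contains non-finite values", call. = FALSE)
  if (normalize) {
    rng <- range(x)
    x <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  }
  x
}

#' Read a grayscale image from PNG or BMP
#'
#' PNG files are read with the \pkg{png} package; uncompressed 8-bit
#' palette/gray and 24-bit BMP files are parsed directly. RGB content is
#' converted to luminance.
#'
#' @param path file path ending in `.png` or `.bmp`.
#' @param normalize min-max rescale to `[0, 1]`?
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path, normalize = TRUE) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    bmp = .read_bmp(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  as_gray_image(x, normalize = normalize)
}

#' Write a grayscale image as PNG
#'
#' Values are clamped to `[0, 1]` and written as 8-bit grayscale.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}

# Minimal reader for uncompressed BMP (BITMAPINFOHEADER, 8-bit indexed or
# 24-bit BGR). Rows are stored bottom-up and padded to 4 bytes.
.read_bmp <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM") {
    stop("not a BMP file: ", path, call. = FALSE)
  }
  le <- function(idx) sum(as.integer(raw[idx]) * 256^(seq_along(idx) - 1))
  offset <- le(11:14)
  width <- le(19:22); height <- le(23:26)
  bpp <- le(29:30); compression <- le(31:34)
  if (compression != 0) stop("compressed BMP not supported", call. = FALSE)
  out <- matrix(0, height, width)
  if (bpp == 8) {
    hdr_size <- le(15:18)
    n_colors <- le(47:50); if (n_colors == 0) n_colors <- 256
    pal <- raw[(14 + hdr_size + 1):(14 + hdr_size + 4 * n_colors)]
    pal <- matrix(as.integer(pal), nrow = 4)  # B,G,R,0 per entry
    lum <- (0.114 * pal[1, ] + 0.587 * pal[2, ] + 0.299 * pal[3, ]) / 255
    stride <- ((width + 3) %/% 4) * 4
    for (r in seq_len(height)) {
      row <- as.integer(raw[offset + (r - 1) * stride + seq_len(width)])
      out[height - r + 1, ] <- lum[row + 1]
    }
  } else if (bpp == 24) {
    stride <- ((3 * width + 3) %/% 4) * 4
    for (r in seq_len(height)) {
      row <- as.integer(raw[offset + (r - 1) * stride + seq_len(3 * width)])
      b <- row[seq(1, 3 * width, 3)]; g <- row[seq(2, 3 * width, 3)]
      rr <- row[seq(3, 3 * width, 3)]
      out[height - r + 1, ] <- (0.299 * rr + 0.587 * g + 0.114 * b) / 255
    }
  } else {
    stop("unsupported BMP bit depth: ", bpp, call. = FALSE)
  }
  out
}

#' Bilinear resize
#'
#' Resizes a numeric matrix with bilinear interpolation (via
#' \pkg{EBImage}). Interpolated values are convex combinations of inputs,
#' so any value bounds on the input are preserved.
#'
#' @param image numeric matrix.
#' @param height,width target extents.
#' @return `height` x `width` numeric matrix.
#' @export
resize_bilinear <- function(image, height, width = height) {
  out <- EBImage::resize(image, w = height, h = width)
  matrix(as.numeric(out), height, width)
}
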