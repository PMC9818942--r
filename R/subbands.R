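#' Sub-band keys
#'
#' A sub-band key addresses one directional band of a decomposition:
#' `transform` (`"contourlet"` or `"curvelet"`), `level` (pyramidal level
#' `P` or curvelet scale `S`), `n_directions` (directional count `D` or
#' angle count `A`, selecting the tree at that level), and a 0-based
#' `index` within the tree. Keys print in the compact `P2D8#0` / `S5A64#0`
#' form; [parse_subband_key()] accepts that form (the `#index` suffix
#' optional, defaulting to 0).
#'
#' @param transform `"contourlet"` or `"curvelet"`.
#' @param level pyramidal level / scale (integer).
#' @param n_directions directional / angular count of the tree.
#' @param index 0-based band index within the tree.
#' @return Object of class `subband_key`.
#' @export
subband_key <- function(transform = c("contourlet", "curvelet"),
                        level, n_directions, index = 0L) {
  transform <- match.arg(transform)
  level <- as.integer(level); n_directions <- as.integer(n_directions)
  index <- as.integer(index)
  if (index < 0 || index >= n_directions) {
    stop("index must satisfy 0 <= index < n_directions", call. = FALSE)
  }
  structure(list(transform = transform, level = level,
                 n_directions = n_directions, index = index),
            class = "subband_key")
}

#' @rdname subband_key
#' @param x a string such as `"P3D16"`, `"S5A64#12"`.
#' @export
parse_subband_key <- function(x) {
  m <- regmatches(x, regexec("^([PS])(\\d+)([DA])(\\d+)(#(\\d+))?$", x))[[1]]
  if (length(m) == 0) stop("cannot parse sub-band key: ", x, call. = FALSE)
  transform <- if (m[2] == "P") "contourlet" else "curvelet"
  idx <- if (m[7] == "") 0L else as.integer(m[7])
  subband_key(transform, as.integer(m[3]), as.integer(m[5]), idx)
}

#' @export
format.subband_key <- function(x, ...) {
  sprintf("%s%d%s%d#%d", if (x$transform == "contourlet") "P" else "S",
          x$level, if (x$transform == "contourlet") "D" else "A",
          x$n_directions, x$index)
}

#' @export
print.subband_key <- function(x, ...) {
  cat("<subband_key ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Default six-band selections
#'
#' The six sub-bands used to build classification stacks: contourlet
#' `P2D4, P2D8, P3D8, P3D16, P4D16, P4D32` and curvelet
#' `S2A16, S3A32, S4A32, S5A16, S5A32, S5A64`. Within a level or scale all
#' bands of a tree share one spatial extent (no within-level directional
#' subsampling), so the largest-band rule degenerates to a tie broken by
#' taking index 0.
#'
#' @return List of six `subband_key` objects.
#' @export
contourlet_default_keys <- function() {
  lapply(c("P2D4", "P2D8", "P3D8", "P3D16", "P4D16", "P4D32"),
         parse_subband_key)
}

#' @rdname contourlet_default_keys
#' @export
curvelet_default_keys <- function() {
  lapply(c("S2A16", "S3A32", "S4A32", "S5A16", "S5A32", "S5A64"),
         parse_subband_key)
}

#' Select sub-bands from a decomposition
#'
#' Resolves each key against a contourlet or curvelet decomposition and
#' returns the addressed bands in key order. Curvelet bands are returned
#' as coefficient magnitudes (nonnegative), contourlet bands as signed
#' real coefficients.
#'
#' @param dec a `contourlet_decomposition` or `curvelet_decomposition`.
#' @param keys list of `subband_key` objects or key strings.
#' @return List of `subband_image` objects: each a list with `key`,
#'   `coeffs` (numeric matrix) and `shape`.
#' @export
select_subbands <- function(dec, keys) {
  keys <- lapply(keys, function(k) {
    if (is.character(k)) parse_subband_key(k) else k
  })
  lapply(keys, function(key) {
    coeffs <- .resolve_subband(dec, key)
    structure(list(key = key, coeffs = coeffs, shape = dim(coeffs)),
              class = "subband_image")
  })
}

.key_error <- function(key, why) {
  stop(structure(class = c("cwriig_key_error", "error", "condition"),
                 list(message = paste0("sub-band key ", format(key),
                                       " not resolvable: ", why),
                      call = NULL)))
}

.resolve_subband <- function(dec, key) {
  if (inherits(dec, "contourlet_decomposition")) {
    if (key$transform != "contourlet") .key_error(key, "decomposition is contourlet")
    if (key$level < 1 || key$level > dec$n_levels) .key_error(key, "no such pyramidal level")
    trees <- dec$levels[[key$level]]
    tree <- trees[[as.character(key$n_directions)]]
    if (is.null(tree)) .key_error(key, "no such directional tree at this level")
    if (key$index >= length(tree)) .key_error(key, "index out of range")
    tree[[key$index + 1L]]
  } else if (inherits(dec, "curvelet_decomposition")) {
    if (key$transform != "curvelet") .key_error(key, "decomposition is curvelet")
    trees <- dec$scales[[as.character(key$level)]]
    if (is.null(trees)) .key_error(key, "no such scale")
    tree <- trees[[as.character(key$n_directions)]]
    if (is.null(tree)) .key_error(key, "no such angular tree at this scale")
    if (key$index >= length(tree)) .key_error(key, "index out of range")
    Mod(tree[[key$index + 1L]])
  } else {
    stop("dec must be a contourlet or curvelet decomposition", call. = FALSE)
  }
}

#' Persist a decomposition to disk
#'
#' Writes all coefficient arrays as little-endian doubles in one `.bin`
#' file with a JSON sidecar (`<path>.json`) listing array names, shapes
#' and whether each array is complex (stored as interleaved re/im).
#'
#' @param dec a decomposition object.
#' @param path output path for the binary container (sidecar adds
#'   `.json`).
#' @return `path`, invisibly.
#' @export
save_decomposition <- function(dec, path) {
  arrays <- .flatten_decomposition(dec)
  con <- file(path, "wb")
  on.exit(close(con))
  meta <- list(class = class(dec)[1], dim = dec$dim,
               arrays = list())
  for (name in names(arrays)) {
    a <- arrays[[name]]
    cplx <- is.complex(a)
    v <- if (cplx) as.numeric(rbind(Re(a), Im(a))) else as.numeric(a)
    writeBin(v, con, size = 8, endian = "little")
    meta$arrays[[name]] <- list(shape = dim(a), complex = cplx)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

.flatten_decomposition <- function(dec) {
  out <- list()
  if (inherits(dec, "contourlet_decomposition")) {
    out[["lowpass"]] <- dec$lowpass
    for (l in seq_len(dec$n_levels)) {
      for (D in names(dec$levels[[l]])) {
        tree <- dec$levels[[l]][[D]]
        for (i in seq_along(tree)) {
          out[[sprintf("P%dD%s#%d", l, D, i - 1L)]] <- tree[[i]]
        }
      }
    }
  } else {
    out[["coarse"]] <- dec$coarse
    for (s in names(dec$scales)) {
      for (A in names(dec$scales[[s]])) {
        tree <- dec$scales[[s]][[A]]
        for (i in seq_along(tree)) {
          out[[sprintf("S%sA%s#%d", s, A, i - 1L)]] <- tree[[i]]
        }
      }
    }
  }
  out
}
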