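#' Spectral cube container
#'
#' A spectral cube holds a per-pixel reflectance spectrum for every pixel of
#' an image: an H x W x 401 array on the common [wavelength_grid()], plus a
#' modality tag (`"wli"` white-light or `"nbi"` narrow-band) and, when the
#' cube came from a reconstruction, the hash of the conversion matrix that
#' produced it. [write_spectral_cube()]/[read_spectral_cube()] store a cube
#' losslessly in a single versioned file.
#'
#' @param values H x W x 401 numeric array (nonnegative reflectance) or an
#'   n_pixels x 401 matrix together with `dim = c(H, W)`.
#' @param wavelengths the wavelength grid; must equal [wavelength_grid()].
#' @param modality `"wli"` or `"nbi"`.
#' @param calibration_hash optional md5 of the conversion matrix.
#' @param dims `c(H, W)` when `values` is a pixel matrix.
#' @return an object of class `"spectral_cube"`.
#' @export
spectral_cube <- function(values, wavelengths = wavelength_grid(),
                          modality = c("wli", "nbi"),
                          calibration_hash = NULL, dims = NULL) {
  modality <- match.arg(modality)
  if (is.matrix(values)) {
    assert_that(!is.null(dims), "pixel-matrix input needs dims = c(H, W)")
    assert_that(nrow(values) == prod(dims), "dims do not match pixel count")
    values <- array(values, dim = c(dims[1], dims[2], ncol(values)))
  }
  d <- dim(values)
  assert_that(length(d) == 3 && d[3] == N_BANDS,
              sprintf("cube must be H x W x %d", N_BANDS))
  assert_that(identical(as.numeric(wavelengths),
                        as.numeric(wavelength_grid())),
              "wavelengths must be the 380-780 nm, 1 nm grid")
  assert_that(all(values >= 0), "cube reflectances must be >= 0")
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 modality = modality, calibration_hash = calibration_hash),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("spectral cube: %d x %d pixels, %d bands (%g-%g nm), modality %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$modality))
  if (!is.null(x$calibration_hash)) {
    cat("  conversion matrix:", x$calibration_hash, "\n")
  }
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

#' @rdname spectral_cube
#' @param x a spectral cube.
#' @param ... unused.
#' @return `as.matrix()`: an n_pixels x 401 matrix (pixels in column-major
#'   image order).
#' @export
as.matrix.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  matrix(x$values, nrow = d[1] * d[2], ncol = d[3])
}

#' @rdname spectral_cube
#' @param cube a spectral cube.
#' @param path file path.
#' @export
write_spectral_cube <- function(cube, path) {
  assert_that(inherits(cube, "spectral_cube"), "not a spectral_cube")
  payload <- list(container = "endospectra_cube", version = 1L,
                  wavelengths = cube$wavelengths, modality = cube$modality,
                  calibration_hash = cube$calibration_hash,
                  values = cube$values)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname spectral_cube
#' @export
read_spectral_cube <- function(path) {
  p <- readRDS(path)
  assert_that(identical(p$container, "endospectra_cube"),
              "file is not a spectral cube container")
  spectral_cube(p$values, p$wavelengths, p$modality, p$calibration_hash)
}
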