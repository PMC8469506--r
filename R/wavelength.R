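#' The 401-point visible-light wavelength grid
#'
#' All reflectance spectra in the package live on a fixed grid: 380 to
#' 780 nm sampled every 1 nm (401 bands). Reconstruction, PCA and the
#' synthetic generators all share this grid.
#'
#' @return numeric vector of length 401, wavelengths in nm.
#' @export
wavelength_grid <- function() {
  seq(380, 780, by = 1)
}

## number of spectral bands
N_BANDS <- 401L

## Validate a reflectance spectrum (or matrix of spectra, rows = spectra).
## Reflectance is unitless, nonnegative; values up to 1.5 are tolerated as
## headroom for specular highlights.
assert_spectra <- function(x, what = "spectrum") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  assert_that(ncol(x) == N_BANDS,
              sprintf("%s must have %d bands (380-780 nm at 1 nm), got %d",
                      what, N_BANDS, ncol(x)))
  assert_that(all(is.finite(x)), sprintf("%s contains non-finite values", what))
  assert_that(all(x >= 0), sprintf("%s contains negative reflectance", what))
  assert_that(all(x <= 1.5),
              sprintf("%s exceeds the 1.5 reflectance headroom", what))
  invisible(x)
}

#' Root-mean-square difference between two reflectance spectra
#'
#' @param a,b numeric vectors of length 401 on the common wavelength grid.
#' @return nonnegative scalar, in reflectance units.
#' @examples
#' spectrum_rmse(rep(0.2, 401), rep(0.5, 401)) # 0.3
#' @export
spectrum_rmse <- function(a, b) {
  if (length(a) != length(b)) {
    stop("wavelength grid mismatch: spectra have lengths ",
         length(a), " and ", length(b))
  }
  sqrt(mean((a - b)^2))
}
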