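#' Fit the RGB-to-spectrum conversion from a 24-patch color target
#'
#' Builds the conversion matrix that turns an endoscopic RGB pixel into a
#' 401-band visible-light reflectance spectrum (380-780 nm, 1 nm steps).
#' The camera and a spectrometer both observe a standard 24-patch color
#' target; a polynomial regression from the linearized camera RGB of each
#' patch to its measured reflectance spectrum yields an F x 401 coefficient
#' matrix (F = `feature_count(degree)`, 20 at the default degree 3) that is
#' then applied per pixel by [predict.spectral_calibration()].
#'
#' With only 24 training patches a small ridge penalty (default `1e-6`)
#' stabilizes the 20-feature fit. With `ridge = 0` the minimum-norm
#' least-squares solution is used and rank deficiency of the design is
#' flagged in the returned object rather than being an error.
#'
#' @param patch_rgb 24 x 3 matrix of the camera's RGB for each patch, in
#'   \[0, 1\], gamma-encoded unless `linearized = TRUE`.
#' @param reference the target's reference spectra: a [color_target] object
#'   or a 24 x 401 matrix (rows = patches, on [wavelength_grid()]).
#' @param degree polynomial degree of the feature expansion (default 3).
#' @param ridge ridge penalty lambda >= 0 (default `1e-6`).
#' @param transfer camera transfer curve used to linearize `patch_rgb` and,
#'   later, images (see [linearize_rgb()]).
#' @param linearized set `TRUE` if `patch_rgb` is already linear-light.
#' @return an object of class `"spectral_calibration"` with elements
#'   `coefficients` (F x 401), `degree`, `ridge`, `transfer`,
#'   `rmse_per_patch` (24 training RMSEs, reflectance units),
#'   `rank_deficient` flag, and `wavelengths`.
#' @seealso [predict.spectral_calibration()], [make_color_target()],
#'   [capture_color_target()]
#' @export
spectral_calibration <- function(patch_rgb, reference, degree = 3,
                                 ridge = 1e-6,
                                 transfer = c("srgb", "gamma", "identity"),
                                 linearized = FALSE) {
  transfer <- match.arg(transfer)
  # already-linear training data: predictions must skip linearization too
  if (linearized) transfer <- "identity"
  if (inherits(reference, "color_target")) reference <- reference$spectra
  patch_rgb <- as.matrix(patch_rgb)
  reference <- as.matrix(reference)
  assert_that(nrow(patch_rgb) == 24 && ncol(patch_rgb) == 3,
              "patch_rgb must be a 24 x 3 matrix (one RGB per patch)")
  assert_that(nrow(reference) == 24,
              "reference must hold exactly 24 patch spectra")
  assert_spectra(reference, "reference spectra")
  if (ridge < 0) stop("ridge penalty must be >= 0")

  lin <- if (linearized) {
    check_channel_range(patch_rgb)
    patch_rgb
  } else {
    linearize_rgb(patch_rgb, transfer)
  }
  X <- expand_features(lin, degree)
  fit <- solve_ls(X, reference, ridge)

  fitted <- X %*% fit$coefficients
  res <- fitted - reference
  structure(list(
    coefficients = fit$coefficients,
    degree = degree,
    ridge = ridge,
    transfer = transfer,
    rmse_per_patch = sqrt(rowMeans(res^2)),
    rank_deficient = fit$rank_deficient,
    rank = fit$rank,
    wavelengths = wavelength_grid(),
    training = list(rgb = patch_rgb, linear_rgb = lin, reference = reference)
  ), class = "spectral_calibration")
}

## Ridge / minimum-norm least squares for multi-response Y.
solve_ls <- function(X, Y, ridge) {
  f <- ncol(X)
  if (ridge > 0) {
    B <- solve(crossprod(X) + diag(ridge, f), crossprod(X, Y))
    sv <- svd(X, nu = 0, nv = 0)$d
    rank <- sum(sv > max(dim(X)) * .Machine$double.eps * sv[1])
    return(list(coefficients = unname(B), rank = rank,
                rank_deficient = rank < f))
  }
  s <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * s$d[1]
  pos <- s$d > tol
  dinv <- ifelse(pos, 1 / s$d, 0)
  B <- s$v %*% (dinv * (t(s$u) %*% Y))
  list(coefficients = unname(B), rank = sum(pos),
       rank_deficient = sum(pos) < f)
}

#' Apply a fitted conversion to RGB pixels or a whole image
#'
#' Each pixel is linearized with the calibration's transfer curve, expanded
#' to polynomial features and multiplied by the conversion matrix; negative
#' reconstructed reflectances are clipped to 0 (their fraction is attached
#' as the `"clip_rate"` attribute).
#'
#' @param object a [spectral_calibration] fit.
#' @param newdata an n x 3 RGB matrix, a length-3 triplet, or an
#'   H x W x 3 image array, all in \[0, 1\].
#' @param clip clip negative reflectances to zero (default TRUE).
#' @param modality modality tag stored when a cube is returned.
#' @param ... unused.
#' @return for matrix input, an n x 401 spectra matrix; for an image array,
#'   a [spectral_cube] of the same height and width.
#' @export
predict.spectral_calibration <- function(object, newdata, clip = TRUE,
                                         modality = "wli", ...) {
  if (is.array(newdata) && length(dim(newdata)) == 3) {
    d <- dim(newdata)
    assert_that(d[3] == 3, "image array must be H x W x 3")
    px <- matrix(newdata, nrow = d[1] * d[2], ncol = 3)
    sp <- predict(object, px, clip = clip)
    cube <- spectral_cube(array(sp, dim = c(d[1], d[2], N_BANDS)),
                          modality = modality,
                          calibration_hash = calibration_hash(object))
    attr(cube, "clip_rate") <- attr(sp, "clip_rate")
    return(cube)
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 3, byrow = TRUE)
  X <- expand_features(linearize_rgb(newdata, object$transfer), object$degree)
  if (ncol(X) != nrow(object$coefficients)) {
    stop("feature expansion mismatch between calibration and input")
  }
  sp <- X %*% object$coefficients
  rate <- mean(sp < 0)
  if (clip) sp[sp < 0] <- 0
  attr(sp, "clip_rate") <- rate
  sp
}

calibration_hash <- function(object) {
  object_hash(object$coefficients)
}

#' @export
coef.spectral_calibration <- function(object, ...) object$coefficients

#' @export
fitted.spectral_calibration <- function(object, ...) {
  expand_features(object$training$linear_rgb, object$degree) %*%
    object$coefficients
}

#' @export
residuals.spectral_calibration <- function(object, ...) {
  fitted(object) - object$training$reference
}

#' @export
print.spectral_calibration <- function(x, ...) {
  cat("RGB -> spectrum conversion fit (24-patch color target)\n")
  cat(sprintf("  features: degree-%d polynomial (%d monomials), transfer = %s\n",
              x$degree, nrow(x$coefficients), x$transfer))
  cat(sprintf("  ridge lambda: %g%s\n", x$ridge,
              if (x$rank_deficient) "  [rank-deficient design]" else ""))
  cat(sprintf("  bands: %d (380-780 nm)\n", ncol(x$coefficients)))
  cat(sprintf("  training RMSE: mean %.4g, max %.4g (reflectance)\n",
              mean(x$rmse_per_patch), max(x$rmse_per_patch)))
  invisible(x)
}

#' @export
summary.spectral_calibration <- function(object, ...) {
  print(object)
  cat("\nPer-patch training RMSE:\n")
  print(round(object$rmse_per_patch, 5))
  invisible(object)
}
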