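#' Camera transfer (gamma) curves
#'
#' 8-bit endoscopic images are gamma-encoded; the spectral regression is fit
#' in linear-light space, so encoded channels are linearized first.
#' `linearize_rgb()` inverts the camera transfer; `encode_rgb()` applies it
#' (used by the synthetic camera when rendering).
#'
#' Supported transfers:
#' \describe{
#'   \item{`"srgb"`}{the standard piecewise sRGB curve (linear toe below
#'     0.04045 encoded / 0.0031308 linear, exponent 2.4 above).}
#'   \item{`"gamma"`}{a pure power law with exponent `gamma`.}
#'   \item{`"identity"`}{no-op, for already-linear data.}
#' }
#'
#' @param x numeric vector, matrix (columns r,g,b) or array of channel values
#'   in \[0, 1\].
#' @param transfer one of `"srgb"`, `"gamma"`, `"identity"`.
#' @param gamma exponent for the `"gamma"` transfer (default 2.2).
#' @return object of the same shape with channels mapped; monotone in each
#'   channel; 0 and 1 are fixed points of every supported transfer.
#' @examples
#' linearize_rgb(c(0.5, 0.5, 0.5)) # ~0.214 each
#' @export
linearize_rgb <- function(x, transfer = c("srgb", "gamma", "identity"),
                          gamma = 2.2) {
  transfer <- match.arg(transfer)
  check_channel_range(x)
  out <- switch(transfer,
    srgb = ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4),
    gamma = x^gamma,
    identity = x
  )
  attributes(out) <- attributes(x)
  out
}

#' @rdname linearize_rgb
#' @export
encode_rgb <- function(x, transfer = c("srgb", "gamma", "identity"),
                       gamma = 2.2) {
  transfer <- match.arg(transfer)
  check_channel_range(x)
  out <- switch(transfer,
    srgb = ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055),
    gamma = x^(1 / gamma),
    identity = x
  )
  attributes(out) <- attributes(x)
  out
}

check_channel_range <- function(x) {
  bad <- which(!is.finite(x) | x < 0 | x > 1)
  if (length(bad)) {
    ch <- channel_name(x, bad[1])
    stop(sprintf("channel value out of [0,1]: %s = %g",
                 ch, as.numeric(x)[bad[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

channel_name <- function(x, flat_index) {
  names3 <- c("r", "g", "b")
  if (is.matrix(x) && ncol(x) == 3) {
    j <- (flat_index - 1) %/% nrow(x) + 1
    return(names3[j])
  }
  if (length(x) == 3 && is.null(dim(x))) return(names3[flat_index])
  if (is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 3) {
    j <- (flat_index - 1) %/% prod(dim(x)[1:2]) + 1
    return(names3[j])
  }
  paste0("element ", flat_index)
}
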