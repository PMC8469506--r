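#' Read and write reference-spectra CSV files
#'
#' The reference-spectra format pairs the wavelength grid with the 24
#' patch spectra: header `wavelength_nm,patch_01,...,patch_24`, 401 data
#' rows (380-780 nm at 1 nm).
#'
#' @param path file path.
#' @return `read_reference_spectra()`: a [color_target]-classed object.
#' @export
read_reference_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  assert_that(names(df)[1] == "wavelength_nm",
              "first column must be wavelength_nm")
  assert_that(nrow(df) == N_BANDS,
              sprintf("reference CSV needs %d rows", N_BANDS))
  assert_that(isTRUE(all.equal(df$wavelength_nm, wavelength_grid())),
              "wavelengths must be the 380-780 nm, 1 nm grid")
  ids <- names(df)[-1]
  assert_that(length(ids) == 24 && !anyDuplicated(ids),
              "reference CSV needs 24 uniquely named patch columns")
  spectra <- t(as.matrix(df[, -1]))
  rownames(spectra) <- ids
  assert_spectra(spectra, "reference spectra")
  structure(list(spectra = spectra, ids = ids,
                 wavelengths = wavelength_grid(), seed = NA_integer_,
                 min_pairwise_rmse = NA_real_),
            class = "color_target")
}

#' @rdname read_reference_spectra
#' @param target a [color_target] (or 24 x 401 spectra matrix).
#' @export
write_reference_spectra <- function(target, path) {
  spectra <- if (inherits(target, "color_target")) target$spectra else target
  ids <- if (inherits(target, "color_target")) target$ids
         else sprintf("patch_%02d", seq_len(nrow(spectra)))
  df <- data.frame(wavelength_nm = wavelength_grid(), t(spectra),
                   check.names = FALSE)
  names(df) <- c("wavelength_nm", ids)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a patch-capture CSV
#'
#' Format: header `patch_id,r,g,b`; values either 8-bit (0-255) or already
#' normalized to \[0, 1\] — detected automatically (any value above 1 means
#' 8-bit).
#'
#' @param path file path.
#' @return 24 x 3 matrix of RGB in \[0, 1\], rownames = patch ids.
#' @export
read_patch_rgb <- function(path) {
  df <- utils::read.csv(path)
  assert_that(all(c("patch_id", "r", "g", "b") %in% names(df)),
              "patch CSV needs columns patch_id, r, g, b")
  m <- as.matrix(df[, c("r", "g", "b")])
  if (max(m) > 1) m <- m / 255
  rownames(m) <- df$patch_id
  m
}

#' Read and write ground-truth / detection JSON
#'
#' Schema (one object per image):
#' `{image_id, width, height, boxes: [{stage, xmin, ymin, xmax, ymax,
#' score?}]}`. Coordinates are 0-based, half-open, origin top-left.
#'
#' @param x an [make_test_set()] test set, or a list of records each with
#'   `image_id`, `width`, `height` and a `boxes` data.frame.
#' @param path file path.
#' @export
write_truth_json <- function(x, path) {
  records <- x$records %||% x
  payload <- lapply(records, function(r) {
    list(image_id = r$image_id, width = r$width, height = r$height,
         boxes = if (nrow(r$boxes) == 0) list() else r$boxes)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @return `read_truth_json()`: list of records (`image_id`, `width`,
#'   `height`, `boxes` data.frame).
#' @export
read_truth_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(r) {
    boxes <- if (length(r$boxes) == 0) {
      data.frame(stage = character(0), xmin = numeric(0), ymin = numeric(0),
                 xmax = numeric(0), ymax = numeric(0))
    } else {
      do.call(rbind, lapply(r$boxes, function(b) {
        as.data.frame(b[c("stage", "xmin", "ymin", "xmax", "ymax",
                          intersect("score", names(b)))])
      }))
    }
    list(image_id = r$image_id, width = r$width, height = r$height,
         boxes = boxes)
  })
}

#' Read / write an RGB image as PNG
#'
#' Thin wrappers over the png package keeping everything in the package's
#' H x W x 3 \[0, 1\] array convention (alpha channels are dropped,
#' grayscale is expanded).
#'
#' @param path file path.
#' @return `read_image_png()`: H x W x 3 array in \[0, 1\].
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image_png
#' @param image H x W x 3 array in \[0, 1\].
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
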