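## Synthetic endoscopic-scene simulator: per-stage tissue reflectance
## spectra, WLI/NBI camera models, rendered scenes with lesion ground truth,
## and a rendered 24-patch color target. Every generator is a pure function
## of (spec, seed).

## Shared smooth spectral basis: three Gaussian reflectance bumps. All
## synthetic spectra (tissue and color target) are nonnegative mixtures of
## these, so the scene's spectra occupy a low-dimensional set on which the
## RGB -> spectrum map is well defined — the premise the conversion
## regression relies on.
spectral_basis <- function() {
  wl <- wavelength_grid()
  cbind(exp(-(wl - 450)^2 / (2 * 45^2)),
        exp(-(wl - 550)^2 / (2 * 45^2)),
        exp(-(wl - 645)^2 / (2 * 55^2)))
}

#' Synthetic per-stage tissue reflectance model
#'
#' Builds four smooth mean reflectance spectra — one per stage — each a
#' mixture of three Gaussian bumps over wavelength, with stage-specific
#' mixture weights (jittered deterministically by `seed`). Pixel spectra are
#' the stage mean scaled by a smooth brightness field plus additive
#' wavelength-independent Gaussian noise. Construction fails if the stage
#' means are not separated by more than `3 * noise_sd` RMS, the margin the
#' downstream separability checks assume.
#'
#' @param seed RNG seed (determines the weight jitter).
#' @param noise_sd per-band additive noise sd, reflectance units
#'   (default 0.01).
#' @param variation_amplitude relative amplitude of the smooth brightness
#'   field (default 0.08).
#' @return object of class `"tissue_spectrum_model"` with `means` (4 x 401,
#'   rows named by stage), `weights`, `noise_sd`, `variation_amplitude`,
#'   `seed`.
#' @export
tissue_spectrum_model <- function(seed = 1, noise_sd = 0.01,
                                  variation_amplitude = 0.08) {
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  base <- rbind(
    normal               = c(0.30, 0.55, 0.60),
    low_grade_dysplasia  = c(0.22, 0.42, 0.72),
    high_grade_dysplasia = c(0.32, 0.28, 0.50),
    invasive_cancer      = c(0.14, 0.22, 0.40)
  )
  w <- with_seed(seed, base * matrix(runif(12, 0.95, 1.05), 4, 3))
  means <- w %*% t(spectral_basis())
  means[means > 1] <- 1
  rownames(means) <- STAGES
  assert_spectra(means, "stage mean spectra")
  sep <- min(utils::combn(4, 2, function(ij) {
    spectrum_rmse(means[ij[1], ], means[ij[2], ])
  }))
  if (noise_sd > 0 && sep <= 3 * noise_sd) {
    stop(sprintf(paste0("stage means are not separable at this noise level ",
                        "(min pairwise RMSE %.4f <= 3 * %.4f)"), sep, noise_sd))
  }
  structure(list(means = means, weights = w, noise_sd = noise_sd,
                 variation_amplitude = variation_amplitude,
                 seed = seed, min_separation = sep),
            class = "tissue_spectrum_model")
}

#' @rdname tissue_spectrum_model
#' @param model a `tissue_spectrum_model`.
#' @return `stage_mean_spectra()`: the 4 x 401 matrix of stage means.
#' @export
stage_mean_spectra <- function(model) model$means

#' @export
print.tissue_spectrum_model <- function(x, ...) {
  cat(sprintf(paste0("synthetic tissue spectra: 4 stages, noise sd %.3g, ",
                     "min pairwise RMSE %.3f (seed %d)\n"),
              x$noise_sd, x$min_separation, x$seed))
  invisible(x)
}

#' Synthetic 24-patch color target
#'
#' Generates 24 smooth, mutually distinct reflectance spectra standing in
#' for a measured 24-patch calibration target (measured ColorChecker spectra
#' are licensed and not bundled; users with a measured target can load it
#' with [read_reference_spectra()]). Patches are mixtures of the shared
#' smooth basis with weights on a 3 x 3 x 3 grid (3 levels per basis
#' function, the 3 least distinct combinations dropped), jittered
#' deterministically by `seed`. All spectra lie in \[0, 1\] and every pair
#' differs by more than 0.03 RMS.
#'
#' @param seed RNG seed.
#' @return object of class `"color_target"`: `spectra` (24 x 401), `ids`
#'   (`patch_01..patch_24`), `wavelengths`, `seed`.
#' @export
make_color_target <- function(seed = 1) {
  levels <- c(0.10, 0.32, 0.55)
  grid <- as.matrix(expand.grid(levels, levels, levels))
  ## drop 3 interior combinations to get 24, keeping the extremes
  drop <- c(14, 5, 23) # (2,2,2), (2,1,1), (2,2,3) in level indices
  w <- grid[-drop, , drop = FALSE]
  w <- with_seed(seed, w + matrix(runif(72, -0.04, 0.04), 24, 3))
  w[w < 0.01] <- 0.01
  spectra <- w %*% t(spectral_basis())
  spectra[spectra > 1] <- 1
  spectra[spectra < 0] <- 0
  ids <- sprintf("patch_%02d", 1:24)
  rownames(spectra) <- ids
  assert_spectra(spectra, "color-target spectra")
  d <- as.matrix(stats::dist(spectra)) / sqrt(N_BANDS)
  min_rmse <- min(d[upper.tri(d)])
  assert_that(min_rmse > 0.03,
              "color-target patches are not mutually distinct (RMSE <= 0.03)")
  structure(list(spectra = spectra, ids = ids,
                 wavelengths = wavelength_grid(), seed = seed,
                 min_pairwise_rmse = min_rmse),
            class = "color_target")
}

#' @export
print.color_target <- function(x, ...) {
  cat(sprintf("synthetic 24-patch color target (seed %d, min pairwise RMSE %.3f)\n",
              x$seed, x$min_pairwise_rmse))
  invisible(x)
}

#' Synthetic camera model
#'
#' Three spectral sensitivity curves (R, G, B rows, each normalized to unit
#' area over the 401-band grid), an exposure scalar, a transfer curve and an
#' optional bit depth. The WLI camera uses broad Gaussians (a conventional
#' white-light endoscope); the NBI camera concentrates its sensitivity in
#' narrow windows at the clinically used 415 nm and 540 nm bands (blue at
#' 415 nm, green at 540 nm, red in a slightly wider window at 550 nm), each
#' curve holding at least 90% of its mass inside a 60 nm window. All camera
#' parameters are fictional: the source system publishes none.
#'
#' A channel is rendered as
#' `transfer(clip(exposure * sum(sensitivity * spectrum)))`, then quantized
#' to `quantize_bits` when rendering scenes.
#'
#' @param modality `"wli"` or `"nbi"`.
#' @param exposure linear exposure scalar (default 0.9: a perfect white
#'   reflector renders just below clipping).
#' @param transfer transfer curve name (see [linearize_rgb()]).
#' @param quantize_bits bit depth of rendered images (default 8; `NULL`
#'   disables quantization).
#' @return object of class `"camera_model"`.
#' @export
camera_model <- function(modality = c("wli", "nbi"), exposure = 0.9,
                         transfer = "srgb", quantize_bits = 8) {
  modality <- match.arg(modality)
  assert_that(exposure >= 0, "exposure must be >= 0")
  wl <- wavelength_grid()
  curves <- if (modality == "wli") {
    rbind(r = exp(-(wl - 610)^2 / (2 * 55^2)),
          g = exp(-(wl - 545)^2 / (2 * 50^2)),
          b = exp(-(wl - 465)^2 / (2 * 45^2)))
  } else {
    rbind(r = exp(-(wl - 550)^2 / (2 * 18^2)),
          g = exp(-(wl - 540)^2 / (2 * 10^2)),
          b = exp(-(wl - 415)^2 / (2 * 10^2)))
  }
  curves <- curves / rowSums(curves)
  structure(list(sensitivities = curves, exposure = exposure,
                 transfer = transfer, modality = modality,
                 quantize_bits = quantize_bits),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("synthetic %s camera: exposure %.2f, transfer %s, %s\n",
              toupper(x$modality), x$exposure, x$transfer,
              if (is.null(x$quantize_bits)) "float output"
              else sprintf("%d-bit output", x$quantize_bits)))
  invisible(x)
}

## spectra (n x 401) -> n x 3 channels. Returns encoded channels with the
## pre-clip linear channels and a clipped flag as attributes.
render_channels <- function(spectra, camera, quantize = TRUE) {
  linear <- camera$exposure * (spectra %*% t(camera$sensitivities))
  clipped_px <- rowSums(linear > 1 | linear < 0) > 0
  clip01 <- pmin(pmax(linear, 0), 1)
  enc <- encode_rgb(clip01, camera$transfer)
  if (quantize && !is.null(camera$quantize_bits)) {
    q <- 2^camera$quantize_bits - 1
    enc <- round(enc * q) / q
  }
  attr(enc, "linear") <- linear
  attr(enc, "clipped") <- clipped_px
  enc
}

#' Render a camera's view of the 24-patch color target
#'
#' Applies the same rendering equation as [render_scene()] to each flat
#' patch: no noise, and by default no quantization, giving the paired
#' (RGB, reference spectrum) observations the conversion regression is
#' fitted on.
#'
#' @param target a [make_color_target()] target (or 24 x 401 spectra
#'   matrix).
#' @param camera a [camera_model()].
#' @param quantize quantize to the camera's bit depth (default FALSE).
#' @return 24 x 3 matrix of encoded RGB triplets; the pre-transfer linear
#'   channels are attached as the `"linear"` attribute.
#' @export
capture_color_target <- function(target, camera, quantize = FALSE) {
  spectra <- if (inherits(target, "color_target")) target$spectra else target
  assert_spectra(spectra, "target spectra")
  render_channels(as.matrix(spectra), camera, quantize = quantize)
}

#' Synthetic scene specification
#'
#' A scene is a normal-tissue background with zero or more elliptical
#' lesions, each carrying a lesion stage. Every ellipse must lie inside the
#' image. Ground truth for detection is the tight axis-aligned bounding box
#' of each ellipse.
#'
#' @param width,height image size in pixels.
#' @param lesions list of lesions, each a list with `cx, cy` (center),
#'   `a, b` (semi-axes), `angle` (radians, default 0) and `stage` (a lesion
#'   stage label).
#' @param seed RNG seed for the scene's pixel noise.
#' @return object of class `"scene_spec"`.
#' @export
scene_spec <- function(width, height, lesions = list(), seed = 1) {
  assert_that(width >= 1 && height >= 1, "scene dimensions must be >= 1")
  for (le in lesions) {
    assert_that(all(c("cx", "cy", "a", "b", "stage") %in% names(le)),
                "each lesion needs cx, cy, a, b, stage")
    if (is.null(le$angle)) le$angle <- 0
    assert_that(le$a > 0 && le$b > 0, "lesion semi-axes must be positive")
    assert_that(le$stage %in% LESION_STAGES,
                "lesion stage must be a non-normal stage")
    ext <- ellipse_extents(le)
    assert_that(le$cx - ext[1] >= 0 && le$cx + ext[1] <= width &&
                  le$cy - ext[2] >= 0 && le$cy + ext[2] <= height,
                "lesion ellipse must lie inside the image")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 lesions = lesions, seed = seed),
            class = "scene_spec")
}

## half-extents of the tight axis-aligned bounding box of a rotated ellipse
ellipse_extents <- function(le) {
  ang <- le$angle %||% 0
  c(sqrt((le$a * cos(ang))^2 + (le$b * sin(ang))^2),
    sqrt((le$a * sin(ang))^2 + (le$b * cos(ang))^2))
}

#' Render a synthetic endoscopic scene
#'
#' Builds the per-pixel true spectrum (stage mean scaled by a smooth
#' brightness field, plus seeded noise), renders it through the camera, and
#' returns the RGB image together with the ground-truth spectral cube and
#' lesion bounding boxes — everything an upstream test needs.
#'
#' @param scene a [scene_spec()].
#' @param tissue a [tissue_spectrum_model()].
#' @param camera a [camera_model()].
#' @return list of class `"rendered_scene"`: `image` (H x W x 3, encoded,
#'   quantized per the camera), `cube` (the true [spectral_cube]), `boxes`
#'   (ground-truth data.frame `stage, xmin, ymin, xmax, ymax`),
#'   `clipped` (H x W logical: pixels whose linear channels clipped),
#'   `stage_map` (H x W integer), `scene`.
#' @export
render_scene <- function(scene, tissue, camera) {
  h <- scene$height; w <- scene$width
  ## column-major pixel order: index p = (col-1)*h + row
  px_col <- rep(seq_len(w), each = h) - 0.5  # pixel-center x
  px_row <- rep(seq_len(h), times = w) - 0.5 # pixel-center y
  stage_idx <- rep(1L, h * w)
  boxes <- NULL
  for (le in scene$lesions) {
    ang <- le$angle %||% 0
    dx <- px_col - le$cx; dy <- px_row - le$cy
    u <- dx * cos(ang) + dy * sin(ang)
    v <- -dx * sin(ang) + dy * cos(ang)
    inside <- (u / le$a)^2 + (v / le$b)^2 <= 1
    stage_idx[inside] <- stage_severity(le$stage)
    ext <- ellipse_extents(le)
    boxes <- rbind(boxes, data.frame(
      stage = le$stage,
      xmin = le$cx - ext[1], ymin = le$cy - ext[2],
      xmax = le$cx + ext[1], ymax = le$cy + ext[2]))
  }
  if (is.null(boxes)) {
    boxes <- data.frame(stage = character(0), xmin = numeric(0),
                        ymin = numeric(0), xmax = numeric(0),
                        ymax = numeric(0))
  }
  ## smooth multiplicative brightness field (fixed shape; seed drives noise)
  amp <- tissue$variation_amplitude
  field <- 1 + amp * (0.6 * sin(2 * pi * (px_col / w * 1.3 + 0.2)) *
                        cos(2 * pi * px_row / h * 0.9) +
                      0.4 * sin(2 * pi * (px_col + px_row) / (w + h) * 1.7))
  spectra <- tissue$means[stage_idx, , drop = FALSE] * field
  if (tissue$noise_sd > 0) {
    spectra <- spectra + with_seed(scene$seed,
      matrix(rnorm(length(spectra), sd = tissue$noise_sd),
             nrow = nrow(spectra)))
  }
  spectra[spectra < 0] <- 0
  spectra[spectra > 1.5] <- 1.5
  enc <- render_channels(spectra, camera, quantize = TRUE)
  structure(list(
    image = array(enc, dim = c(h, w, 3)),
    cube = spectral_cube(spectra, modality = camera$modality, dims = c(h, w)),
    boxes = boxes,
    clipped = matrix(attr(enc, "clipped"), nrow = h, ncol = w),
    stage_map = matrix(stage_idx, nrow = h, ncol = w),
    scene = scene
  ), class = "rendered_scene")
}

#' Geometric augmentation of an image and its boxes
#'
#' Flips and right-angle rotations, applied consistently to pixels and
#' bounding boxes (areas are preserved). Returns the original plus one
#' entry per op.
#'
#' @param image H x W x 3 array.
#' @param boxes data.frame with `xmin, ymin, xmax, ymax` (and any other
#'   columns, carried through).
#' @param ops character vector, subset of
#'   `c("hflip", "vflip", "rot90", "rot180", "rot270")` (rotations are
#'   clockwise).
#' @return list of `list(image, boxes, op)`, first entry the original.
#' @export
augment <- function(image, boxes, ops = character(0)) {
  known <- c("hflip", "vflip", "rot90", "rot180", "rot270")
  bad <- setdiff(ops, known)
  if (length(bad)) stop("unsupported augmentation op(s): ",
                        paste(bad, collapse = ", "))
  out <- list(list(image = image, boxes = boxes, op = "identity"))
  for (op in ops) {
    out[[length(out) + 1]] <- apply_aug(image, boxes, op)
  }
  out
}

apply_aug <- function(image, boxes, op) {
  h <- dim(image)[1]; w <- dim(image)[2]
  b <- boxes
  img <- switch(op,
    hflip = image[, w:1, , drop = FALSE],
    vflip = image[h:1, , , drop = FALSE],
    rot90 = aperm(image, c(2, 1, 3))[, h:1, , drop = FALSE][1:w, , , drop = FALSE],
    rot180 = image[h:1, w:1, , drop = FALSE],
    rot270 = aperm(image, c(2, 1, 3))[w:1, , , drop = FALSE]
  )
  if (nrow(b) > 0) {
    x0 <- b$xmin; y0 <- b$ymin; x1 <- b$xmax; y1 <- b$ymax
    new <- switch(op,
      hflip = list(w - x1, y0, w - x0, y1),
      vflip = list(x0, h - y1, x1, h - y0),
      rot90 = list(h - y1, x0, h - y0, x1),
      rot180 = list(w - x1, h - y1, w - x0, h - y0),
      rot270 = list(y0, w - x1, y1, w - x0)
    )
    b$xmin <- new[[1]]; b$ymin <- new[[2]]; b$xmax <- new[[3]]; b$ymax <- new[[4]]
  }
  list(image = img, boxes = b, op = op)
}

#' Generate a balanced synthetic test set with ground truth
#'
#' `n_per_stage` scenes per stage: normal scenes have no lesion; each lesion
#' stage gets single-lesion scenes with randomized (seeded) ellipse
#' geometry. Every record carries the rendered image, the ground-truth
#' boxes, the image-level true stage, and the image size — the inputs a
#' scorer (see [stub_scorer()]) and the evaluation chain consume.
#'
#' @param n_per_stage images per stage (>= 1).
#' @param seed RNG seed.
#' @param camera a [camera_model()].
#' @param tissue a [tissue_spectrum_model()] (default: one built from
#'   `seed`).
#' @param width,height scene size in pixels (default 48 x 48).
#' @return object of class `"endo_test_set"`: `records` (list of records
#'   with `image_id, image, boxes, stage, width, height`), `truth`
#'   (data.frame of all ground-truth boxes), `camera`, `tissue`, `seed`.
#' @export
make_test_set <- function(n_per_stage, seed = 1, camera = camera_model("wli"),
                          tissue = NULL, width = 48, height = 48) {
  assert_that(n_per_stage >= 1, "n_per_stage must be >= 1")
  if (is.null(tissue)) tissue <- tissue_spectrum_model(seed = seed)
  geom <- with_seed(seed, {
    n_lesion <- 3 * n_per_stage
    data.frame(cx = runif(n_lesion, 0.35, 0.65) * width,
               cy = runif(n_lesion, 0.35, 0.65) * height,
               a = runif(n_lesion, 0.10, 0.22) * width,
               b = runif(n_lesion, 0.10, 0.22) * height,
               angle = runif(n_lesion, 0, pi))
  })
  records <- list()
  k <- 0L; li <- 0L
  for (stage in STAGES) {
    for (i in seq_len(n_per_stage)) {
      k <- k + 1L
      lesions <- list()
      if (stage != "normal") {
        li <- li + 1L
        g <- geom[li, ]
        lesions <- list(list(cx = g$cx, cy = g$cy, a = g$a, b = g$b,
                             angle = g$angle, stage = stage))
      }
      sc <- scene_spec(width, height, lesions, seed = seed * 1000L + k)
      r <- render_scene(sc, tissue, camera)
      records[[k]] <- list(image_id = sprintf("img_%03d", k),
                           image = r$image, boxes = r$boxes, stage = stage,
                           width = width, height = height)
    }
  }
  truth <- do.call(rbind, lapply(records, function(r) {
    if (nrow(r$boxes) == 0) return(NULL)
    cbind(image_id = r$image_id, r$boxes)
  }))
  structure(list(records = records, truth = truth, camera = camera,
                 tissue = tissue, seed = seed),
            class = "endo_test_set")
}

#' @export
print.endo_test_set <- function(x, ...) {
  n <- length(x$records)
  cat(sprintf("synthetic test set: %d images (%d per stage), %s camera, seed %d\n",
              n, n %/% 4, toupper(x$camera$modality), x$seed))
  invisible(x)
}
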