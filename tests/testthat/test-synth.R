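# Synthetic scene simulator: tissue spectra, color target, cameras,
# rendering, augmentation, test sets.

test_that("stage spectra are smooth, separated and deterministic per seed", {
  tis <- tissue_spectrum_model(seed = 1)
  expect_equal(dim(tis$means), c(4, 401))
  expect_true(all(tis$means >= 0 & tis$means <= 1))
  # separation invariant: pairwise RMSE > 3 * noise sd
  pairs <- combn(4, 2)
  for (j in seq_len(ncol(pairs))) {
    expect_gt(spectrum_rmse(tis$means[pairs[1, j], ], tis$means[pairs[2, j], ]),
              3 * tis$noise_sd)
  }
  expect_identical(tissue_spectrum_model(seed = 1)$means, tis$means)
  expect_false(identical(tissue_spectrum_model(seed = 2)$means, tis$means))
  # unsatisfiable separation -> configuration error
  expect_error(tissue_spectrum_model(seed = 1, noise_sd = 0.5),
               "not separable")
  # noise-free scenes reproduce the stage mean exactly
  tis0 <- tissue_spectrum_model(seed = 1, noise_sd = 0,
                                variation_amplitude = 0)
  sc <- scene_spec(8, 8, seed = 1)
  r <- render_scene(sc, tis0, camera_model("wli"))
  expect_equal(as.matrix(r$cube)[5, ], unname(tis0$means["normal", ]),
               tolerance = 1e-12)
})

test_that("color target has 24 distinct in-range patches, fixed by seed", {
  tgt <- make_color_target(seed = 1)
  expect_equal(dim(tgt$spectra), c(24, 401))
  expect_equal(anyDuplicated(tgt$ids), 0L)
  expect_true(all(tgt$spectra >= 0 & tgt$spectra <= 1))
  expect_gt(tgt$min_pairwise_rmse, 0.03)
  expect_identical(make_color_target(seed = 1)$spectra, tgt$spectra)
  # captured through the camera, patches stay distinct at 8-bit depth
  rgb <- capture_color_target(tgt, camera_model("wli"), quantize = TRUE)
  expect_equal(nrow(unique(round(rgb * 255))), 24)
})

test_that("camera rendering is linear before transfer and NBI is narrow-band", {
  cam <- camera_model("wli")
  zero <- capture_color_target(matrix(0, 1, 401), cam)
  expect_equal(as.numeric(zero), c(0, 0, 0))
  tgt <- make_color_target(seed = 1)
  lin1 <- attr(capture_color_target(tgt, camera_model("wli", exposure = 0.4)),
               "linear")
  lin2 <- attr(capture_color_target(tgt, camera_model("wli", exposure = 0.8)),
               "linear")
  expect_equal(lin2, 2 * lin1, tolerance = 1e-12)
  # NBI curves: >= 90% of each curve's mass inside a 60 nm window
  nbi <- camera_model("nbi")
  for (ch in 1:3) {
    s <- nbi$sensitivities[ch, ]
    peak <- which.max(s)
    win <- max(1, peak - 30):min(401, peak + 30)
    expect_gte(sum(s[win]) / sum(s), 0.90)
  }
  # all curves nonnegative and on the grid
  expect_true(all(nbi$sensitivities >= 0))
  expect_equal(ncol(nbi$sensitivities), 401)
})

test_that("scene rendering produces tight ellipse boxes and valid channels", {
  tis <- tissue_spectrum_model(seed = 2)
  le <- list(cx = 30, cy = 25, a = 10, b = 6, angle = 0.7,
             stage = "high_grade_dysplasia")
  sc <- scene_spec(64, 48, lesions = list(le), seed = 2)
  r <- render_scene(sc, tis, camera_model("wli"))
  expect_equal(dim(r$image), c(48, 64, 3))
  expect_true(all(r$image >= 0 & r$image <= 1))
  expect_equal(nrow(r$boxes), 1)
  ex <- sqrt((le$a * cos(le$angle))^2 + (le$b * sin(le$angle))^2)
  ey <- sqrt((le$a * sin(le$angle))^2 + (le$b * cos(le$angle))^2)
  expect_equal(as.numeric(r$boxes[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(30 - ex, 25 - ey, 30 + ex, 25 + ey), tolerance = 1e-9)
  # every pixel the stage map marks as lesion lies inside that box
  lesion_px <- which(r$stage_map > 1, arr.ind = TRUE)
  expect_true(all(lesion_px[, 2] - 0.5 >= r$boxes$xmin &
                    lesion_px[, 2] - 0.5 <= r$boxes$xmax))
  # zero exposure -> all-black image
  dark <- render_scene(sc, tis, camera_model("wli", exposure = 0))
  expect_true(all(dark$image == 0))
  # same spec renders identically; WLI and NBI differ clearly
  r2 <- render_scene(sc, tis, camera_model("wli"))
  expect_identical(r2$image, r$image)
  rn <- render_scene(sc, tis, camera_model("nbi"))
  expect_gt(mean(abs(rn$image - r$image)), 0.01)
  expect_error(scene_spec(20, 20, lesions = list(
    list(cx = 2, cy = 2, a = 5, b = 5, stage = "invasive_cancer"))),
    "inside")
})

test_that("augmentation transforms boxes with the pixels and preserves area", {
  set.seed(30)
  img <- array(runif(40 * 60 * 3), dim = c(40, 60, 3)) # H=40, W=60
  boxes <- data.frame(stage = "invasive_cancer",
                      xmin = 0, ymin = 0, xmax = 10, ymax = 20)
  # horizontal flip is an involution
  once <- augment(img, boxes, "hflip")[[2]]
  twice <- augment(once$image, once$boxes, "hflip")[[2]]
  expect_equal(twice$image, img)
  expect_equal(twice$boxes[, c("xmin", "ymin", "xmax", "ymax")],
               boxes[, c("xmin", "ymin", "xmax", "ymax")])
  # rotation by 90 degrees swaps box dimensions, area preserved
  r90 <- augment(img, boxes, "rot90")[[2]]
  expect_equal(dim(r90$image), c(60, 40, 3))
  w <- r90$boxes$xmax - r90$boxes$xmin
  h <- r90$boxes$ymax - r90$boxes$ymin
  expect_equal(c(w, h), c(20, 10))
  expect_equal(w * h, 200)
  # four 90-degree rotations compose to the identity
  cur <- list(image = img, boxes = boxes)
  for (i in 1:4) cur <- augment(cur$image, cur$boxes, "rot90")[[2]]
  expect_equal(cur$image, img)
  expect_equal(cur$boxes$xmin, boxes$xmin)
  # pixels move with the boxes: a pixel inside the box stays inside
  marked <- img; marked[5, 3, ] <- 1   # x ~ 2.5, y ~ 4.5, inside the box
  m90 <- augment(marked, boxes, "rot90")[[2]]
  hit <- which(m90$image[, , 1] == 1, arr.ind = TRUE)
  expect_true(hit[1, 2] - 0.5 >= m90$boxes$xmin &&
                hit[1, 2] - 0.5 <= m90$boxes$xmax)
  expect_true(hit[1, 1] - 0.5 >= m90$boxes$ymin &&
                hit[1, 1] <= m90$boxes$ymax)
  # empty ops -> singleton original; unknown op errors
  expect_length(augment(img, boxes, character(0)), 1)
  expect_error(augment(img, boxes, "shear"), "unsupported")
})

test_that("balanced test sets count out scenes and ground-truth boxes", {
  ts <- make_test_set(2, seed = 4, width = 32, height = 32)
  expect_length(ts$records, 8)
  expect_equal(sum(vapply(ts$records, function(r) nrow(r$boxes), 1L)), 6)
  expect_equal(nrow(ts$truth), 6)
  stages_seen <- vapply(ts$records, function(r) r$stage, character(1))
  expect_equal(unname(table(stages_seen)[stages()]), rep(2L, 4),
               ignore_attr = TRUE)
  # determinism
  ts2 <- make_test_set(2, seed = 4, width = 32, height = 32)
  expect_identical(ts2$records[[3]]$image, ts$records[[3]]$image)
})
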