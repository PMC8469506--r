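#' Bounding boxes
#'
#' Boxes are rows of a numeric matrix (or data.frame) with columns
#' `xmin, ymin, xmax, ymax` in pixels, origin at the top-left corner,
#' half-open intervals (`xmax > xmin`, `ymax > ymin`).
#'
#' @param boxes n x 4 matrix/data.frame of box coordinates.
#' @return validated n x 4 numeric matrix.
#' @export
as_boxes <- function(boxes) {
  if (is.data.frame(boxes)) {
    boxes <- as.matrix(boxes[, c("xmin", "ymin", "xmax", "ymax")])
  }
  if (is.null(dim(boxes))) boxes <- matrix(boxes, ncol = 4, byrow = TRUE)
  assert_that(ncol(boxes) == 4, "boxes need 4 columns: xmin, ymin, xmax, ymax")
  assert_that(all(is.finite(boxes)) && all(boxes >= 0),
              "box coordinates must be finite and >= 0")
  if (any(boxes[, 3] <= boxes[, 1]) || any(boxes[, 4] <= boxes[, 2])) {
    stop("degenerate box: xmax must exceed xmin and ymax must exceed ymin")
  }
  colnames(boxes) <- c("xmin", "ymin", "xmax", "ymax")
  boxes
}

box_area <- function(b) (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])

#' Intersection over union between two sets of boxes
#'
#' @param a,b box sets (see [as_boxes()]), n x 4 and m x 4.
#' @return n x m matrix of IoU values in \[0, 1\]; 0 for disjoint pairs.
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)) # 1/7
#' @export
box_iou <- function(a, b) {
  a <- as_boxes(a); b <- as_boxes(b)
  n <- nrow(a); m <- nrow(b)
  ix <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  iy <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- ix * iy
  union <- outer(box_area(a), box_area(b), "+") - inter
  inter / union
}

#' Center/size offset coding between ground-truth and default boxes
#'
#' The regression targets the detector predicts: the center shift relative to
#' the default box size and the log size ratios, each divided by the usual
#' variance scalers (0.1, 0.1, 0.2, 0.2). `decode_offsets()` is the exact
#' inverse.
#'
#' @param gt,defaults aligned n x 4 box sets (row i of `gt` paired with
#'   row i of `defaults`).
#' @param offsets n x 4 encoded offsets.
#' @param variances the 4 scalers.
#' @return n x 4 matrix: encoded offsets, or decoded boxes.
#' @export
encode_offsets <- function(gt, defaults, variances = c(0.1, 0.1, 0.2, 0.2)) {
  gt <- as_boxes(gt); defaults <- as_boxes(defaults)
  assert_that(nrow(gt) == nrow(defaults), "gt/defaults row mismatch")
  gcx <- (gt[, 1] + gt[, 3]) / 2;  gw <- gt[, 3] - gt[, 1]
  gcy <- (gt[, 2] + gt[, 4]) / 2;  gh <- gt[, 4] - gt[, 2]
  dcx <- (defaults[, 1] + defaults[, 3]) / 2; dw <- defaults[, 3] - defaults[, 1]
  dcy <- (defaults[, 2] + defaults[, 4]) / 2; dh <- defaults[, 4] - defaults[, 2]
  cbind((gcx - dcx) / dw / variances[1],
        (gcy - dcy) / dh / variances[2],
        log(gw / dw) / variances[3],
        log(gh / dh) / variances[4])
}

#' @rdname encode_offsets
#' @export
decode_offsets <- function(offsets, defaults, variances = c(0.1, 0.1, 0.2, 0.2)) {
  defaults <- as_boxes(defaults)
  if (is.null(dim(offsets))) offsets <- matrix(offsets, ncol = 4, byrow = TRUE)
  assert_that(nrow(offsets) == nrow(defaults), "offsets/defaults row mismatch")
  dcx <- (defaults[, 1] + defaults[, 3]) / 2; dw <- defaults[, 3] - defaults[, 1]
  dcy <- (defaults[, 2] + defaults[, 4]) / 2; dh <- defaults[, 4] - defaults[, 2]
  cx <- offsets[, 1] * variances[1] * dw + dcx
  cy <- offsets[, 2] * variances[2] * dh + dcy
  w <- dw * exp(offsets[, 3] * variances[3])
  h <- dh * exp(offsets[, 4] * variances[4])
  out <- cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  colnames(out) <- c("xmin", "ymin", "xmax", "ymax")
  out
}

#' Tile default (anchor) boxes over feature maps
#'
#' Default boxes of several scales and aspect ratios are placed at every
#' cell center of each feature map, mirroring the detector's convolutional
#' tiling, then clipped to the image. Each map spec is a list with `grid`
#' (cells per side), `scale` (box side as a fraction of the image),
#' `scale_next` (the next map's scale; when present an extra square box at
#' the geometric-mean scale is added) and `aspect_ratios` (each ratio a adds
#' boxes of aspect a and 1/a). Per-cell box count is therefore
#' `1 + !is.null(scale_next) + 2 * length(aspect_ratios)`.
#'
#' @param width,height image size in pixels.
#' @param maps list of per-map specs; default [ssd_feature_maps()], the
#'   canonical 300 x 300 layout (grids 38, 19, 10, 5, 3, 1 with 4/6/6/6/4/4
#'   boxes per cell — 8732 boxes).
#' @return data.frame of boxes with metadata columns `feature_map`, `scale`,
#'   `aspect`.
#' @export
generate_default_boxes <- function(width, height, maps = ssd_feature_maps()) {
  if (length(maps) == 0) stop("feature-map spec must not be empty")
  out <- vector("list", length(maps))
  for (mi in seq_along(maps)) {
    m <- maps[[mi]]
    shapes <- list(c(m$scale, m$scale, 1))
    if (!is.null(m$scale_next)) {
      s2 <- sqrt(m$scale * m$scale_next)
      shapes <- c(shapes, list(c(s2, s2, 1)))
    }
    for (a in m$aspect_ratios) {
      shapes <- c(shapes,
                  list(c(m$scale * sqrt(a), m$scale / sqrt(a), a)),
                  list(c(m$scale / sqrt(a), m$scale * sqrt(a), 1 / a)))
    }
    centers <- (seq_len(m$grid) - 0.5) / m$grid
    cx <- rep(centers * width, each = m$grid)
    cy <- rep(centers * height, times = m$grid)
    rows <- lapply(shapes, function(s) {
      w2 <- s[1] * width / 2; h2 <- s[2] * height / 2
      data.frame(xmin = pmax(0, cx - w2), ymin = pmax(0, cy - h2),
                 xmax = pmin(width, cx + w2), ymax = pmin(height, cy + h2),
                 feature_map = mi, scale = s[1], aspect = s[3])
    })
    out[[mi]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname generate_default_boxes
#' @export
ssd_feature_maps <- function() {
  grids <- c(38, 19, 10, 5, 3, 1)
  scales <- c(0.10, 0.20, 0.375, 0.55, 0.725, 0.90)
  next_scales <- c(scales[-1], 1.0)
  ars <- list(2, c(2, 3), c(2, 3), c(2, 3), 2, 2)
  lapply(seq_along(grids), function(i) {
    list(grid = grids[i], scale = scales[i], scale_next = next_scales[i],
         aspect_ratios = ars[[i]])
  })
}

#' Non-maximum suppression of detections
#'
#' Greedy, per stage: detections are visited in descending score order
#' (ties broken by original position); a detection is kept unless a
#' previously kept detection of the same stage overlaps it with
#' IoU >= `iou_threshold`.
#'
#' @param dets data.frame with columns `xmin, ymin, xmax, ymax, stage,
#'   score` (scores in \[0, 1\]).
#' @param iou_threshold suppression threshold, default 0.45.
#' @return the kept rows, ordered by descending score; idempotent.
#' @export
nms <- function(dets, iou_threshold = 0.45) {
  if (nrow(dets) == 0) return(dets)
  assert_that(all(dets$score >= 0 & dets$score <= 1),
              "detection scores must lie in [0, 1]")
  ord <- order(-dets$score, seq_len(nrow(dets)))
  boxes <- as_boxes(dets)
  keep <- logical(nrow(dets))
  for (i in ord) {
    kept_same <- which(keep & dets$stage == dets$stage[i])
    if (length(kept_same) == 0 ||
        all(box_iou(boxes[i, , drop = FALSE],
                    boxes[kept_same, , drop = FALSE]) < iou_threshold)) {
      keep[i] <- TRUE
    }
  }
  out <- dets[ord[keep[ord]], , drop = FALSE]
  rownames(out) <- NULL
  out
}
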