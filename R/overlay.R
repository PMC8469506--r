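#' Stage overlay colors
#'
#' The display convention for detection overlays: low-grade dysplasia is
#' boxed in blue, high-grade dysplasia in light blue-gray, invasive cancer
#' in orange; ground-truth boxes are drawn in green for comparison. Normal
#' images are left unmodified (no box is drawn for a normal call).
#'
#' @return named list of RGB triplets in \[0, 1\].
#' @export
stage_colors <- function() {
  list(low_grade_dysplasia  = c(0.10, 0.30, 0.95),
       high_grade_dysplasia = c(0.69, 0.77, 0.82),
       invasive_cancer      = c(1.00, 0.55, 0.05),
       ground_truth         = c(0.05, 0.80, 0.15))
}

#' Draw detections (and optionally ground truth) on an image
#'
#' Rectangle borders are painted in the stage color; with `labels = TRUE` a
#' short stage tag (LGD / HGD / INV, GT for ground truth) is drawn in a
#' small bitmap font above the box's top-left corner. Boxes reaching outside
#' the image are clipped with a warning. An empty detection set returns the
#' image pixel-identical.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param dets detection data.frame (`xmin, ymin, xmax, ymax, stage`,
#'   optionally `score`); stages must be lesion stages.
#' @param gts optional ground-truth boxes (same columns, drawn green).
#' @param labels draw stage tags (default TRUE).
#' @param thickness border thickness in pixels.
#' @param colors color map, see [stage_colors()].
#' @return the annotated H x W x 3 array.
#' @export
render_overlay <- function(image, dets = NULL, gts = NULL, labels = TRUE,
                           thickness = 2, colors = stage_colors()) {
  d <- dim(image)
  assert_that(length(d) == 3 && d[3] == 3, "image must be H x W x 3")
  out <- image
  draw_set <- function(img, boxes, stage_of, tag_of) {
    for (i in seq_len(nrow(boxes))) {
      col <- colors[[stage_of(i)]]
      img <- draw_rect(img, as.numeric(boxes[i, c("xmin", "ymin", "xmax", "ymax")]),
                       col, thickness)
      if (labels) {
        b <- boxes[i, ]
        img <- draw_text(img, tag_of(i), x = b$xmin, y = b$ymin - 12, col)
      }
    }
    img
  }
  if (!is.null(gts) && nrow(gts) > 0) {
    out <- draw_set(out, gts, function(i) "ground_truth", function(i) "GT")
  }
  if (!is.null(dets) && nrow(dets) > 0) {
    tags <- c(low_grade_dysplasia = "LGD", high_grade_dysplasia = "HGD",
              invasive_cancer = "INV")
    out <- draw_set(out, dets, function(i) dets$stage[i],
                    function(i) tags[[dets$stage[i]]])
  }
  out
}

## paint the border of a half-open box [xmin,xmax) x [ymin,ymax)
draw_rect <- function(img, box, col, thickness = 2) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (box[1] < 0 || box[2] < 0 || box[3] > w || box[4] > h) {
    warning("box reaches outside the image; clipping")
  }
  x0 <- max(0, floor(box[1])); y0 <- max(0, floor(box[2]))
  x1 <- min(w, ceiling(box[3])); y1 <- min(h, ceiling(box[4]))
  if (x1 <= x0 || y1 <= y0) return(img)
  cols <- (x0 + 1):x1           # 1-based pixel columns
  rows <- (y0 + 1):y1
  t_rows <- intersect(c(y0 + seq_len(thickness), y1 - seq_len(thickness) + 1), rows)
  t_cols <- intersect(c(x0 + seq_len(thickness), x1 - seq_len(thickness) + 1), cols)
  for (ch in 1:3) {
    img[t_rows, cols, ch] <- col[ch]
    img[rows, t_cols, ch] <- col[ch]
  }
  img
}

## minimal 3x5 bitmap font for the stage tags
tag_font <- function() {
  glyph <- function(s) {
    m <- matrix(as.integer(strsplit(gsub("\n", "", s), "")[[1]]), 5, 3,
                byrow = TRUE)
    m
  }
  list(
    G = glyph("111100101101111"),
    T = glyph("111010010010010"),
    L = glyph("100100100100111"),
    D = glyph("110101101101110"),
    H = glyph("101101111101101"),
    I = glyph("111010010010111"),
    N = glyph("101111111111101"),
    V = glyph("101101101101010")
  )
}

draw_text <- function(img, text, x, y, col, scale = 2) {
  font <- tag_font()
  h <- dim(img)[1]; w <- dim(img)[2]
  cx <- floor(x)
  cy <- floor(y)
  for (ch in strsplit(text, "")[[1]]) {
    g <- font[[ch]]
    if (!is.null(g)) {
      for (r in 1:5) for (c in 1:3) {
        if (g[r, c] == 1) {
          rr <- cy + (r - 1) * scale + seq_len(scale)
          cc <- cx + (c - 1) * scale + seq_len(scale)
          rr <- rr[rr >= 1 & rr <= h]; cc <- cc[cc >= 1 & cc <= w]
          if (length(rr) && length(cc)) {
            for (k in 1:3) img[rr, cc, k] <- col[k]
          }
        }
      }
    }
    cx <- cx + 4 * scale
  }
  img
}
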