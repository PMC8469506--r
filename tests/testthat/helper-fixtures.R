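# Shared fixture builders and independent oracles.

# An exact-linear calibration fixture: reference spectra generated as
# features %*% M_true for a known coefficient matrix, so least squares must
# recover M_true exactly (full-rank design).
make_exact_linear_fixture <- function(degree = 2, seed = 42,
                                      zero_constant = FALSE) {
  set.seed(seed)
  rgb <- matrix(runif(24 * 3, 0.05, 0.95), 24, 3)
  f <- endospectra::feature_count(degree)
  m_true <- matrix(runif(f * 401, -0.02, 0.05), f, 401)
  # keep reference spectra in [0, 1.5] and >= 0
  m_true <- abs(m_true) / (f * 1.2)
  if (zero_constant) m_true[1, ] <- 0
  x <- endospectra::expand_features(rgb, degree)
  ref <- x %*% m_true
  list(rgb = rgb, m_true = m_true, reference = ref, degree = degree)
}

random_boxes <- function(n, size = 100, seed = 1) {
  set.seed(seed)
  x0 <- runif(n, 0, size * 0.7)
  y0 <- runif(n, 0, size * 0.7)
  cbind(xmin = x0, ymin = y0,
        xmax = x0 + runif(n, 1, size * 0.3),
        ymax = y0 + runif(n, 1, size * 0.3))
}

# Exhaustive NMS oracle for small detection sets: among all maximal
# admissible subsets (no same-stage pair with IoU >= threshold), pick the
# one that is lexicographically first in the greedy visiting order
# (score descending, original index ascending).
nms_oracle <- function(dets, iou_threshold) {
  n <- nrow(dets)
  boxes <- as.matrix(dets[, c("xmin", "ymin", "xmax", "ymax")])
  iou <- endospectra::box_iou(boxes, boxes)
  conflict <- iou >= iou_threshold &
    outer(dets$stage, dets$stage, "==") & !diag(TRUE, n)
  admissible <- function(s) {
    length(s) < 2 || !any(conflict[s, s])
  }
  subsets <- lapply(0:(2^n - 1), function(m) which(bitwAnd(m, 2^(0:(n - 1))) > 0))
  adm <- Filter(admissible, subsets)
  maximal <- Filter(function(s) {
    !any(vapply(setdiff(seq_len(n), s),
                function(j) admissible(c(s, j)), logical(1)))
  }, adm)
  rank <- order(order(-dets$score, seq_len(n)))
  keys <- lapply(maximal, function(s) sort(rank[s]))
  best <- 1
  for (i in seq_along(keys)) {
    a <- keys[[i]]; b <- keys[[best]]
    l <- min(length(a), length(b))
    cmp <- if (l > 0) (a[1:l] - b[1:l])[which((a[1:l] - b[1:l]) != 0)[1]] else NA
    if (!is.na(cmp) && cmp < 0) best <- i
    else if (is.na(cmp) && length(a) > length(b)) best <- i
  }
  sort(maximal[[best]])
}

# variance-ratio separability statistic (between / within group scatter)
separability_ratio <- function(scores, labels) {
  gm <- colMeans(scores)
  b <- 0; w <- 0
  for (g in unique(labels)) {
    sg <- scores[labels == g, , drop = FALSE]
    b <- b + nrow(sg) * sum((colMeans(sg) - gm)^2)
    w <- w + sum(sweep(sg, 2, colMeans(sg))^2)
  }
  b / w
}
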