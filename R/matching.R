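#' Match default boxes to ground-truth lesions
#'
#' The detector's matching strategy has two steps. First, every ground-truth
#' box claims the default box with the largest IoU against it, so each
#' ground truth gets at least one positive match even when all overlaps are
#' below the threshold (ties break to the lowest default index; if a later
#' ground truth's argmax default is already claimed, it takes its best
#' unclaimed default). Second, every remaining default whose best IoU
#' against any ground truth reaches `threshold` (default 0.5) is reclassified
#' as a positive for that ground truth. All other defaults are negatives.
#'
#' @param defaults default-box set (matrix/data.frame, see [as_boxes()]).
#' @param gt_boxes ground-truth boxes (may have zero rows: all negatives).
#' @param gt_stages stage labels of the ground-truth boxes (never "normal").
#' @param threshold IoU threshold in (0, 1), default 0.5.
#' @return list of class `"match_assignment"`: `assignment` (integer per
#'   default: 0 = negative, j > 0 = matched to ground truth j),
#'   `n_positive`, `gt_stages`, `threshold`, `iou` (the defaults x gt IoU
#'   matrix).
#' @export
match_boxes <- function(defaults, gt_boxes, gt_stages = NULL, threshold = 0.5) {
  defaults <- as_boxes(defaults)
  if (nrow(defaults) == 0) stop("default-box set must not be empty")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (!is.null(gt_boxes) && NROW(gt_boxes) > 0) gt_boxes <- as_boxes(gt_boxes)
  n_gt <- if (is.null(gt_boxes)) 0 else nrow(gt_boxes)
  assignment <- integer(nrow(defaults))
  if (n_gt == 0) {
    return(structure(list(assignment = assignment, n_positive = 0L,
                          gt_stages = character(0), threshold = threshold,
                          iou = matrix(0, nrow(defaults), 0)),
                     class = "match_assignment"))
  }
  if (!is.null(gt_stages)) {
    assert_that(length(gt_stages) == n_gt, "one stage label per ground truth")
    assert_that(!any(gt_stages == "normal"),
                "'normal' cannot label a ground-truth lesion box")
    stage_severity(gt_stages)
  }
  iou <- box_iou(defaults, gt_boxes)

  ## step 1: argmax default per ground truth (claimed defaults excluded)
  for (j in seq_len(n_gt)) {
    cand <- iou[, j]
    cand[assignment > 0] <- -Inf
    assignment[which.max(cand)] <- j
  }
  ## step 2: threshold reclassification of the rest
  free <- which(assignment == 0)
  if (length(free)) {
    best <- apply(iou[free, , drop = FALSE], 1, which.max)
    best_iou <- iou[cbind(free, best)]
    hit <- best_iou >= threshold
    assignment[free[hit]] <- best[hit]
  }
  structure(list(assignment = assignment,
                 n_positive = sum(assignment > 0),
                 gt_stages = if (is.null(gt_stages)) NULL else gt_stages,
                 threshold = threshold, iou = iou),
            class = "match_assignment")
}

#' @export
print.match_assignment <- function(x, ...) {
  cat(sprintf("box matching: %d defaults, %d ground truths, %d positives (threshold %.2f)\n",
              length(x$assignment), ncol(x$iou), x$n_positive, x$threshold))
  invisible(x)
}

#' Hard-negative selection for the confidence loss
#'
#' Keeps the `ceiling(ratio * N)` unmatched defaults with the highest
#' per-box confidence loss (all of them if fewer exist), the usual 3:1
#' negative:positive balance. Ties keep the lowest default index, making the
#' selection deterministic.
#'
#' @param conf_loss per-default confidence-loss values.
#' @param match a [match_boxes()] assignment.
#' @param ratio negatives kept per positive (default 3).
#' @return integer indices of the selected negative defaults.
#' @export
select_hard_negatives <- function(conf_loss, match, ratio = 3) {
  if (ratio <= 0) stop("negative:positive ratio must be > 0")
  assert_that(length(conf_loss) == length(match$assignment),
              "one confidence loss per default box")
  neg <- which(match$assignment == 0)
  quota <- min(length(neg), ceiling(ratio * match$n_positive))
  if (quota == 0) return(integer(0))
  neg[order(-conf_loss[neg], neg)][seq_len(quota)]
}
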