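#' Multibox training loss
#'
#' The detector's training objective combines a confidence (classification)
#' term and a localization term, normalized by the number N of positive
#' default-box matches:
#' \deqn{L(x, c, l, g) = \frac{1}{N}\,(L_{conf}(x, c) + \alpha\,L_{loc}(x, l, g))}
#' When N = 0 the loss is defined as 0.
#'
#' `L_conf` is softmax cross-entropy: over the positives against their
#' matched stage, plus over the hard-mined negatives (see
#' [select_hard_negatives()]) against the background class. `L_loc` is the
#' smooth-L1 distance between predicted offsets and the encoded
#' ground-truth offsets (see [encode_offsets()]), summed over positives.
#'
#' Confidence columns are `(background, low_grade_dysplasia,
#' high_grade_dysplasia, invasive_cancer)`.
#'
#' @param conf n_defaults x 4 matrix of class scores (logits).
#' @param loc n_defaults x 4 matrix of predicted offsets.
#' @param match a [match_boxes()] assignment carrying `gt_stages`.
#' @param defaults the default boxes the predictions refer to.
#' @param gt_boxes the ground-truth boxes the assignment indexes.
#' @param alpha localization weight (default 1).
#' @param neg_ratio hard-negative ratio (default 3).
#' @param variances offset-coding scalers.
#' @return object of class `"multibox_loss"`: `total`, `conf`, `loc`
#'   (the unnormalized sums), `n_positive`.
#' @export
multibox_loss <- function(conf, loc, match, defaults, gt_boxes,
                          alpha = 1, neg_ratio = 3,
                          variances = c(0.1, 0.1, 0.2, 0.2)) {
  if (alpha < 0) stop("alpha must be >= 0")
  conf <- as.matrix(conf); loc <- as.matrix(loc)
  n <- length(match$assignment)
  assert_that(nrow(conf) == n && nrow(loc) == n,
              "conf and loc need one row per default box")
  assert_that(ncol(conf) == 4, "conf needs 4 columns (background + 3 stages)")
  assert_that(all(is.finite(conf)) && all(is.finite(loc)),
              "confidences and offsets must be finite")
  if (match$n_positive == 0) {
    return(multibox_total(0, 0, alpha, 0L))
  }
  defaults <- as_boxes(defaults)
  gt_boxes <- as_boxes(gt_boxes)
  pos <- which(match$assignment > 0)
  gt_idx <- match$assignment[pos]
  cls <- stage_class_column(match$gt_stages[gt_idx])

  logp <- log_softmax_rows(conf)
  conf_pos <- -logp[cbind(pos, cls)]
  neg_losses <- -logp[, 1]  # background column
  hard <- select_hard_negatives(neg_losses, match, neg_ratio)
  l_conf <- sum(conf_pos) + sum(neg_losses[hard])

  targets <- encode_offsets(gt_boxes[gt_idx, , drop = FALSE],
                            defaults[pos, , drop = FALSE], variances)
  l_loc <- sum(smooth_l1(loc[pos, , drop = FALSE] - targets))

  multibox_total(l_conf, l_loc, alpha, length(pos))
}

#' @rdname multibox_loss
#' @param conf_sum,loc_sum unnormalized confidence and localization sums.
#' @param n_positive the positive-match count N.
#' @return `multibox_total()`: the same `"multibox_loss"` structure from
#'   already-computed sums; `total` is `(conf_sum + alpha * loc_sum) / N`,
#'   or 0 when N = 0.
#' @export
multibox_total <- function(conf_sum, loc_sum, alpha = 1, n_positive) {
  if (alpha < 0) stop("alpha must be >= 0")
  assert_that(conf_sum >= 0 && loc_sum >= 0, "loss terms must be >= 0")
  total <- if (n_positive == 0) 0 else (conf_sum + alpha * loc_sum) / n_positive
  structure(list(total = total,
                 conf = if (n_positive == 0) 0 else conf_sum,
                 loc = if (n_positive == 0) 0 else loc_sum,
                 alpha = alpha, n_positive = as.integer(n_positive)),
            class = "multibox_loss")
}

#' @export
print.multibox_loss <- function(x, ...) {
  cat(sprintf("multibox loss: total %.6g (Lconf %.6g + %g * Lloc %.6g, N = %d)\n",
              x$total, x$conf, x$alpha, x$loc, x$n_positive))
  invisible(x)
}

## stage -> confidence column (background is column 1)
stage_class_column <- function(stage) {
  stage_severity(stage) # errors on unknown labels; normal maps to 1 below
  i <- match(stage, STAGES)
  if (any(i == 1)) stop("'normal' is the background class, not a box label")
  i
}

log_softmax_rows <- function(m) {
  mx <- apply(m, 1, max)
  z <- m - mx
  z - log(rowSums(exp(z)))
}

#' Smooth-L1 (Huber) penalty
#'
#' `0.5 x^2` for `|x| < 1`, `|x| - 0.5` otherwise; applied elementwise.
#'
#' @param x numeric vector or matrix.
#' @return elementwise penalties, same shape.
#' @export
smooth_l1 <- function(x) {
  ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
}
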