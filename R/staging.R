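#' Image-level stage call from detections
#'
#' The image is called `"normal"` when no detection reaches the score floor
#' (a normal esophagus shows no detection box at all); otherwise the call is
#' the stage of the highest-scoring surviving detection, with score ties
#' resolved toward the more severe stage.
#'
#' @param dets data.frame of detections (`stage`, `score`, box columns); may
#'   have zero rows.
#' @param score_floor minimum score for a detection to count (default 0.5).
#' @return a single stage label.
#' @export
image_level_call <- function(dets, score_floor = 0.5) {
  if (score_floor < 0 || score_floor > 1) stop("score_floor must be in [0, 1]")
  if (is.null(dets) || nrow(dets) == 0) return("normal")
  keep <- dets$score >= score_floor
  if (!any(keep)) return("normal")
  d <- dets[keep, , drop = FALSE]
  ord <- order(-d$score, -stage_severity(d$stage))
  d$stage[ord[1]]
}

#' Deterministic ground-truth-driven scorer stub
#'
#' The trained detection network is a pluggable contract: a scorer is any
#' function that takes one test-set record (list with `image`, `boxes`,
#' `stage`, `width`, `height`) and returns a detection data.frame
#' (`xmin, ymin, xmax, ymax, stage, score`). This stub stands in for the
#' network in pipeline tests. It reads the record's ground truth and emits a
#' detection at the true lesion box; with probability `confusion_rate` the
#' image-level outcome is flipped to one of the other three stages (uniformly)
#' — flipping a lesion image to "normal" drops its detection, flipping a
#' normal image plants a centered box of the confused stage.
#'
#' @param confusion_rate probability of mislabeling an image (default 0).
#' @param score score given to emitted detections (default 0.9).
#' @param seed RNG seed making the stub deterministic.
#' @return a scorer function `function(record) -> data.frame`.
#' @export
stub_scorer <- function(confusion_rate = 0, score = 0.9, seed = 1) {
  assert_that(confusion_rate >= 0 && confusion_rate <= 1,
              "confusion_rate must be in [0, 1]")
  rng_seed <- as.integer(seed)
  counter <- 0L
  function(record) {
    counter <<- counter + 1L
    true_stage <- record$stage
    called <- true_stage
    if (confusion_rate > 0) {
      ## per-record substream keyed on (seed, record index): deterministic
      ## regardless of evaluation order
      called <- with_seed(rng_seed * 100003L + counter, {
        if (runif(1) < confusion_rate) {
          sample(setdiff(STAGES, true_stage), 1)
        } else true_stage
      })
    }
    if (called == "normal") {
      return(empty_detections())
    }
    if (!is.null(record$boxes) && nrow(record$boxes) > 0) {
      b <- record$boxes[1, , drop = FALSE]
      box <- c(b$xmin, b$ymin, b$xmax, b$ymax)
    } else {
      w <- record$width; h <- record$height
      box <- c(w / 4, h / 4, 3 * w / 4, 3 * h / 4)
    }
    data.frame(xmin = box[1], ymin = box[2], xmax = box[3], ymax = box[4],
               stage = called, score = score)
  }
}

empty_detections <- function() {
  data.frame(xmin = numeric(0), ymin = numeric(0), xmax = numeric(0),
             ymax = numeric(0), stage = character(0), score = numeric(0))
}

#' Run a scorer over a test set and call each image's stage
#'
#' @param testset an [make_test_set()] test set (or any list of records).
#' @param scorer a scorer function (see [stub_scorer()] for the contract).
#' @param score_floor floor passed to [image_level_call()].
#' @param nms_threshold per-stage NMS threshold applied to the scorer output.
#' @return data.frame with one row per image: `image_id`, `truth`,
#'   `predicted`; detections attached as the `"detections"` attribute
#'   (a list of data.frames).
#' @export
detect_images <- function(testset, scorer, score_floor = 0.5,
                          nms_threshold = 0.45) {
  records <- testset$records %||% testset
  dets <- lapply(records, function(r) nms(scorer(r), nms_threshold))
  calls <- vapply(dets, image_level_call, character(1),
                  score_floor = score_floor)
  out <- data.frame(
    image_id = vapply(records, function(r) r$image_id, character(1)),
    truth = vapply(records, function(r) r$stage, character(1)),
    predicted = calls
  )
  attr(out, "detections") <- dets
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
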