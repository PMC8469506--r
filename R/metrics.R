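#' Four-stage confusion matrix
#'
#' Counts of (predicted, true) stage pairs: rows are the predicted stage,
#' columns the true stage, both in the canonical order normal, low-grade
#' dysplasia, high-grade dysplasia, invasive cancer. Column sums are the
#' per-stage test-set sizes.
#'
#' @param counts 4 x 4 matrix of nonnegative integers (rows = predicted).
#' @param modality optional tag, `"wli"` or `"nbi"`.
#' @param representation optional tag, `"rgb"` or `"spectrum"`.
#' @return object of class `"staging_confusion"` (a 4 x 4 integer matrix
#'   with dimnames and tag attributes).
#' @export
staging_confusion <- function(counts, modality = NA_character_,
                              representation = NA_character_) {
  counts <- as.matrix(counts)
  assert_that(all(dim(counts) == c(4, 4)), "confusion matrix must be 4 x 4")
  assert_that(all(is.finite(counts)) && all(counts >= 0) &&
                all(counts == round(counts)),
              "counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(predicted = STAGES, true = STAGES)
  structure(counts, modality = modality, representation = representation,
            class = c("staging_confusion", "matrix", "array"))
}

#' @rdname staging_confusion
#' @param truth,predicted character vectors of stage labels, equal length.
#' @return `confusion_from_calls()`: the tallied `staging_confusion`.
#' @export
confusion_from_calls <- function(truth, predicted,
                                 modality = NA_character_,
                                 representation = NA_character_) {
  assert_that(length(truth) > 0, "no (truth, predicted) pairs given")
  assert_that(length(truth) == length(predicted),
              "truth and predicted must have equal length")
  stage_severity(truth); stage_severity(predicted) # validate labels
  tab <- table(factor(predicted, levels = STAGES),
               factor(truth, levels = STAGES))
  staging_confusion(unclass(tab), modality, representation)
}

#' @export
print.staging_confusion <- function(x, ...) {
  tags <- c(attr(x, "modality"), attr(x, "representation"))
  tags <- tags[!is.na(tags)]
  cat("4-stage confusion matrix (rows = predicted, columns = true)",
      if (length(tags)) paste0("[", paste(tags, collapse = ", "), "]") else "",
      "\n")
  m <- unclass(x)
  attr(m, "modality") <- NULL
  attr(m, "representation") <- NULL
  print(m)
  cat("total:", sum(x), "\n")
  invisible(x)
}

check_nonempty <- function(m) {
  assert_that(inherits(m, "staging_confusion"), "not a staging_confusion")
  if (sum(m) == 0) stop("metrics are undefined for an empty confusion matrix")
  invisible(m)
}

#' Per-stage and overall staging metrics
#'
#' Sensitivity (per-stage recall) is the diagonal count over the stage's
#' column sum; precision is the diagonal over the stage's row sum; F1 is
#' their harmonic mean — all as percentages. Accuracy is the trace over the
#' total. Cohen's kappa is the chance-corrected agreement
#' `(p_o - p_e) / (1 - p_e)` with `p_e = sum(rowsum_i * colsum_i) / total^2`.
#'
#' All functions return *unrounded* values; a zero denominator yields `NA`
#' (an undefined metric, never reported as 0). Reporting rounds percentages
#' half-up to integers and kappa to two decimals (see [metrics_table()]).
#'
#' @param m a [staging_confusion] matrix.
#' @param stage a stage label.
#' @return a single numeric value (percent, or kappa in \[-1, 1\]); `NA` if
#'   undefined.
#' @export
stage_sensitivity <- function(m, stage) {
  check_nonempty(m)
  i <- stage_severity(stage)
  denom <- sum(m[, i])
  if (denom == 0) return(NA_real_)
  100 * m[i, i] / denom
}

#' @rdname stage_sensitivity
#' @export
stage_precision <- function(m, stage) {
  check_nonempty(m)
  i <- stage_severity(stage)
  denom <- sum(m[i, ])
  if (denom == 0) return(NA_real_)
  100 * m[i, i] / denom
}

#' @rdname stage_sensitivity
#' @export
stage_f1 <- function(m, stage) {
  s <- stage_sensitivity(m, stage)
  p <- stage_precision(m, stage)
  if (is.na(s) || is.na(p)) return(NA_real_)
  if (s + p == 0) return(NA_real_)
  2 * s * p / (s + p)
}

#' @rdname stage_sensitivity
#' @export
overall_accuracy <- function(m) {
  check_nonempty(m)
  100 * sum(diag(m)) / sum(m)
}

#' @rdname stage_sensitivity
#' @export
cohen_kappa <- function(m) {
  check_nonempty(m)
  total <- sum(m)
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Assemble the full metrics table for a confusion matrix
#'
#' One row per stage with sensitivity, precision and F1 (both unrounded and
#' rounded half-up to integer percent), plus overall accuracy and Cohen's
#' kappa (rounded to 2 decimals for reporting).
#'
#' @param m a [staging_confusion] matrix.
#' @return object of class `"staging_metrics"`: list with `per_stage`
#'   (data.frame), `accuracy`, `kappa` and their `_rounded` companions,
#'   and the source matrix tags.
#' @export
metrics_table <- function(m) {
  check_nonempty(m)
  per <- data.frame(
    stage = STAGES,
    sensitivity = vapply(STAGES, function(s) stage_sensitivity(m, s), 1),
    precision = vapply(STAGES, function(s) stage_precision(m, s), 1),
    f1 = vapply(STAGES, function(s) stage_f1(m, s), 1),
    row.names = NULL
  )
  per$sensitivity_pct <- round_half_up(per$sensitivity)
  per$precision_pct <- round_half_up(per$precision)
  per$f1_pct <- round_half_up(per$f1)
  structure(list(
    per_stage = per,
    accuracy = overall_accuracy(m),
    accuracy_pct = round_half_up(overall_accuracy(m)),
    kappa = cohen_kappa(m),
    kappa_2dp = round_half_up(cohen_kappa(m), 2),
    total = sum(m),
    modality = attr(m, "modality"),
    representation = attr(m, "representation")
  ), class = "staging_metrics")
}

#' @export
print.staging_metrics <- function(x, ...) {
  tags <- c(x$modality, x$representation)
  tags <- tags[!is.na(tags)]
  cat("staging metrics",
      if (length(tags)) paste0("[", paste(tags, collapse = " "), "]") else "",
      sprintf("(n = %d)\n", x$total))
  tab <- x$per_stage[, c("stage", "sensitivity_pct", "precision_pct", "f1_pct")]
  names(tab) <- c("stage", "sensitivity(%)", "precision(%)", "F1(%)")
  print(tab, row.names = FALSE)
  cat(sprintf("accuracy: %s%%   kappa: %s\n",
              format(x$accuracy_pct), format(x$kappa_2dp)))
  invisible(x)
}

#' @rdname metrics_table
#' @param x a `staging_metrics` object.
#' @param ... unused.
#' @return `as.data.frame()`: the per-stage table with accuracy/kappa
#'   attached as columns (repeated), convenient for CSV export.
#' @export
as.data.frame.staging_metrics <- function(x, ...) {
  df <- x$per_stage
  df$accuracy_pct <- x$accuracy_pct
  df$kappa <- x$kappa_2dp
  df
}

#' Bundled reference confusion matrices
#'
#' Four 4-stage confusion matrices from a published clinical evaluation of
#' esophageal-lesion staging on white-light (WLI) and narrow-band (NBI)
#' endoscopic test images, each modality scored once on plain RGB images and
#' once on reconstructed spectral data. They are shipped as example data and
#' as the reference surface for the evaluation module's tests.
#'
#' Note: the NBI-spectrum matrix is reproduced exactly as printed in its
#' source, whose cells sum to 150 although the test set is stated as 153
#' images; metrics derived from that matrix (other than its normal column)
#' are therefore not comparable to the source's reported values.
#'
#' @param which one of `"wli_rgb"`, `"nbi_rgb"`, `"wli_spectrum"`,
#'   `"nbi_spectrum"`, or `"all"` (default) for a named list.
#' @return a [staging_confusion], or a named list of all four.
#' @export
clinical_confusions <- function(which = c("all", "wli_rgb", "nbi_rgb",
                                          "wli_spectrum", "nbi_spectrum")) {
  which <- match.arg(which)
  load1 <- function(name) {
    path <- system.file("extdata", paste0("confusion_", name, ".csv"),
                        package = "endospectra", mustWork = TRUE)
    parts <- strsplit(name, "_")[[1]]
    read_confusion_csv(path, modality = parts[1], representation = parts[2])
  }
  if (which == "all") {
    nm <- c("wli_rgb", "nbi_rgb", "wli_spectrum", "nbi_spectrum")
    return(setNames(lapply(nm, load1), nm))
  }
  load1(which)
}

#' Read / write a confusion matrix as CSV
#'
#' The CSV is a 4 x 4 integer grid with a header row of true-stage names and
#' a leading `predicted` column of predicted-stage names.
#'
#' @param path file path.
#' @param modality,representation optional tags attached to the matrix.
#' @return the [staging_confusion] (reader) or `path` invisibly (writer).
#' @export
read_confusion_csv <- function(path, modality = NA_character_,
                               representation = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  assert_that(identical(df[[1]], STAGES),
              "confusion CSV rows must be the four stages in canonical order")
  m <- as.matrix(df[, STAGES])
  staging_confusion(m, modality, representation)
}

#' @rdname read_confusion_csv
#' @param m a [staging_confusion].
#' @export
write_confusion_csv <- function(m, path) {
  check_nonempty(m)
  df <- data.frame(predicted = STAGES, unclass(m)[, , drop = FALSE],
                   check.names = FALSE)
  colnames(df) <- c("predicted", STAGES)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
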