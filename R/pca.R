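#' Principal-component basis for reflectance spectra
#'
#' Reduces 401-band spectra to a few principal components (default k = 3,
#' the reduction used before stage classification). Spectra are mean-centered
#' but not variance-scaled: all bands share reflectance units. The sample
#' covariance uses 1/(n-1). Loadings carry a fixed sign convention — the
#' largest-magnitude element of each loading is positive — so bases are
#' reproducible across platforms and input orderings.
#'
#' Internally the decomposition is computed by [stats::prcomp()].
#'
#' @param x n x 401 matrix of spectra (rows = samples), or a
#'   [spectral_cube] (pixels become samples).
#' @param k number of components to keep (default 3); needs `n >= k + 1`.
#' @return object of class `"spectral_pca"`: `mean` (401), `loadings`
#'   (401 x k, orthonormal), `explained_variance` (k, descending),
#'   `all_variances` (every eigenvalue, for variance bookkeeping), `k`, `n`.
#' @seealso [predict.spectral_pca()], [reconstruct()]
#' @export
spectral_pca <- function(x, k = 3) {
  if (inherits(x, "spectral_cube")) x <- as.matrix(x)
  x <- as.matrix(x)
  assert_that(ncol(x) == N_BANDS,
              sprintf("spectra must have %d bands", N_BANDS))
  n <- nrow(x)
  if (k < 1 || k > n - 1) {
    stop(sprintf("k must be between 1 and n - 1 = %d", n - 1))
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(k)
  load <- pr$rotation[, keep, drop = FALSE]
  ## sign convention: largest-|.| element of each loading positive
  for (j in keep) {
    m <- which.max(abs(load[, j]))
    if (load[m, j] < 0) load[, j] <- -load[, j]
  }
  structure(list(
    mean = as.numeric(pr$center),
    loadings = unname(load),
    explained_variance = unname(pr$sdev[keep]^2),
    all_variances = unname(pr$sdev^2),
    k = as.integer(k),
    n = n
  ), class = "spectral_pca")
}

#' Project spectra onto a fitted principal-component basis
#'
#' @param object a [spectral_pca] basis.
#' @param newdata a length-401 spectrum, n x 401 matrix, or [spectral_cube].
#' @param ... unused.
#' @return n x k score matrix (columns `pc1..pck`).
#' @export
predict.spectral_pca <- function(object, newdata, ...) {
  if (inherits(newdata, "spectral_cube")) newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$mean)) {
    stop("wavelength grid mismatch: spectra have ", ncol(newdata),
         " bands, basis expects ", length(object$mean))
  }
  scores <- sweep(newdata, 2, object$mean) %*% object$loadings
  colnames(scores) <- paste0("pc", seq_len(object$k))
  scores
}

#' Map principal-component scores back to spectra
#'
#' Returns `mean + scores %*% t(loadings)`; exact for data on the fitted
#' subspace, the orthogonal projection otherwise. No clipping is applied.
#'
#' @param object a [spectral_pca] basis.
#' @param scores length-k vector or n x k matrix of scores.
#' @return n x 401 matrix of spectra (a vector for single-score input).
#' @export
reconstruct <- function(object, scores) {
  UseMethod("reconstruct")
}

#' @export
reconstruct.spectral_pca <- function(object, scores) {
  single <- is.null(dim(scores))
  if (single) scores <- matrix(scores, nrow = 1)
  if (ncol(scores) != object$k) {
    stop("scores must have k = ", object$k, " columns")
  }
  out <- sweep(scores %*% t(object$loadings), 2, object$mean, "+")
  if (single) as.numeric(out) else out
}

#' @export
print.spectral_pca <- function(x, ...) {
  tot <- sum(x$all_variances)
  cat(sprintf("principal-component basis: k = %d (fit on %d spectra)\n",
              x$k, x$n))
  cat(sprintf("  explained variance: %s (%.1f%% of total)\n",
              paste(signif(x$explained_variance, 4), collapse = ", "),
              100 * sum(x$explained_variance) / max(tot, .Machine$double.xmin)))
  invisible(x)
}

#' Write PCA scores with stage labels to CSV
#'
#' Columns `sample_id, stage, pc1..pck`.
#'
#' @param scores n x k score matrix.
#' @param stage character vector of stage labels, length n.
#' @param path output file.
#' @param sample_id optional ids (default `s1..sn`).
#' @export
write_scores_csv <- function(scores, stage, path, sample_id = NULL) {
  n <- nrow(scores)
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(n))
  stage_severity(stage) # validates labels
  df <- data.frame(sample_id = sample_id, stage = stage, scores,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
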