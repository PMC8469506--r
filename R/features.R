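#' Polynomial feature expansion of linear RGB
#'
#' The conversion regression maps an expanded RGB feature vector to 401
#' reflectance bands. Features are all monomials `r^a * g^b * b^c` with
#' `a + b + c <= degree`, constant term first, then ordered by total degree
#' and, within a degree, by descending exponent of r then g (so degree 2 is
#' `r^2, rg, rb, g^2, gb, b^2`). Degree 2 gives 10 features, degree 3 gives
#' 20 (`choose(degree + 3, 3)` in general).
#'
#' @param rgb numeric length-3 vector or n x 3 matrix of *linear* RGB values.
#' @param degree integer >= 1, polynomial degree.
#' @return n x F feature matrix (a 1 x F matrix for a single triplet), with
#'   column names naming the monomials.
#' @examples
#' expand_features(c(0.2, 0.4, 0.6), degree = 1) # 1, r, g, b
#' ncol(expand_features(c(0, 0, 0), degree = 3)) # 20
#' @export
expand_features <- function(rgb, degree = 3) {
  if (degree < 1 || degree != as.integer(degree)) {
    stop("polynomial degree must be an integer >= 1")
  }
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  assert_that(ncol(rgb) == 3, "rgb must have 3 columns")
  assert_that(all(is.finite(rgb)), "rgb values must be finite")
  ex <- monomial_exponents(degree)
  out <- matrix(1, nrow = nrow(rgb), ncol = nrow(ex))
  for (k in seq_len(nrow(ex))) {
    e <- ex[k, ]
    v <- rep(1, nrow(rgb))
    if (e[1] > 0) v <- v * rgb[, 1]^e[1]
    if (e[2] > 0) v <- v * rgb[, 2]^e[2]
    if (e[3] > 0) v <- v * rgb[, 3]^e[3]
    out[, k] <- v
  }
  colnames(out) <- monomial_names(ex)
  out
}

#' @rdname expand_features
#' @return `feature_count()`: the number of monomials for a degree.
#' @export
feature_count <- function(degree) {
  if (degree < 1) stop("polynomial degree must be an integer >= 1")
  choose(degree + 3, 3)
}

## exponent table: rows (a, b, c), constant first, grouped by total degree,
## within a degree ordered by a desc then b desc
monomial_exponents <- function(degree) {
  rows <- list()
  for (d in 0:degree) {
    for (a in d:0) {
      for (b in (d - a):0) {
        rows[[length(rows) + 1]] <- c(a, b, d - a - b)
      }
    }
  }
  do.call(rbind, rows)
}

monomial_names <- function(ex) {
  apply(ex, 1, function(e) {
    if (all(e == 0)) return("1")
    parts <- c("r", "g", "b")
    paste0(mapply(function(ch, p) {
      if (p == 0) "" else if (p == 1) ch else paste0(ch, p)
    }, parts, e), collapse = "")
  })
}
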