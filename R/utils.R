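## Internal helpers shared across modules.

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Reporting convention for all percentage and kappa values: ties round up
#' (83.5 -> 84), unlike base [round()]'s round-half-even. Internal metric
#' functions return unrounded values; tables report with this rule.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return rounded numeric vector (`NA` passes through).
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## md5 of an arbitrary R object, used to stamp artifacts with the identity
## of the calibration that produced them.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

## stopifnot with a custom message
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
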