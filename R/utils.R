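#' Round half away from zero
#'
#' Fixed-convention rounding used wherever fractional slice positions or
#' 8-bit intensities are quantised: halves round away from zero (2.5 -> 3,
#' -2.5 -> -3), unlike base \code{round()}'s round-half-even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
roundHalfAway <- function(x) {
  trunc(x) + trunc(2 * (x - trunc(x)))
}

#' @keywords internal
#' @noRd
clip01 <- function(x) pmin(pmax(x, 0), 1)

## Derive a child seed from a parent seed and a stream label without
## consuming the caller's RNG state. Kept below 2^31 - 1.
#' @keywords internal
#' @noRd
childSeed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.double(seed) * 48271 + h) %% 2147483563) + 1L
}

## Evaluate expr with a local RNG seeded by `seed`; restores global state.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @keywords internal
#' @noRd
isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) > 0 && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}
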