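#' @keywords internal
"_PACKAGE"

## Run code under a fixed RNG state, restoring the caller's state afterwards.
## All stochastic functions in the package route their `seed` argument here so
## that results are reproducible without clobbering the session RNG.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  code
}

## Deterministic child seeds so that independent sub-simulations driven by one
## user seed do not reuse the same stream. Kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  (as.integer(seed) * 7919L + as.integer(k) * 104729L) %% 2147483629L
}

#' Spearman-Brown prophecy correction
#'
#' Predicts full-length reliability from a half-length correlation:
#' `2 * r / (1 + r)`.
#'
#' @param r A correlation in `[-1, 1]` (typically a mean split-half
#'   correlation). `r = -1` is a pole of the formula and raises an error.
#' @return The corrected reliability, same length as `r`.
#' @examples
#' spearman_brown(0.5)  # 0.667
#' @export
spearman_brown <- function(r) {
  stopifnot(is.numeric(r), all(is.finite(r)), all(r >= -1), all(r <= 1))
  if (any(r == -1)) {
    stop("Spearman-Brown correction is undefined at r = -1")
  }
  2 * r / (1 + r)
}
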