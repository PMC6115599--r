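#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (half-up), the
#' convention every printed percentage in the summary tables follows.
#' Base R's `round()` rounds half to even, which would print 0.125 as 0.12.
#'
#' @param x Numeric vector (assumed nonnegative in this package's use).
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @examples
#' round_half_up(2.345, 2) # 2.35
#' round(2.345, 2)         # 2.34 (banker's rounding)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count, rounded half-up to two decimals
#'
#' The percentage operation used in every sentiment-distribution table:
#' `100 * count / total`, rounded half-up to two decimal places.
#'
#' @param count Numeric vector of counts.
#' @param total Positive total.
#' @return Numeric vector of percentages on the 0-100 scale.
#' @examples
#' percent_of(18362, 27070) # 67.83
#' @export
percent_of <- function(count, total) {
  if (length(total) != 1 || is.na(total) || total <= 0) {
    stop("total must be a single positive number")
  }
  round_half_up(100 * count / total, 2)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
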