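#' Discretize a rating into a sentiment label
#'
#' Maps a 1-5 rating to a three-valued sentiment label using the fixed
#' partition of the rating scale: a rating of at least 4 is positive, at
#' least 3 but below 4 is neutral, and below 3 is negative. The same rule
#' serves review-level ratings and product-level average ratings, so
#' non-integer ratings are accepted.
#'
#' @param rating Numeric vector of ratings in \[1, 5\]. `NA` passes through
#'   as `NA` (a missing aspect rating stays missing).
#' @return Character vector of `"positive"`, `"neutral"`, `"negative"`.
#' @examples
#' discretize_rating(c(4, 3.99, 3, 2.99, 1))
#' @export
discretize_rating <- function(rating) {
  ok <- !is.na(rating)
  if (any(rating[ok] < 1 | rating[ok] > 5)) {
    bad <- rating[ok][which(rating[ok] < 1 | rating[ok] > 5)[1]]
    stop("rating ", bad, " outside [1, 5]")
  }
  out <- rep(NA_character_, length(rating))
  r <- rating[ok]
  out[ok] <- ifelse(r >= 4, "positive", ifelse(r >= 3, "neutral", "negative"))
  out
}

#' Discretize all ratings of a corpus
#'
#' Applies [discretize_rating()] to the overall rating and each of the four
#' aspect ratings of every review. Missing aspect ratings stay missing.
#'
#' @param corpus A corpus tibble.
#' @return A tibble with one row per review and columns `overall`,
#'   `flavor_accuracy`, `value`, `cloud_production`, `throat_hit`, each a
#'   sentiment label (or `NA` for a missing aspect rating).
#' @export
discretize_reviews <- function(corpus) {
  out <- tibble::tibble(overall = discretize_rating(corpus$overall_rating))
  for (a in ASPECTS) out[[a]] <- discretize_rating(corpus[[a]])
  out[, c("overall", ASPECTS)]
}

#' Keep only reviews with all four aspect ratings present
#'
#' Influential-aspect analysis requires complete aspect ratings; this filter
#' drops any review missing one or more of them. Order is preserved and the
#' operation is idempotent.
#'
#' @param corpus A corpus tibble.
#' @return The filtered corpus tibble.
#' @export
filter_complete <- function(corpus) {
  keep <- stats::complete.cases(as.data.frame(corpus[, ASPECTS]))
  corpus[keep, , drop = FALSE]
}

#' Build the labeled dataset for tree construction
#'
#' Filters to complete reviews and discretizes, yielding the 4-aspect-label
#' plus overall-label table that [build_id3()] consumes. Aspect columns are
#' in the canonical order `flavor_accuracy`, `value`, `cloud_production`,
#' `throat_hit`.
#'
#' @param corpus A corpus tibble.
#' @return A tibble with columns `flavor_accuracy`, `value`,
#'   `cloud_production`, `throat_hit`, `overall`, all sentiment labels.
#' @export
labeled_dataset <- function(corpus) {
  cc <- filter_complete(corpus)
  if (nrow(cc) == 0) stop("no complete reviews after filtering")
  labs <- discretize_reviews(cc)
  labs[, c(ASPECTS, "overall")]
}
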