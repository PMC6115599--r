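# Canonical vocabularies shared across the package.
ASPECTS <- c("flavor_accuracy", "value", "cloud_production", "throat_hit")
ASPECT_CODES <- c(
  flavor_accuracy = "f", value = "v", cloud_production = "c", throat_hit = "t"
)
FLAVORS <- c(
  "sweet", "fruity", "rich", "creamy", "spiced",
  "tobacco", "cool", "nutty", "coffee"
)
LABELS <- c("positive", "neutral", "negative")
LABEL_CODES <- c(positive = 1L, neutral = 0L, negative = -1L)

# Column order of the corpus CSV / JSON-lines interchange format.
CORPUS_COLS <- c(
  "product_id", "flavor_category", "overall_rating",
  "flavor_accuracy", "throat_hit", "value", "cloud_production",
  "text", "date"
)

#' Canonical vocabularies
#'
#' The four rated aspects of an e-liquid (in the fixed canonical order used
#' throughout the package), the nine flavor categories, and the three
#' sentiment labels.
#'
#' @return A character vector.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
aspect_names <- function() ASPECTS

#' @rdname vocabularies
#' @export
flavor_categories <- function() FLAVORS

#' @rdname vocabularies
#' @export
sentiment_levels <- function() LABELS

#' Numeric codes for sentiment labels
#'
#' Sentiment labels carry canonical numeric codes used in serialized output
#' (decision trees, reports): 1 = positive, 0 = neutral, -1 = negative.
#'
#' @param label Character vector of labels (`"positive"`, `"neutral"`,
#'   `"negative"`).
#' @param code Integer vector of codes (1, 0, -1).
#' @return `sentiment_code()` returns an integer vector; `sentiment_from_code()`
#'   returns a character vector of labels.
#' @examples
#' sentiment_code(c("positive", "negative"))
#' sentiment_from_code(c(1, 0, -1))
#' @export
sentiment_code <- function(label) {
  out <- unname(LABEL_CODES[match(label, LABELS)])
  if (anyNA(out) && !anyNA(label)) stop("unknown sentiment label")
  out
}

#' @rdname sentiment_code
#' @export
sentiment_from_code <- function(code) {
  LABELS[match(as.integer(code), LABEL_CODES)]
}
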