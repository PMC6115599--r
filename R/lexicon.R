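#' Sentiment lexicons
#'
#' A sentiment lexicon maps lowercase adjectives to a polarity, `"positive"`
#' or `"negative"`. The package bundles a seed lexicon of roughly 120
#' adjectives covering the opinion vocabulary common in e-liquid reviews;
#' any larger dictionary can be substituted via `read_lexicon()` from a TSV
#' of `word<TAB>polarity` lines.
#'
#' @param path Path to a two-column TSV (`word`, `polarity`), no header;
#'   lines starting with `#` are ignored.
#' @return A named character vector: names are lowercase words, values
#'   `"positive"` or `"negative"`.
#' @export
read_lexicon <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c("word", "polarity"), col_types = "cc",
    comment = "#", progress = FALSE
  )
  df$word <- tolower(df$word)
  if (!all(df$polarity %in% c("positive", "negative"))) {
    stop("lexicon polarity must be 'positive' or 'negative'")
  }
  dup <- unique(df$word[duplicated(df$word)])
  conflicting <- dup[vapply(
    dup, function(w) length(unique(df$polarity[df$word == w])) > 1, logical(1)
  )]
  if (length(conflicting)) {
    stop("word with both polarities in lexicon: ", conflicting[1])
  }
  df <- df[!duplicated(df$word), ]
  stats::setNames(df$polarity, df$word)
}

#' @rdname read_lexicon
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "sentiment_lexicon.tsv",
                           package = "vapemine"))
}

#' Look up the polarity of a sentiment word
#'
#' Case-insensitive exact lookup; a word absent from the lexicon has
#' polarity `"unknown"`.
#'
#' @param word Character vector of words.
#' @param lexicon A lexicon from [read_lexicon()] / [default_lexicon()].
#' @return Character vector of `"positive"`, `"negative"`, `"unknown"`.
#' @examples
#' polarity(c("great", "harsh", "purple"))
#' @export
polarity <- function(word, lexicon = default_lexicon()) {
  p <- unname(lexicon[tolower(word)])
  p[is.na(p)] <- "unknown"
  p
}

#' Aspect keyword configuration
#'
#' Maps each of the four aspect categories to the nouns (one or two tokens)
#' that signal it in review text: flavor accuracy is signalled by "flavor",
#' "juice", "vape", "taste", "aftertaste"; value by "price", "value",
#' "quality"; cloud production by "vapor production", "vapor", "cloud
#' production"; throat hit by "throat", "hit", "throat hit". The bundled
#' configuration can be replaced by `read_aspect_keywords()` from a JSON
#' object of category -> term-list.
#'
#' @param path Path to a JSON file mapping the four aspect names to arrays
#'   of lowercase terms.
#' @return A named list of character vectors, names being the four aspect
#'   names in canonical order.
#' @export
read_aspect_keywords <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(ASPECTS, names(cfg))
  if (length(missing)) {
    stop("aspect keyword config missing categories: ",
         paste(missing, collapse = ", "))
  }
  cfg <- lapply(cfg[ASPECTS], function(x) tolower(as.character(x)))
  all_terms <- unlist(cfg, use.names = FALSE)
  dup <- unique(all_terms[duplicated(all_terms)])
  if (length(dup)) stop("keyword term in two categories: ", dup[1])
  cfg
}

#' @rdname read_aspect_keywords
#' @export
default_aspect_keywords <- function() {
  read_aspect_keywords(system.file("extdata", "aspect_keywords.json",
                                   package = "vapemine"))
}

# All unigram tokens occurring in keyword terms (used as the candidate set
# when extracting from a single sentence without corpus-level TF counts).
keyword_unigrams <- function(keywords = default_aspect_keywords()) {
  unique(unlist(strsplit(unlist(keywords, use.names = FALSE), " ")))
}

keyword_bigrams <- function(keywords = default_aspect_keywords()) {
  terms <- unlist(keywords, use.names = FALSE)
  terms[grepl(" ", terms)]
}

#' Map a noun span to its aspect category
#'
#' Looks up a one- or two-token lowercase span in the keyword
#' configuration. A two-token span matches a bigram entry as a whole
#' ("throat hit" matches the bigram, not "throat" and "hit" separately).
#'
#' @param span Lowercase term, e.g. `"price"` or `"throat hit"`.
#' @param keywords Keyword configuration from [default_aspect_keywords()].
#' @return The aspect category name, or `"uncategorized"`.
#' @examples
#' match_aspect_category("throat hit")
#' match_aspect_category("waffles")
#' @export
match_aspect_category <- function(span, keywords = default_aspect_keywords()) {
  hit <- names(keywords)[vapply(keywords, function(terms) span %in% terms,
                                logical(1))]
  if (length(hit)) hit[1] else "uncategorized"
}
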