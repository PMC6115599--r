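#' Candidate aspect nouns by corpus-wide term frequency
#'
#' Counts every noun-token occurrence in the corpus (lowercased) and keeps
#' the nouns whose term frequency is strictly greater than the threshold. A
#' noun occurring exactly `tf_threshold` times is excluded.
#'
#' @param corpus A corpus tibble, or `NULL` if `parsed` is supplied.
#' @param tf_threshold Strict frequency threshold (default 20).
#' @param lexicon Lexicon passed to the parser.
#' @param parsed Optional precomputed list of [parse_text()] results, one
#'   element per review (avoids reparsing).
#' @return A tibble (`noun`, `n`) sorted by descending frequency, ties
#'   broken lexicographically.
#' @export
candidate_aspect_nouns <- function(corpus, tf_threshold = 20,
                                   lexicon = default_lexicon(),
                                   parsed = NULL) {
  if (is.null(parsed)) {
    parsed <- lapply(corpus$text, parse_text, lexicon = lexicon)
  }
  nouns <- unlist(lapply(parsed, function(sentences) {
    unlist(lapply(sentences, function(s) s$tokens$lower[s$tokens$tag == "NN"]),
           use.names = FALSE)
  }), use.names = FALSE)
  if (is.null(nouns) || length(nouns) == 0) {
    return(tibble::tibble(noun = character(), n = integer()))
  }
  tab <- table(nouns)
  out <- tibble::tibble(noun = names(tab), n = as.integer(tab))
  out <- out[out$n > tf_threshold, ]
  out[order(-out$n, out$noun), ]
}

# Prefer a keyword bigram containing the head noun; direction = "forward"
# looks at (head, head+1) first (amod heads are the first noun of a
# compound), "backward" at (head-1, head) first (copular subjects are the
# last).
resolve_term <- function(tokens, idx, bigrams, direction = "forward") {
  n <- nrow(tokens)
  fwd <- if (idx < n && tokens$tag[idx + 1] == "NN") {
    paste(tokens$lower[idx], tokens$lower[idx + 1])
  }
  bwd <- if (idx > 1 && tokens$tag[idx - 1] == "NN") {
    paste(tokens$lower[idx - 1], tokens$lower[idx])
  }
  ordered <- if (direction == "forward") c(fwd, bwd) else c(bwd, fwd)
  for (bg in ordered) if (!is.null(bg) && bg %in% bigrams) return(bg)
  tokens$lower[idx]
}

#' Extract opinion pairs from one parsed sentence
#'
#' Emits an (aspect term, sentiment adjective) pair for each adjectival
#' modifier whose head noun is a candidate, and for each copular predicate
#' adjective whose subject noun is a candidate. If the noun sits inside a
#' keyword bigram ("throat hit", "cloud production", "vapor production"),
#' the bigram becomes the aspect term. Polarity is a lexicon lookup, else
#' `"unknown"`; the category comes from [match_aspect_category()]. With
#' `negation = TRUE` a direct "not"/"never" before the adjective (or
#' between copula and adjective) inverts a known polarity; this is an
#' optional extension, off by default.
#'
#' @param sentence One parsed sentence from [parse_text()].
#' @param candidates Character vector of candidate aspect nouns (unigrams),
#'   e.g. from [candidate_aspect_nouns()].
#' @param lexicon Sentiment lexicon.
#' @param keywords Aspect keyword configuration.
#' @param negation Logical; invert polarity under a direct negator.
#' @return A tibble (`aspect_term`, `sentiment_word`, `polarity`,
#'   `category`), in token order.
#' @examples
#' s <- parse_text("A great flavor.")[[1]]
#' extract_pairs(s, candidates = "flavor")
#' @export
extract_pairs <- function(sentence, candidates,
                          lexicon = default_lexicon(),
                          keywords = default_aspect_keywords(),
                          negation = FALSE) {
  toks <- sentence$tokens
  deps <- sentence$deps
  bigrams <- keyword_bigrams(keywords)
  rows <- list()
  emit <- function(noun_idx, adj_idx, direction) {
    noun <- toks$lower[noun_idx]
    if (!(noun %in% candidates)) return()
    term <- resolve_term(toks, noun_idx, bigrams, direction)
    adj <- toks$lower[adj_idx]
    pol <- polarity(adj, lexicon)
    if (negation && pol != "unknown" && is_negated(toks, adj_idx)) {
      pol <- if (pol == "positive") "negative" else "positive"
    }
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      aspect_term = term, sentiment_word = adj, polarity = pol,
      category = match_aspect_category(term, keywords),
      .pos = noun_idx
    )
  }
  amod <- deps[deps$relation == "amod", ]
  for (k in seq_len(nrow(amod))) emit(amod$head[k], amod$dep[k], "forward")
  nsubj <- deps[deps$relation == "nsubj", ]
  for (k in seq_len(nrow(nsubj))) emit(nsubj$dep[k], nsubj$head[k], "backward")
  if (length(rows) == 0) {
    return(tibble::tibble(
      aspect_term = character(), sentiment_word = character(),
      polarity = character(), category = character()
    ))
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$.pos), ]
  out$.pos <- NULL
  out
}

is_negated <- function(toks, adj_idx) {
  i <- adj_idx - 1L
  while (i >= 1 && toks$tag[i] == "RB") {
    if (toks$lower[i] %in% c("not", "never")) return(TRUE)
    i <- i - 1L
  }
  FALSE
}

#' Extract opinion pairs from a whole corpus
#'
#' The full extraction pipeline: parse every review, select candidate
#' aspect nouns by corpus-wide term frequency, extract pairs sentence by
#' sentence, and attach each pair's review index for provenance.
#' Deterministic given the parser and inputs.
#'
#' @param corpus A corpus tibble.
#' @param lexicon Sentiment lexicon.
#' @param keywords Aspect keyword configuration.
#' @param tf_threshold Strict term-frequency threshold for candidate nouns.
#' @param negation Logical; see [extract_pairs()].
#' @return A tibble (`review_index`, `aspect_term`, `sentiment_word`,
#'   `polarity`, `category`).
#' @export
extract_corpus <- function(corpus,
                           lexicon = default_lexicon(),
                           keywords = default_aspect_keywords(),
                           tf_threshold = 20,
                           negation = FALSE) {
  parsed <- lapply(corpus$text, parse_text, lexicon = lexicon)
  cand <- candidate_aspect_nouns(NULL, tf_threshold, lexicon, parsed = parsed)
  candidates <- cand$noun
  per_review <- lapply(seq_along(parsed), function(i) {
    pairs <- dplyr::bind_rows(lapply(
      parsed[[i]], extract_pairs,
      candidates = candidates, lexicon = lexicon, keywords = keywords,
      negation = negation
    ))
    if (nrow(pairs)) pairs$review_index <- i
    pairs
  })
  out <- dplyr::bind_rows(per_review)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      review_index = integer(), aspect_term = character(),
      sentiment_word = character(), polarity = character(),
      category = character()
    ))
  }
  out[, c("review_index", "aspect_term", "sentiment_word", "polarity",
          "category")]
}
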