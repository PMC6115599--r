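#' Parse review text with the bundled rule parser
#'
#' A deterministic, dictionary-based sentence splitter, tokenizer,
#' part-of-speech tagger and dependency approximator for the two dependency
#' patterns that opinion extraction uses:
#'
#' * adjectival modifier (`amod`): an adjective immediately preceding a
#'   noun, as in "a *great* *flavor*";
#' * copular predication (`nsubj` + `cop`): a predicate adjective after a
#'   copula whose subject is the nearest preceding noun, as in "the
#'   *flavor* is *great*".
#'
#' Tags are Penn-style (`DT`, `PRP`, `JJ`, `NN`, `RB`, `VB`, `IN`, `CC`,
#' `CD`); words outside every dictionary default to `NN`. The parser is
#' intentionally small: it covers the closed vocabulary of the synthetic
#' templates perfectly and degrades gracefully on free text. A statistical
#' parser can replace it by producing the same sentence structure.
#'
#' @param text A single review text (may contain several sentences).
#' @param lexicon Sentiment lexicon; its words are tagged as adjectives.
#' @return A list of parsed sentences. Each sentence is a list with
#'   `tokens` (tibble: `surface`, `lower`, `tag`) and `deps` (tibble:
#'   `relation` in `amod`/`nsubj`/`cop`, `head`, `dep`, token indices).
#'   Empty text yields an empty list.
#' @examples
#' s <- parse_text("Flavor is great, definitely an adv.")[[1]]
#' s$deps # nsubj(great -> flavor), cop(great -> is)
#' @export
parse_text <- function(text, lexicon = default_lexicon()) {
  text <- trimws(text %||% "")
  if (is.na(text) || !nzchar(text)) return(list())
  raw <- strsplit(text, "[.!?]+")[[1]]
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  lapply(raw, parse_sentence, adjectives = c(names(lexicon), DICT_EXTRA_ADJ))
}

parse_sentence <- function(sentence, adjectives) {
  m <- gregexpr("[A-Za-z][A-Za-z']*|[0-9]+", sentence)[[1]]
  surface <- regmatches(sentence, list(m))[[1]]
  lower <- tolower(surface)
  tag <- vapply(lower, tag_word, character(1), adjectives = adjectives)
  tokens <- tibble::tibble(surface = surface, lower = lower, tag = unname(tag))
  list(tokens = tokens, deps = find_dependencies(tokens))
}

tag_word <- function(w, adjectives) {
  if (grepl("^[0-9]+$", w)) return("CD")
  if (w %in% DICT_DET) return("DT")
  if (w %in% DICT_PRON) return("PRP")
  if (w %in% DICT_COPULA) return("VBZ")
  if (w %in% DICT_ADV) return("RB")
  if (w %in% DICT_PREP) return("IN")
  if (w %in% DICT_CONJ) return("CC")
  if (w %in% DICT_VERB) return("VB")
  if (w %in% adjectives) return("JJ")
  "NN"
}

find_dependencies <- function(tokens) {
  n <- nrow(tokens)
  rel <- character(0); head <- integer(0); dep <- integer(0)
  add <- function(r, h, d) {
    rel <<- c(rel, r); head <<- c(head, h); dep <<- c(dep, d)
  }
  # amod: adjective directly before a noun
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      if (tokens$tag[i] == "JJ" && tokens$tag[i + 1] == "NN") {
        add("amod", i + 1L, i)
      }
    }
  }
  # nsubj + cop: nearest noun before a copula, first adjective after it
  # (skipping adverbs)
  for (ci in which(tokens$lower %in% DICT_COPULA)) {
    j <- ci + 1L
    while (j <= n && tokens$tag[j] == "RB") j <- j + 1L
    if (j > n || tokens$tag[j] != "JJ") next
    s <- ci - 1L
    while (s >= 1 && tokens$tag[s] != "NN") s <- s - 1L
    if (s < 1) next
    add("nsubj", j, s)
    add("cop", j, ci)
  }
  tibble::tibble(relation = rel, head = head, dep = dep)
}
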