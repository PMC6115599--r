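test_that("the rule parser recovers the two sanctioned dependency patterns", {
  s <- parse_text("Flavor is great, definitely an adv.")[[1]]
  i_flavor <- which(s$tokens$lower == "flavor")
  i_is <- which(s$tokens$lower == "is")
  i_great <- which(s$tokens$lower == "great")
  expect_true(any(s$deps$relation == "nsubj" & s$deps$head == i_great &
                    s$deps$dep == i_flavor))
  expect_true(any(s$deps$relation == "cop" & s$deps$head == i_great &
                    s$deps$dep == i_is))

  s2 <- parse_text("A great flavor.")[[1]]
  expect_true(any(s2$deps$relation == "amod" &
                    s2$tokens$lower[s2$deps$head] == "flavor" &
                    s2$tokens$lower[s2$deps$dep] == "great"))

  expect_identical(parse_text(""), list())
  expect_identical(parse_text("   "), list())
  expect_length(parse_text("Great taste! Harsh hit. The end."), 3)
})

test_that("every emitted pair replays one of the two dependency patterns", {
  sentences <- c(
    "The sweet taste is great.",
    "A harsh throat hit and a weak flavor.",
    "The vapor production was really poor."
  )
  for (txt in sentences) {
    for (s in parse_text(txt)) {
      pairs <- extract_pairs(s, candidates = keyword_unigrams_for_test())
      for (k in seq_len(nrow(pairs))) {
        term_tokens <- strsplit(pairs$aspect_term[k], " ")[[1]]
        adj_idx <- which(s$tokens$lower == pairs$sentiment_word[k])
        expect_true(all(s$tokens$tag[adj_idx] == "JJ"))
        via_amod <- with(s$deps, relation == "amod" &
                           s$tokens$lower[dep] %in% pairs$sentiment_word[k] &
                           s$tokens$lower[head] %in% term_tokens)
        via_cop <- with(s$deps, relation == "nsubj" &
                          s$tokens$lower[head] %in% pairs$sentiment_word[k] &
                          s$tokens$lower[dep] %in% term_tokens)
        expect_true(any(via_amod) || any(via_cop))
      }
    }
  }
})

test_that("candidate noun selection is strict at the threshold", {
  corpus <- tibble::tibble(
    product_id = "p", flavor_category = "sweet", overall_rating = 4,
    flavor_accuracy = 4, throat_hit = 4, value = 4, cloud_production = 4,
    text = c(
      paste(rep("The flavor arrived.", 21), collapse = " "),
      paste(rep("The juice arrived.", 20), collapse = " ")
    ),
    date = as.Date(NA)
  )
  cand <- candidate_aspect_nouns(corpus, tf_threshold = 20)
  expect_true("flavor" %in% cand$noun)   # 21 occurrences > 20
  expect_false("juice" %in% cand$noun)   # exactly 20 -> excluded
  expect_identical(cand$n[cand$noun == "flavor"], 21L)
  # and a noun at the threshold never surfaces in extracted pairs
  pairs <- extract_corpus(corpus, tf_threshold = 20)
  expect_false("juice" %in% pairs$aspect_term)
})

test_that("aspect category matching prefers bigrams and knows the keyword lists", {
  expect_identical(match_aspect_category("throat hit"), "throat_hit")
  expect_identical(match_aspect_category("price"), "value")
  expect_identical(match_aspect_category("aftertaste"), "flavor_accuracy")
  expect_identical(match_aspect_category("vapor production"), "cloud_production")
  expect_identical(match_aspect_category("waffles"), "uncategorized")
})

test_that("polarity lookup is case-insensitive and closed over the lexicon", {
  expect_identical(polarity("great"), "positive")
  expect_identical(polarity("GREAT"), "positive")
  expect_identical(polarity("harsh"), "negative")
  expect_identical(polarity("purple"), "unknown")
  lex <- default_lexicon()
  pairs <- extract_corpus(generate_corpus(
    synthetic_config(n_reviews = 100, seed = 13, phrase_rate = 1)
  )$corpus)
  known <- pairs$polarity != "unknown"
  expect_identical(pairs$polarity[known],
                   unname(lex[pairs$sentiment_word[known]]))
})

test_that("the worked example sentences yield exactly the expected pairs", {
  cand <- keyword_unigrams_for_test()
  one_pair <- function(text) {
    dplyr::bind_rows(lapply(parse_text(text), extract_pairs, candidates = cand))
  }
  p1 <- one_pair("Flavor is great, definitely an adv")
  expect_equal(nrow(p1), 1)
  expect_identical(unlist(p1[1, c("aspect_term", "sentiment_word", "polarity")],
                          use.names = FALSE),
                   c("flavor", "great", "positive"))

  p2 <- one_pair("A great flavor. Tastes like tobacco with waffles and maple syrup")
  expect_equal(nrow(p2), 1)
  expect_identical(unlist(p2[1, c("aspect_term", "sentiment_word", "polarity")],
                          use.names = FALSE),
                   c("flavor", "great", "positive"))

  p3 <- one_pair("The harsh throat hit makes me cough")
  expect_equal(nrow(p3), 1)
  expect_identical(unlist(p3[1, c("aspect_term", "sentiment_word", "polarity",
                                  "category")], use.names = FALSE),
                   c("throat hit", "harsh", "negative", "throat_hit"))
})

test_that("extraction recovers planted pairs on synthetic text", {
  gen <- generate_corpus(synthetic_config(n_reviews = 300, seed = 17,
                                          phrase_rate = 1))
  pairs <- extract_corpus(gen$corpus)
  planted <- gen$truth$planted
  recall <- mean(pair_key(planted) %in% pair_key(pairs))
  precision <- mean(pair_key(pairs) %in% pair_key(planted))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  # categories of matched pairs agree with the planted ones
  merged <- merge(pairs, planted,
                  by = c("review_index", "aspect_term", "sentiment_word"))
  expect_identical(merged$category.x, merged$category.y)
  expect_identical(merged$polarity.x, merged$polarity.y)
})

test_that("corpus extraction is deterministic and empty in yields empty out", {
  gen <- generate_corpus(synthetic_config(n_reviews = 60, seed = 19))
  expect_identical(extract_corpus(gen$corpus), extract_corpus(gen$corpus))
  empty <- gen$corpus
  empty$text <- ""
  expect_equal(nrow(extract_corpus(empty)), 0)
})

test_that("optional negation handling inverts polarity under a direct negator", {
  s <- parse_text("The flavor is not great.")[[1]]
  off <- extract_pairs(s, candidates = "flavor")
  on <- extract_pairs(s, candidates = "flavor", negation = TRUE)
  expect_identical(off$polarity, "positive") # default: no negation rule
  expect_identical(on$polarity, "negative")
})
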