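# Independent oracles and small fixture builders used across the suite.

# Entropy recomputed directly from a count vector (independent of the
# package's implementation).
oracle_entropy <- function(counts) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Information gain recomputed brute-force from the aspect x overall
# contingency table.
oracle_gain <- function(df, aspect) {
  tab <- table(df[[aspect]], df$overall)
  h_parent <- oracle_entropy(colSums(tab))
  h_children <- sum(rowSums(tab) / sum(tab) *
                      apply(tab, 1, oracle_entropy))
  h_parent - h_children
}

# Walk a fitted tree alongside the training rows, re-deriving each branch
# node's row subset by replaying the splits, and apply `fn(node, rows)` at
# every branch node.
walk_branches <- function(tree, rows, fn) {
  rec <- function(node, rows) {
    if (node$kind != "branch") return(invisible())
    fn(node, rows)
    for (v in names(node$children)) {
      rec(node$children[[v]], rows[rows[[node$split]] == v, , drop = FALSE])
    }
  }
  rec(tree, rows)
}

# Random labeled dataset for oracle-equivalence tests.
random_labeled_dataset <- function(n) {
  labs <- sentiment_levels()
  df <- tibble::tibble(
    flavor_accuracy = sample(labs, n, replace = TRUE),
    value = sample(labs, n, replace = TRUE),
    cloud_production = sample(labs, n, replace = TRUE),
    throat_hit = sample(labs, n, replace = TRUE),
    overall = sample(labs, n, replace = TRUE)
  )
  df
}

# Tiny hand-built corpus used by I/O and summarization tests.
tiny_corpus <- function() {
  tibble::tibble(
    product_id = c("p1", "p1", "p2", "p3", "p3"),
    flavor_category = c("fruity", "fruity", "sweet", "tobacco", "tobacco"),
    overall_rating = c(5, 4, 3.5, 2, 4.5),
    flavor_accuracy = c(5, 4, NA, 2, 4),
    throat_hit = c(4, NA, 3, 2, 5),
    value = c(5, 4, 2, 1, 3.5),
    cloud_production = c(3, 4, 3, 2, 4),
    text = c(
      "A great flavor. Definitely an adv for me.",
      "The price is reasonable.",
      "The value was really poor. Price is steep.",
      "The harsh throat hit makes me cough.",
      "Flavor is great, definitely an adv."
    ),
    date = as.Date(c("2014-01-01", "2015-06-15", NA, "2016-03-03", "2017-12-31"))
  )
}

pair_key <- function(d) paste(d$review_index, d$aspect_term, d$sentiment_word)

# Unigram tokens of the bundled aspect keyword lists, used as the candidate
# set when testing extraction on standalone sentences.
keyword_unigrams_for_test <- function() {
  unique(unlist(strsplit(unlist(default_aspect_keywords(), use.names = FALSE),
                         " ")))
}
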