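test_that("percentages reproduce printed two-decimal values from raw counts", {
  expect_identical(percent_of(18362, 27070), 67.83)
  expect_identical(percent_of(3430, 27070), 12.67)
  expect_identical(percent_of(6381, 9653), 66.10)
  expect_identical(percent_of(3315, 5128), 64.65)
  # half-up, not banker's
  expect_identical(round_half_up(0.125, 2), 0.13)
  expect_identical(round_half_up(2.345, 2), 2.35)
  expect_error(percent_of(1, 0), "positive")
})

test_that("review sentiment distributions count and percentage correctly", {
  one <- tiny_corpus()[1, ]
  d <- review_sentiment_distribution(one)
  expect_equal(d$count[d$label == "positive"], 1)
  expect_equal(d$pct[d$label == "positive"], 100)
  expect_equal(sum(d$count), 1)

  corpus <- tiny_corpus()
  d2 <- review_sentiment_distribution(corpus, group_by = "flavor")
  fruity <- d2[d2$group == "fruity", ]
  expect_equal(fruity$count[fruity$label == "positive"], 2)
  expect_equal(unique(fruity$n), 2)
  # percentages sum to 100 within rounding slack, per group
  for (g in unique(d2$group)) {
    expect_equal(sum(d2$pct[d2$group == g]), 100, tolerance = 0.02)
  }
  # totals conserved
  expect_equal(sum(d2$count), nrow(corpus))
  expect_equal(nrow(review_sentiment_distribution(corpus[0, ])), 0)
})

test_that("flavor review counts rank categories by popularity", {
  corpus <- tiny_corpus()
  counts <- flavor_review_counts(corpus)
  expect_identical(counts$flavor_category[counts$rank == 1][1],
                   counts$flavor_category[which.max(counts$n)])
  expect_equal(sum(counts$n), nrow(corpus))
  expect_equal(nrow(flavor_review_counts(corpus[0, ])), 0)

  gen <- generate_corpus(synthetic_config(n_reviews = 500, seed = 7))
  counts2 <- flavor_review_counts(gen$corpus)
  recount <- table(gen$corpus$flavor_category)
  expect_identical(stats::setNames(counts2$n, counts2$flavor_category)[names(recount)],
                   stats::setNames(as.integer(recount), names(recount)))
})

test_that("product sentiment uses the mean rating and counts products", {
  corpus <- tibble::tibble(
    product_id = c("a", "a", "a", "b", "c"),
    flavor_category = c("fruity", "fruity", "fruity", "fruity", "sweet"),
    overall_rating = c(5, 4, 3, 2.5, 3.2),
    flavor_accuracy = 4, throat_hit = 4, value = 4, cloud_production = 4,
    text = "", date = as.Date(NA)
  )
  ps <- product_sentiment(corpus)
  expect_equal(nrow(ps$products), 3)
  # mean (5,4,3) = 4.0 -> positive at the boundary
  expect_identical(ps$products$label[ps$products$product_id == "a"], "positive")
  expect_identical(ps$products$label[ps$products$product_id == "b"], "negative")
  expect_identical(ps$products$label[ps$products$product_id == "c"], "neutral")
  fruity <- ps$distribution[ps$distribution$group == "fruity", ]
  expect_equal(unique(fruity$n), 2) # products, not the 4 reviews
  expect_equal(sum(ps$distribution$count), 3)
})

test_that("aspect-scope opinion summaries gate by the source review's aspect rating", {
  corpus <- tibble::tibble(
    product_id = c("a", "b", "c"),
    flavor_category = "fruity",
    overall_rating = c(2, 3.5, 2),
    flavor_accuracy = c(4, 4, 4), throat_hit = 4,
    value = c(2, 3.5, 2), cloud_production = 4,
    text = "", date = as.Date(NA)
  )
  pairs <- tibble::tibble(
    review_index = c(1L, 2L, 3L),
    aspect_term = "price", sentiment_word = "steep",
    polarity = "negative", category = "value"
  )
  s <- opinion_summary(pairs, corpus, scope = "aspect_rating")
  # reviews 1 and 3 (value rating 2 < 3) land in the negative value summary
  expect_equal(nrow(s), 1)
  expect_identical(s$side, "negative")
  expect_identical(s$category, "value")
  expect_equal(s$n, 2) # two identical pairs -> frequency 2
  # review 2 (value rating 3.5, neutral band) appears nowhere
  # a pair lands in at most one side
  s_all <- opinion_summary(pairs, corpus, scope = "aspect_rating")
  expect_lte(sum(s_all$n), nrow(pairs))

  # uncategorized pairs are excluded from aspect scope, kept in product scope
  upairs <- pairs
  upairs$category <- "uncategorized"
  expect_equal(nrow(opinion_summary(upairs, corpus, "aspect_rating")), 0)
  sp <- opinion_summary(upairs, corpus, "product_rating")
  expect_equal(sum(sp$n), 2) # overall ratings 2,2 negative; 3.5 neutral dropped
})

test_that("opinion summaries rank by descending frequency then lexicographically", {
  corpus <- tibble::tibble(
    product_id = letters[1:6], flavor_category = "sweet",
    overall_rating = 5, flavor_accuracy = 5, throat_hit = 5, value = 5,
    cloud_production = 5, text = "", date = as.Date(NA)
  )
  pairs <- tibble::tibble(
    review_index = 1:6,
    aspect_term = c("taste", "taste", "taste", "flavor", "flavor", "juice"),
    sentiment_word = c("good", "good", "good", "great", "great", "amazing"),
    polarity = "positive", category = "flavor_accuracy"
  )
  s <- opinion_summary(pairs, corpus, scope = "aspect_rating")
  expect_identical(s$aspect_term, c("taste", "flavor", "juice"))
  expect_identical(s$n, c(3L, 2L, 1L))
})

test_that("keyword incidence counts reviews, not occurrences", {
  corpus <- tiny_corpus()
  # "adv" appears in reviews 1 and 5 (once each), nowhere else
  expect_equal(keyword_incidence(corpus, "adv"), 2)
  dup <- corpus
  dup$text[1] <- "adv adv adv"
  expect_equal(keyword_incidence(dup, "adv"), 2) # still two reviews
  expect_equal(keyword_incidence(corpus, character(0)), 0)
  expect_equal(keyword_incidence(corpus, c("be addicted to")), 0)
  # whole-token matching: "advance" does not contain the token "adv"
  adv <- corpus
  adv$text[2] <- "advance notice"
  expect_equal(keyword_incidence(adv, "adv"), 2)
  # matches an independent grepl recount on a generated corpus
  gen <- generate_corpus(synthetic_config(n_reviews = 400, seed = 23))
  expect_equal(keyword_incidence(gen$corpus, "adv"),
               sum(grepl("\\badv\\b", tolower(gen$corpus$text))))
})

test_that("reports round-trip through the JSON bundle", {
  gen <- generate_corpus(synthetic_config(n_reviews = 150, seed = 29))
  pairs <- extract_corpus(gen$corpus, tf_threshold = 5)
  dir <- withr::local_tempdir()
  bundle <- write_report(gen$corpus, pairs, dir, keywords = "adv")
  expect_true(file.exists(file.path(dir, "flavor_counts.tsv")))
  expect_true(file.exists(file.path(dir, "review_sentiment.tsv")))
  expect_true(file.exists(file.path(dir, "product_sentiment.tsv")))
  back <- jsonlite::read_json(file.path(dir, "bundle.json"),
                              simplifyVector = TRUE)
  expect_equal(back$flavor_counts$n, bundle$flavor_counts$n)
  expect_equal(back$review_sentiment$count, bundle$review_sentiment$count)
  expect_equal(back$product_sentiment$count, bundle$product_sentiment$count)
  expect_equal(back$keyword_incidence$n_reviews,
               keyword_incidence(gen$corpus, "adv"))
  # sentiment TSVs print two-decimal percentages
  rs <- readLines(file.path(dir, "review_sentiment.tsv"))
  expect_true(all(grepl("\t[0-9]+\\.[0-9]{2}\t", rs[-1])))
  # empty corpus still writes valid empty tables
  dir2 <- withr::local_tempdir()
  write_report(gen$corpus[0, ], NULL, dir2)
  expect_true(file.exists(file.path(dir2, "bundle.json")))
})
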