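#' Sentiment distribution of reviews
#'
#' Discretizes every review's overall rating and tabulates counts and
#' percentages per sentiment label, for the whole corpus or per flavor
#' category. Percentages are `100 * count / n` rounded half-up to two
#' decimals; groups with no reviews are omitted.
#'
#' @param corpus A corpus tibble.
#' @param group_by `"none"` (whole corpus) or `"flavor"`.
#' @return A tibble (`group`, `label`, `count`, `pct`, `n`); `group` is
#'   `"all"` when ungrouped.
#' @export
review_sentiment_distribution <- function(corpus,
                                          group_by = c("none", "flavor")) {
  group_by <- match.arg(group_by)
  if (nrow(corpus) == 0) {
    return(tibble::tibble(group = character(), label = character(),
                          count = integer(), pct = numeric(), n = integer()))
  }
  df <- tibble::tibble(
    group = if (group_by == "flavor") corpus$flavor_category else "all",
    label = discretize_rating(corpus$overall_rating)
  )
  distribution_table(df)
}

distribution_table <- function(df) {
  parts <- lapply(split(df$label, df$group), function(labs) {
    n <- length(labs)
    counts <- vapply(LABELS, function(l) sum(labs == l), integer(1))
    tibble::tibble(
      label = LABELS, count = unname(counts),
      pct = percent_of(unname(counts), n), n = n
    )
  })
  out <- dplyr::bind_rows(parts, .id = "group")
  tibble::as_tibble(out)
}

#' Review counts per flavor category
#'
#' Tabulates how many reviews each flavor category received, ranked by
#' descending count (more reviews indicating a more popular flavor).
#'
#' @param corpus A corpus tibble.
#' @return A tibble (`flavor_category`, `n`, `rank`), most-reviewed first.
#' @export
flavor_review_counts <- function(corpus) {
  if (nrow(corpus) == 0) {
    return(tibble::tibble(flavor_category = character(), n = integer(),
                          rank = integer()))
  }
  out <- dplyr::count(corpus, .data$flavor_category)
  out <- out[order(-out$n, out$flavor_category), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Product-level sentiment
#'
#' Labels each product by the arithmetic mean of its overall ratings,
#' discretized with the same rule as reviews (mean >= 4 positive, >= 3 and
#' < 4 neutral, < 3 negative), and tabulates the per-flavor distribution of
#' product labels. The distribution counts products, not reviews.
#'
#' @param corpus A corpus tibble; every product has at least one review.
#' @return A list with `products` (tibble: `product_id`,
#'   `flavor_category`, `n_reviews`, `mean_rating`, `label`) and
#'   `distribution` (tibble as in [review_sentiment_distribution()], with
#'   `group` the flavor category and counts over products).
#' @export
product_sentiment <- function(corpus) {
  if (nrow(corpus) == 0) {
    return(list(
      products = tibble::tibble(
        product_id = character(), flavor_category = character(),
        n_reviews = integer(), mean_rating = numeric(), label = character()
      ),
      distribution = tibble::tibble(
        group = character(), label = character(), count = integer(),
        pct = numeric(), n = integer()
      )
    ))
  }
  products <- dplyr::summarise(
    dplyr::group_by(corpus, .data$product_id),
    flavor_category = .data$flavor_category[1],
    n_reviews = dplyr::n(),
    mean_rating = mean(.data$overall_rating),
    .groups = "drop"
  )
  products$label <- discretize_rating(products$mean_rating)
  dist <- distribution_table(tibble::tibble(
    group = products$flavor_category, label = products$label
  ))
  list(products = products, distribution = dist)
}

#' Opinion summaries gated by ratings
#'
#' Aggregates opinion pairs into ranked positive and negative summaries.
#' Under `scope = "aspect_rating"`, a pair contributes to the positive
#' (resp. negative) summary of its aspect category only if its source
#' review's rating for that category is at least 4 (resp. below 3); reviews
#' in the neutral band, reviews missing that aspect rating, and
#' uncategorized pairs contribute to neither. Under
#' `scope = "product_rating"`, pairs are gated by the source review's
#' overall label instead (neutral reviews again excluded) and uncategorized
#' pairs are kept.
#'
#' @param pairs Opinion pairs from [extract_corpus()] (must carry
#'   `review_index`).
#' @param corpus The corpus the pairs came from.
#' @param scope `"aspect_rating"` or `"product_rating"`.
#' @param group_by `"none"` or `"flavor"` (group additionally by the source
#'   review's flavor category).
#' @return A tibble (`group`, `category`, `side`, `aspect_term`,
#'   `sentiment_word`, `n`) ranked within each group/category/side by
#'   descending frequency, ties lexicographic.
#' @export
opinion_summary <- function(pairs, corpus,
                            scope = c("aspect_rating", "product_rating"),
                            group_by = c("none", "flavor")) {
  scope <- match.arg(scope)
  group_by <- match.arg(group_by)
  empty <- tibble::tibble(
    group = character(), category = character(), side = character(),
    aspect_term = character(), sentiment_word = character(), n = integer()
  )
  if (nrow(pairs) == 0) return(empty)
  df <- pairs
  df$group <- if (group_by == "flavor") {
    corpus$flavor_category[df$review_index]
  } else {
    "all"
  }
  if (scope == "aspect_rating") {
    df <- df[df$category %in% ASPECTS, , drop = FALSE]
    if (nrow(df) == 0) return(empty)
    rating <- vapply(seq_len(nrow(df)), function(i) {
      corpus[[df$category[i]]][df$review_index[i]]
    }, numeric(1))
    side <- rep(NA_character_, nrow(df))
    side[!is.na(rating) & rating >= 4] <- "positive"
    side[!is.na(rating) & rating < 3] <- "negative"
  } else {
    overall <- discretize_rating(corpus$overall_rating[df$review_index])
    side <- ifelse(overall == "neutral", NA_character_, overall)
  }
  df$side <- side
  df <- df[!is.na(df$side), , drop = FALSE]
  if (nrow(df) == 0) return(empty)
  out <- dplyr::count(
    df, .data$group, .data$category, .data$side,
    .data$aspect_term, .data$sentiment_word
  )
  out <- out[order(out$group, out$category, out$side, -out$n,
                   out$aspect_term, out$sentiment_word), ]
  tibble::as_tibble(out)
}

#' Count reviews containing any keyword phrase
#'
#' Counts distinct reviews (posts), not occurrences, whose lowercased text
#' contains at least one of the keyword phrases as a whole-token sequence.
#'
#' @param corpus A corpus tibble.
#' @param keywords Character vector of lowercase phrases (e.g.
#'   `c("adv", "addicting", "be addicted to")`).
#' @return Integer count of reviews.
#' @export
keyword_incidence <- function(corpus, keywords) {
  if (length(keywords) == 0 || nrow(corpus) == 0) return(0L)
  txt <- tolower(corpus$text)
  patterns <- vapply(keywords, function(k) {
    paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tolower(k)), "\\b")
  }, character(1))
  hit <- rep(FALSE, length(txt))
  for (p in patterns) hit <- hit | grepl(p, txt, perl = TRUE)
  sum(hit)
}

#' Write a report of all summary tables
#'
#' Computes the standard summaries and writes them as TSV tables plus a
#' single JSON bundle. Percentages are printed with two decimals.
#' Files written under `dir`: `flavor_counts.tsv`, `review_sentiment.tsv`,
#' `product_sentiment.tsv`, one `opinions_<category>_<side>.tsv` per
#' non-empty combination, and `bundle.json` containing every table (plus
#' keyword incidence when `keywords` is given).
#'
#' @param corpus A corpus tibble.
#' @param pairs Opinion pairs from [extract_corpus()] (optional; `NULL`
#'   skips opinion tables).
#' @param dir Output directory (created if needed).
#' @param keywords Optional character vector for [keyword_incidence()].
#' @return The list of computed tables, invisibly.
#' @export
write_report <- function(corpus, pairs = NULL, dir, keywords = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt_pct <- function(df) {
    df$pct <- formatC(df$pct, format = "f", digits = 2)
    df
  }
  flavor_counts <- flavor_review_counts(corpus)
  review_dist <- review_sentiment_distribution(corpus, "flavor")
  prod <- product_sentiment(corpus)
  readr::write_tsv(flavor_counts, file.path(dir, "flavor_counts.tsv"))
  readr::write_tsv(fmt_pct(review_dist), file.path(dir, "review_sentiment.tsv"))
  readr::write_tsv(fmt_pct(prod$distribution),
                   file.path(dir, "product_sentiment.tsv"))
  opinions <- NULL
  if (!is.null(pairs)) {
    opinions <- opinion_summary(pairs, corpus, scope = "aspect_rating")
    groups <- unique(opinions[, c("category", "side")])
    for (i in seq_len(nrow(groups))) {
      sub <- opinions[opinions$category == groups$category[i] &
                        opinions$side == groups$side[i], ]
      readr::write_tsv(sub, file.path(
        dir, sprintf("opinions_%s_%s.tsv", groups$category[i], groups$side[i])
      ))
    }
  }
  bundle <- list(
    flavor_counts = flavor_counts,
    review_sentiment = review_dist,
    product_sentiment = prod$distribution,
    opinions = opinions
  )
  if (!is.null(keywords)) {
    bundle$keyword_incidence <- list(
      keywords = as.list(keywords),
      n_reviews = keyword_incidence(corpus, keywords)
    )
  }
  jsonlite::write_json(bundle, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(bundle)
}
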