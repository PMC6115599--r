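#' Read a review corpus
#'
#' Reads a corpus of rated e-liquid reviews from CSV or JSON-lines. Each
#' record carries a product id, a flavor category (one of the nine category
#' names or `"unknown"`), an overall rating in \[1, 5\], four aspect ratings
#' in \[1, 5\] (any of which may be missing), free review text, and an
#' optional date. Input order is preserved; duplicates are permitted.
#'
#' The CSV dialect is UTF-8, comma-separated, header row, RFC-4180 quoting.
#' Missing aspect ratings are empty fields (CSV) or `null` (JSON-lines);
#' they are never encoded as 0.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"jsonl"`.
#' @return A tibble with columns `product_id`, `flavor_category`,
#'   `overall_rating`, `flavor_accuracy`, `throat_hit`, `value`,
#'   `cloud_production`, `text`, `date`.
#' @seealso [write_corpus()], [generate_corpus()]
#' @export
read_corpus <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- readr::read_csv(
      path,
      col_types = readr::cols(
        product_id = readr::col_character(),
        flavor_category = readr::col_character(),
        overall_rating = readr::col_double(),
        flavor_accuracy = readr::col_double(),
        throat_hit = readr::col_double(),
        value = readr::col_double(),
        cloud_production = readr::col_double(),
        text = readr::col_character(),
        date = readr::col_date(format = "%Y-%m-%d")
      ),
      na = c("", "NA"),
      progress = FALSE,
      show_col_types = FALSE
    )
    probs <- readr::problems(df)
    if (nrow(probs) > 0) {
      stop(sprintf(
        "parse error in %s, line %d: expected %s, got %s",
        path, probs$row[1] + 1L, probs$expected[1], probs$actual[1]
      ))
    }
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(
        jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
        error = function(e) {
          stop(sprintf("parse error in %s, line %d: %s",
                       path, i, conditionMessage(e)))
        }
      )
      recs[[i]] <- tibble::tibble(
        product_id = as.character(rec$product_id %||% NA_character_),
        flavor_category = as.character(rec$flavor_category %||% NA_character_),
        overall_rating = as.numeric(rec$overall_rating %||% NA_real_),
        flavor_accuracy = as.numeric(rec$flavor_accuracy %||% NA_real_),
        throat_hit = as.numeric(rec$throat_hit %||% NA_real_),
        value = as.numeric(rec$value %||% NA_real_),
        cloud_production = as.numeric(rec$cloud_production %||% NA_real_),
        text = as.character(rec$text %||% NA_character_),
        date = as.Date(rec$date %||% NA_character_)
      )
    }
    df <- if (length(recs)) dplyr::bind_rows(recs) else empty_corpus()
  }
  missing_cols <- setdiff(setdiff(CORPUS_COLS, "date"), names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"date" %in% names(df)) df$date <- as.Date(NA)
  validate_corpus(df[, CORPUS_COLS])
}

empty_corpus <- function() {
  tibble::tibble(
    product_id = character(), flavor_category = character(),
    overall_rating = numeric(), flavor_accuracy = numeric(),
    throat_hit = numeric(), value = numeric(), cloud_production = numeric(),
    text = character(), date = as.Date(character())
  )
}

#' Validate a review corpus
#'
#' Checks the corpus invariants: overall rating present and within \[1, 5\],
#' every present aspect rating within \[1, 5\], flavor category drawn from
#' the closed nine-name vocabulary or `"unknown"`.
#'
#' @param corpus A corpus tibble.
#' @return The corpus, invisibly unchanged, if valid; otherwise an error
#'   naming the offending record.
#' @export
validate_corpus <- function(corpus) {
  if (nrow(corpus) == 0) return(corpus)
  bad <- which(is.na(corpus$overall_rating))
  if (length(bad)) stop("record ", bad[1], ": overall_rating is missing")
  check_range <- function(x, name) {
    bad <- which(!is.na(x) & (x < 1 | x > 5))
    if (length(bad)) {
      stop(sprintf("record %d: %s %s outside [1, 5]", bad[1], name, x[bad[1]]))
    }
  }
  check_range(corpus$overall_rating, "overall_rating")
  for (a in ASPECTS) check_range(corpus[[a]], a)
  flav <- corpus$flavor_category
  bad <- which(!is.na(flav) & !(flav %in% c(FLAVORS, "unknown")))
  if (length(bad)) {
    stop(sprintf("record %d: unknown flavor_category '%s'", bad[1], flav[bad[1]]))
  }
  corpus$flavor_category[is.na(flav)] <- "unknown"
  corpus$text[is.na(corpus$text)] <- ""
  corpus
}

#' Write a review corpus
#'
#' Inverse of [read_corpus()]: writes CSV or JSON-lines such that reading
#' the file back reproduces every field, including the missingness pattern,
#' record order, and ratings at full precision.
#'
#' @param corpus A corpus tibble (see [read_corpus()] for columns).
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  corpus <- corpus[, CORPUS_COLS]
  if (format == "csv") {
    readr::write_csv(corpus, path, na = "")
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(corpus))) {
      rec <- as.list(corpus[i, ])
      rec$date <- if (is.na(rec$date)) NULL else format(rec$date, "%Y-%m-%d")
      line <- jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null", digits = NA)
      writeLines(line, con, useBytes = TRUE)
    }
  }
  invisible(path)
}
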