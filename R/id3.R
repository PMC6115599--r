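#' Shannon entropy of sentiment-label counts, in bits
#'
#' @param counts Nonnegative counts, one per label (zeros allowed); total
#'   must be positive.
#' @return Entropy in bits, between 0 and `log2(3)` for three labels.
#' @examples
#' entropy_bits(c(10, 0, 0)) # 0, pure
#' entropy_bits(c(5, 5))     # 1
#' @export
entropy_bits <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- sum(counts)
  if (n <= 0) stop("entropy undefined for an empty node")
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Information gain of splitting on one aspect
#'
#' The ID3 split criterion: the reduction in overall-label entropy achieved
#' by partitioning the rows on the given aspect's label,
#' `H(overall) - sum_v (n_v / n) H(overall | aspect = v)` over observed
#' values `v`. Always in `[0, H(overall)]`.
#'
#' @param data A labeled dataset (see [labeled_dataset()]) or any subset of
#'   its rows; must contain an `overall` column and the aspect column.
#' @param aspect One of the four aspect names.
#' @return Information gain in bits.
#' @export
information_gain <- function(data, aspect) {
  if (!aspect %in% names(data)) stop("unknown aspect: ", aspect)
  n <- nrow(data)
  if (n < 1) stop("information gain requires at least one row")
  h <- entropy_bits(table(data$overall))
  groups <- split(data$overall, data[[aspect]])
  h_cond <- sum(vapply(
    groups,
    function(g) length(g) / n * entropy_bits(table(g)),
    numeric(1)
  ))
  max(h - h_cond, 0)
}

label_counts <- function(overall) {
  vapply(LABELS, function(l) sum(overall == l), integer(1))
}

# Majority label; ties resolved positive > neutral > negative.
majority_label <- function(counts) LABELS[which.max(counts)]

#' Build an ID3 decision tree over discretized aspect labels
#'
#' Grows a decision tree predicting the discretized overall sentiment label
#' from the four discretized aspect labels. At each node the aspect with the
#' largest information gain among the aspects not yet used on the path is
#' chosen; the rows are split by that aspect's observed label values and the
#' procedure recurses. Recursion stops when a node is pure, when no unused
#' aspect remains, or (by default) when every remaining aspect has zero
#' gain; `full_depth = TRUE` keeps splitting on zero-gain aspects until no
#' aspect remains, which changes the tree shape but never the importance
#' mass (zero-gain splits contribute nothing).
#'
#' Ties in information gain break by the canonical aspect order
#' (`flavor_accuracy`, `value`, `cloud_production`, `throat_hit`); ties in
#' leaf majority labels break positive > neutral > negative.
#'
#' @param data A labeled dataset from [labeled_dataset()]; at least one row.
#' @param full_depth Logical; split even on zero-gain aspects.
#' @return An object of class `id3_tree`: a nested list of nodes. Each node
#'   has `kind` (`"branch"` or `"leaf"`), `n_rows`, `counts` (per-label
#'   counts), and `prediction` (majority label); branch nodes additionally
#'   have `split` (aspect name), `gain` (bits), and `children` (named by the
#'   split aspect's label values observed at the node).
#' @seealso [predict.id3_tree()], [aspect_importance()], [export_tree()]
#' @export
build_id3 <- function(data, full_depth = FALSE) {
  if (nrow(data) < 1) stop("cannot build a tree from an empty dataset")
  node <- grow_id3(data, ASPECTS, full_depth)
  class(node) <- "id3_tree"
  node
}

grow_id3 <- function(rows, available, full_depth) {
  counts <- label_counts(rows$overall)
  leaf <- list(
    kind = "leaf", n_rows = nrow(rows), counts = counts,
    prediction = majority_label(counts)
  )
  if (length(available) == 0 || sum(counts > 0) <= 1) return(leaf)
  gains <- vapply(available, function(a) information_gain(rows, a), numeric(1))
  best_i <- which.max(gains) # first max: canonical-order tie-break
  if (!full_depth && gains[best_i] <= 1e-12) return(leaf)
  best <- available[best_i]
  children <- lapply(
    split(rows, rows[[best]], drop = TRUE),
    grow_id3,
    available = setdiff(available, best), full_depth = full_depth
  )
  list(
    kind = "branch", n_rows = nrow(rows), counts = counts,
    prediction = majority_label(counts),
    split = best, gain = unname(gains[best_i]), children = children
  )
}

#' Predict overall sentiment labels from aspect labels
#'
#' Routes each row of aspect labels down the tree. A label value with no
#' child branch at some node (unseen during training) falls back to that
#' node's majority label.
#'
#' @param object An `id3_tree` from [build_id3()].
#' @param newdata A data frame / tibble with the four aspect label columns
#'   (no missing values).
#' @param ... Unused.
#' @return Character vector of predicted sentiment labels.
#' @export
predict.id3_tree <- function(object, newdata, ...) {
  vapply(seq_len(nrow(newdata)), function(i) {
    node <- object
    repeat {
      if (node$kind == "leaf") return(node$prediction)
      child <- node$children[[newdata[[node$split]][i]]]
      if (is.null(child)) return(node$prediction)
      node <- child
    }
  }, character(1))
}

#' Aspect importance as normalized total information gain
#'
#' For each aspect, sums over all branch nodes splitting on that aspect the
#' node's information gain weighted by the fraction of training rows
#' reaching the node, then rescales the four totals to sum to one. This is
#' the tree-based importance statistic: the aspect with the higher value has
#' the greater influence on the overall sentiment. A single-leaf tree (no
#' split anywhere) yields the all-zero vector.
#'
#' @param tree An `id3_tree`.
#' @param n_total Number of training rows (defaults to the root's count).
#' @param weighted Logical; if `FALSE`, sums raw per-node gains without the
#'   row-fraction weight (an alternative reading of "total gain").
#' @return Named numeric vector over the four aspects, nonnegative, summing
#'   to 1 when any split occurred.
#' @export
aspect_importance <- function(tree, n_total = tree$n_rows, weighted = TRUE) {
  if (is.null(n_total) || n_total <= 0) stop("n_total must be positive")
  acc <- stats::setNames(numeric(length(ASPECTS)), ASPECTS)
  walk <- function(node) {
    if (node$kind == "branch") {
      w <- if (weighted) node$n_rows / n_total else 1
      acc[node$split] <<- acc[node$split] + w * node$gain
      for (child in node$children) walk(child)
    }
  }
  walk(tree)
  total <- sum(acc)
  if (total > 0) acc / total else acc
}

#' Serialize a decision tree to JSON
#'
#' Writes the tree with the conventional short aspect codes (`f` flavor
#' accuracy, `v` value, `c` cloud production, `t` throat hit), numeric edge
#' labels (1 positive, 0 neutral, -1 negative), leaf predictions as numeric
#' codes, and per-node row counts. [import_tree()] reads it back.
#'
#' @param tree An `id3_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_tree <- function(tree, path) {
  jsonlite::write_json(
    tree_to_list(tree), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

tree_to_list <- function(node) {
  out <- list(
    kind = node$kind,
    n = node$n_rows,
    counts = as.list(stats::setNames(
      as.integer(node$counts), as.character(LABEL_CODES[LABELS])
    )),
    prediction = unname(LABEL_CODES[node$prediction])
  )
  if (node$kind == "branch") {
    out$aspect <- unname(ASPECT_CODES[node$split])
    out$gain <- node$gain
    out$children <- stats::setNames(
      lapply(node$children, tree_to_list),
      as.character(LABEL_CODES[names(node$children)])
    )
  }
  out
}

#' @rdname export_tree
#' @export
import_tree <- function(path) {
  node <- list_to_tree(jsonlite::read_json(path, simplifyVector = FALSE))
  class(node) <- "id3_tree"
  node
}

list_to_tree <- function(x) {
  node <- list(
    kind = x$kind,
    n_rows = as.integer(x$n),
    counts = stats::setNames(
      vapply(as.character(LABEL_CODES[LABELS]),
             function(k) as.integer(x$counts[[k]] %||% 0L), integer(1)),
      LABELS
    ),
    prediction = sentiment_from_code(x$prediction)
  )
  if (x$kind == "branch") {
    node$split <- names(ASPECT_CODES)[match(x$aspect, ASPECT_CODES)]
    node$gain <- as.numeric(x$gain)
    node$children <- stats::setNames(
      lapply(x$children, list_to_tree),
      sentiment_from_code(names(x$children))
    )
  }
  node
}

#' @export
print.id3_tree <- function(x, ...) {
  rec <- function(node, indent, edge) {
    pad <- strrep("  ", indent)
    lab <- if (nzchar(edge)) paste0(edge, ": ") else ""
    if (node$kind == "leaf") {
      cat(sprintf("%s%s<leaf> %s (%d)\n", pad, lab, node$prediction, node$n_rows))
    } else {
      cat(sprintf("%s%s[%s] gain=%.4f (%d)\n",
                  pad, lab, ASPECT_CODES[node$split], node$gain, node$n_rows))
      for (v in names(node$children)) rec(node$children[[v]], indent + 1, v)
    }
  }
  rec(x, 0, "")
  invisible(x)
}
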