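#' Features actually consulted by a tree
#' @param tree A `cart_tree`.
#' @return Character vector of split features (empty for a stump).
#' @export
tree_features_used <- function(tree) {
  seen <- character(0)
  walk <- function(node) {
    if (is_leaf(node)) return(invisible())
    seen[[length(seen) + 1L]] <<- node$feature
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
  unique(seen)
}

#' Predict class labels with a classification tree
#'
#' Routes each row down the tree: values less than or equal to the node
#' threshold go left, values greater go right (so a value exactly at a
#' cutoff takes the left branch), and the leaf's class is returned.
#'
#' @param object A `cart_tree`.
#' @param newdata Data frame containing every feature the tree splits on,
#'   with no missing values in those columns.
#' @param ... Unused.
#' @return Factor of predicted labels with the tree's class levels.
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(newdata)
  used <- tree_features_used(object)
  missing <- setdiff(used, names(newdata))
  if (length(missing))
    stop_input("newdata is missing features required by the tree: %s",
               paste(missing, collapse = ", "))
  for (f in used) {
    if (anyNA(newdata[[f]]))
      stop_input("feature '%s' contains missing values", f)
  }
  out <- character(nrow(newdata))
  walk <- function(node, rows) {
    if (!length(rows)) return(invisible())
    if (is_leaf(node)) {
      out[rows] <<- node$class
      return(invisible())
    }
    left <- newdata[[node$feature]][rows] <= node$threshold
    walk(node$left, rows[left])
    walk(node$right, rows[!left])
  }
  walk(object$root, seq_len(nrow(newdata)))
  factor(out, levels = object$classes)
}

#' Gini feature importance of a fitted tree
#'
#' Sums, over the internal nodes splitting on each feature, the node's
#' weighted Gini impurity decrease times the fraction of training rows
#' reaching the node, then normalizes the totals to sum to one. Features
#' the tree never consults get importance 0.
#'
#' @param tree A `cart_tree` with recorded split decreases (i.e. grown by
#'   [grow_tree()], possibly pruned).
#' @return Named numeric vector over `tree$features`, summing to 1; for a
#'   stump an all-zero vector with attribute `degenerate = TRUE` and a
#'   warning.
#' @export
feature_importance <- function(tree) {
  if (!inherits(tree, "cart_tree")) stop_input("tree must be a cart_tree")
  imp <- stats::setNames(numeric(length(tree$features)), tree$features)
  n_root <- tree$root$n
  walk <- function(node) {
    if (is_leaf(node)) return(invisible())
    imp[[node$feature]] <<- imp[[node$feature]] +
      node$n / n_root * node$decrease
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
  total <- sum(imp)
  if (total == 0) {
    warning("stump tree: all feature importances are zero", call. = FALSE)
    attr(imp, "degenerate") <- TRUE
    return(imp)
  }
  imp / total
}
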