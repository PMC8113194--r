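#' Gini impurity of a class-count vector
#'
#' `1 - sum(p^2)` over class proportions; 0 for a pure node, at most
#' `1 - 1/K` for K perfectly balanced classes.
#'
#' @param class_counts Non-negative counts, one per class, summing > 0.
#' @return Impurity in `[0, 1 - 1/K]`.
#' @export
#' @examples
#' gini_impurity(c(5, 5))  # 0.5
gini_impurity <- function(class_counts) {
  if (!is.numeric(class_counts) || any(class_counts < 0))
    stop_input("class counts must be non-negative numbers")
  n <- sum(class_counts)
  if (n <= 0) stop_input("class counts must sum to a positive total")
  1 - sum((class_counts / n)^2)
}

# Split-search score for a candidate partition: sum over children of
# (sum of squared class counts) / child size. Maximizing this is equivalent
# to maximizing the weighted Gini decrease, but every term is a single
# division of integers, so scores computed by independent implementations
# of the same definition agree bit-for-bit and tie-breaks are reproducible.
split_score <- function(ss_left, n_left, ss_right, n_right) {
  ss_left / n_left + ss_right / n_right
}

# Weighted Gini decrease of a split, from the same integer building blocks:
# parent impurity minus child-size-weighted child impurities.
split_decrease <- function(ss_left, n_left, ss_right, n_right, ss_parent, n) {
  (split_score(ss_left, n_left, ss_right, n_right) - ss_parent / n) / n
}

#' Exhaustive best binary split of a node
#'
#' Scans every feature and every midpoint between consecutive distinct
#' sorted values, and returns the split maximizing the weighted Gini
#' impurity decrease. Ties are broken deterministically: first by the order
#' of `features`, then by the smallest threshold. Splits leaving fewer than
#' `minbucket` rows on either side are inadmissible, as are splits with no
#' strictly positive impurity decrease.
#'
#' @param data Data frame containing the feature columns and the label.
#' @param features Character vector of feature column names, in
#'   tie-breaking order.
#' @param label Name of the class-label column (factor).
#' @param minbucket Minimum rows in each child.
#' @return `NULL` when no admissible split exists; otherwise a list with
#'   `feature`, `threshold`, `decrease` (weighted Gini decrease at the
#'   node) and the child sizes `n_left`, `n_right`.
#' @export
best_split <- function(data, features, label = "group", minbucket = 1L) {
  y <- data[[label]]
  if (!is.factor(y)) stop_input("label column '%s' must be a factor", label)
  n <- length(y)
  counts <- tabulate(y, nbins = nlevels(y))
  if (max(counts) == n) return(NULL)  # pure node: nothing to gain
  ss_parent <- sum(counts^2)
  best <- NULL
  best_score <- -Inf
  for (f in features) {
    x <- data[[f]]
    if (anyNA(x)) stop_input("feature '%s' contains missing values", f)
    o <- order(x)
    xs <- x[o]
    yi <- as.integer(y)[o]
    # cumulative per-class counts after each sorted row
    cum <- matrix(0L, n, nlevels(y))
    cum[cbind(seq_len(n), yi)] <- 1L
    cum <- apply(cum, 2, cumsum)
    cuts <- which(diff(xs) > 0)
    cuts <- cuts[cuts >= minbucket & (n - cuts) >= minbucket]
    if (!length(cuts)) next
    left <- cum[cuts, , drop = FALSE]
    right <- rep(counts, each = length(cuts)) - left
    ssl <- rowSums(left^2)
    ssr <- rowSums(right^2)
    scores <- split_score(ssl, cuts, ssr, n - cuts)
    j <- which.max(scores)  # first max = smallest threshold
    if (scores[j] > best_score) {
      best_score <- scores[j]
      cut <- cuts[j]
      best <- list(feature = f,
                   threshold = (xs[cut] + xs[cut + 1]) / 2,
                   decrease = split_decrease(ssl[j], cut, ssr[j], n - cut,
                                             ss_parent, n),
                   n_left = cut, n_right = n - cut)
    }
  }
  if (is.null(best) || !(best_score > ss_parent / n)) return(NULL)
  best
}

new_leaf <- function(counts, classes) {
  structure(list(
    n = sum(counts),
    counts = stats::setNames(as.integer(counts), classes),
    class = classes[which.max(counts)],
    impurity = gini_impurity(counts),
    feature = NULL, threshold = NULL, decrease = NULL,
    left = NULL, right = NULL
  ), class = "cart_node")
}

is_leaf <- function(node) is.null(node$feature)

#' Grow a classification tree by recursive binary partitioning
#'
#' From-scratch CART growth with the Gini criterion: starting from all
#' rows, the node-local best split (see [best_split()]) is applied
#' recursively until a node is pure, has fewer than `minsplit` rows,
#' reaches `max_depth`, or admits no impurity-decreasing split. Each node's
#' predicted class is the majority class, ties broken by factor-level
#' order.
#'
#' @param data Data frame with the feature columns and a factor label
#'   column.
#' @param features Feature column names in tie-breaking order; defaults to
#'   the six quantitative indices.
#' @param label Name of the label column.
#' @param minsplit Minimum rows for a node to be considered for splitting.
#' @param minbucket Minimum rows in any leaf.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @return An object of class `cart_tree`: list with the root node, the
#'   feature names, class levels, training size and growth parameters.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' fit <- grow_tree(cohort)
#' n_leaves(fit)
grow_tree <- function(data, features = index_features(), label = "group",
                      minsplit = 20L, minbucket = 7L, max_depth = 30L) {
  if (!is.data.frame(data) || nrow(data) == 0L)
    stop_input("data must be a non-empty data frame")
  missing <- setdiff(c(features, label), names(data))
  if (length(missing))
    stop_input("data is missing columns: %s", paste(missing, collapse = ", "))
  y <- data[[label]]
  if (!is.factor(y)) {
    y <- factor(y, levels = intersect(diagnostic_groups(), unique(y)))
    if (anyNA(y)) y <- factor(data[[label]])
    data[[label]] <- y
  }
  if (anyNA(y)) stop_input("label column contains missing values")
  classes <- levels(y)
  if (minbucket < 1 || minsplit < 2)
    stop_input("minsplit must be >= 2 and minbucket >= 1")

  build <- function(rows, depth) {
    counts <- tabulate(y[rows], nbins = length(classes))
    node <- new_leaf(counts, classes)
    if (node$impurity == 0 || length(rows) < minsplit || depth >= max_depth)
      return(node)
    sp <- best_split(data[rows, , drop = FALSE], features, label,
                     minbucket = minbucket)
    if (is.null(sp)) return(node)
    go_left <- data[[sp$feature]][rows] <= sp$threshold
    node$feature <- sp$feature
    node$threshold <- sp$threshold
    node$decrease <- sp$decrease
    node$left <- build(rows[go_left], depth + 1L)
    node$right <- build(rows[!go_left], depth + 1L)
    node
  }

  structure(list(
    root = build(seq_len(nrow(data)), 0L),
    features = features, classes = classes, n = nrow(data),
    params = list(minsplit = as.integer(minsplit),
                  minbucket = as.integer(minbucket),
                  max_depth = as.integer(max_depth))
  ), class = "cart_tree")
}

#' Number of leaves of a tree
#' @param tree A `cart_tree`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(tree) {
  count <- function(node) {
    if (is_leaf(node)) 1L else count(node$left) + count(node$right)
  }
  count(tree$root)
}

# Misclassification count of the subtree below `node` (sum over leaves of
# n - majority count).
subtree_error <- function(node) {
  if (is_leaf(node)) node$n - max(node$counts)
  else subtree_error(node$left) + subtree_error(node$right)
}
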