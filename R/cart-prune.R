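# Rational comparison helpers: every link strength g is a ratio of two
# small integers (error increase / leaves removed), so comparing them by
# cross-multiplication is exact and the pruning sequence is reproducible.
ratio_lt <- function(num1, den1, num2, den2) num1 * den2 < num2 * den1
ratio_eq <- function(num1, den1, num2, den2) num1 * den2 == num2 * den1

# Minimum link strength g(t) = (R(t) - R(T_t)) / (|leaves| - 1) over the
# internal nodes of a subtree, kept as an exact integer ratio.
min_link <- function(node) {
  if (is_leaf(node))
    return(list(leaves = 1L, rsub = node$n - max(node$counts),
                num = NULL, den = NULL))
  l <- min_link(node$left)
  r <- min_link(node$right)
  leaves <- l$leaves + r$leaves
  rsub <- l$rsub + r$rsub
  num <- (node$n - max(node$counts)) - rsub
  den <- leaves - 1L
  for (child in list(l, r)) {
    if (!is.null(child$num) && ratio_lt(child$num, child$den, num, den)) {
      num <- child$num; den <- child$den
    }
  }
  list(leaves = leaves, rsub = rsub, num = num, den = den)
}

# Collapse (in one top-down pass) every internal node whose link strength
# equals the current minimum; ancestors of a collapsed node always have
# strictly larger g afterwards, so one pass per step is enough.
collapse_at <- function(node, num, den) {
  if (is_leaf(node)) return(node)
  info <- min_link(node)
  g_num <- (node$n - max(node$counts)) - info$rsub
  g_den <- info$leaves - 1L
  if (ratio_eq(g_num, g_den, num, den)) {
    return(new_leaf(node$counts, names(node$counts)))
  }
  node$left <- collapse_at(node$left, num, den)
  node$right <- collapse_at(node$right, num, den)
  node
}

as_subtree <- function(tree, root) {
  tree$root <- root
  tree
}

#' Cost-complexity pruning path of a grown tree
#'
#' Weakest-link pruning: starting from the full tree, the internal node(s)
#' with the smallest per-leaf error increase
#' `g(t) = (R(t) - R(T_t)) / (|leaves(T_t)| - 1)` are collapsed repeatedly
#' until only the root stump remains, yielding the nested sequence of
#' optimal subtrees indexed by the complexity parameter. Errors are
#' misclassification counts; both the complexity parameter `alpha` and the
#' resubstitution error are reported relative to the root-stump error, so
#' the stump has relative error 1.
#'
#' @param tree A `cart_tree` from [grow_tree()].
#' @return An object of class `prune_path`: list with `table` (data frame
#'   with `alpha`, `n_leaves`, `rel_error`, `xerror`, `xstd` — the latter
#'   two `NA` until [cross_validate()] fills them), `trees` (the nested
#'   subtrees, largest first) and the growth metadata.
#' @export
prune_path <- function(tree) {
  if (!inherits(tree, "cart_tree")) stop_input("tree must be a cart_tree")
  root_err <- tree$root$n - max(tree$root$counts)
  cur <- tree$root
  # collapse ineffective links (g = 0) first, so the alpha = 0 entry is the
  # smallest subtree attaining the full tree's resubstitution error
  while (!is_leaf(cur)) {
    info <- min_link(cur)
    if (info$num != 0L) break
    cur <- collapse_at(cur, info$num, info$den)
  }
  alphas <- 0
  trees <- list(cur)
  while (!is_leaf(cur)) {
    info <- min_link(cur)
    cur <- collapse_at(cur, info$num, info$den)
    alphas <- c(alphas, (info$num / info$den) / root_err)
    trees <- c(trees, list(cur))
  }
  table <- data.frame(
    alpha = alphas,
    n_leaves = vapply(trees, function(nd) n_leaves(as_subtree(tree, nd)),
                      integer(1)),
    rel_error = if (root_err > 0)
      vapply(trees, subtree_error, numeric(1)) / root_err
    else rep(0, length(trees)),
    xerror = NA_real_, xstd = NA_real_
  )
  structure(list(table = table,
                 trees = lapply(trees, as_subtree, tree = tree),
                 features = tree$features, classes = tree$classes,
                 n = tree$n, params = tree$params,
                 root_error = root_err),
            class = "prune_path")
}

#' Cross-validated error along the pruning path
#'
#' Grows the tree on the full data, computes its pruning path, then runs
#' seeded stratified k-fold cross-validation: each fold's training part is
#' grown and pruned with the same controls, and for every complexity value
#' of the master path (represented by the geometric mean of adjacent path
#' alphas) the fold subtree optimal at that complexity predicts the held-out
#' rows. `xerror` is the pooled held-out misclassification count relative
#' to the root-stump error; `xstd` is its binomial standard error on the
#' same scale.
#'
#' @inheritParams grow_tree
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed for the stratified fold assignment.
#' @return A `prune_path` (see [prune_path()]) with `xerror` and `xstd`
#'   filled in, and attributes `folds` and `seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' path <- cross_validate(cohort, folds = 5, seed = 1)
#' path$table
cross_validate <- function(data, features = index_features(),
                           label = "group", minsplit = 20L, minbucket = 7L,
                           max_depth = 30L, folds = 10L, seed = 1L) {
  if (!is_scalar_number(folds) || folds < 2)
    stop_input("folds must be an integer >= 2")
  if (folds > nrow(data))
    stop_input("folds (%d) cannot exceed the number of rows (%d)",
               folds, nrow(data))
  full <- grow_tree(data, features, label, minsplit, minbucket, max_depth)
  path <- prune_path(full)
  alphas <- path$table$alpha
  m <- length(alphas)
  betas <- if (m > 1) c(sqrt(alphas[-m] * alphas[-1]), Inf) else Inf

  y <- data[[label]]
  if (!is.factor(y)) y <- factor(y)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  fold_of <- integer(nrow(data))
  for (cl in levels(y)) {
    rows <- which(y == cl)
    fold_of[rows[sample.int(length(rows))]] <-
      rep_len(seq_len(folds), length(rows))
  }

  errs <- numeric(m)
  for (f in seq_len(folds)) {
    test <- fold_of == f
    if (!any(test) || all(test)) next
    fold_tree <- grow_tree(data[!test, , drop = FALSE], features, label,
                           minsplit, minbucket, max_depth)
    fold_path <- prune_path(fold_tree)
    fa <- fold_path$table$alpha
    truth <- as.character(y[test])
    for (k in seq_len(m)) {
      i <- max(which(fa <= betas[k]))
      pred <- as.character(predict(fold_path$trees[[i]],
                                   data[test, , drop = FALSE]))
      errs[k] <- errs[k] + sum(pred != truth)
    }
  }
  root_err <- path$root_error
  n <- nrow(data)
  if (root_err > 0) {
    path$table$xerror <- errs / root_err
    path$table$xstd <- sqrt(errs * (n - errs) / n) / root_err
  } else {
    path$table$xerror <- 0
    path$table$xstd <- 0
  }
  attr(path, "folds") <- as.integer(folds)
  attr(path, "seed") <- as.integer(seed)
  path
}

#' Min-1SE subtree selection
#'
#' Applies the one-standard-error rule to a cross-validated pruning path:
#' among all subtrees whose cross-validated error does not exceed the
#' minimum `xerror` plus the `xstd` at that minimum, the smallest subtree
#' (largest complexity parameter) is returned.
#'
#' @param path A `prune_path` with `xerror`/`xstd` filled (see
#'   [cross_validate()]).
#' @return The selected `cart_tree`, with attributes `alpha`, `xerror` and
#'   `n_leaves` recording the chosen path entry.
#' @export
select_min_1se <- function(path) {
  if (!inherits(path, "prune_path")) stop_input("path must be a prune_path")
  xe <- path$table$xerror
  if (anyNA(xe))
    stop_input("path has no cross-validated errors; run cross_validate()")
  i_min <- which.min(xe)
  threshold <- xe[i_min] + path$table$xstd[i_min]
  chosen <- max(which(xe <= threshold))
  tree <- path$trees[[chosen]]
  attr(tree, "alpha") <- path$table$alpha[chosen]
  attr(tree, "xerror") <- xe[chosen]
  attr(tree, "n_leaves") <- path$table$n_leaves[chosen]
  tree
}
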