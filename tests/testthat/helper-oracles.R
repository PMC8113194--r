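# Independent brute-force oracles for the CART engine. These re-derive the
# split search, tree growth and cost-complexity pruning sequence from their
# definitions by plain enumeration, sharing no code with the engine beyond
# the public node accessors used for comparison.

# Exhaustive split search: double loop over every feature and every midpoint
# between consecutive distinct values, scoring each candidate by the sum over
# children of (sum of squared class counts) / child size (monotone in the
# weighted Gini decrease). Ties: feature order, then smallest threshold.
oracle_best_split <- function(data, features, label = "group",
                              minbucket = 1L) {
  y <- data[[label]]
  classes <- levels(y)
  n <- nrow(data)
  ssp <- sum(table(y)^2)
  best <- NULL
  best_score <- -Inf
  for (f in features) {
    xs <- sort(unique(data[[f]]))
    if (length(xs) < 2) next
    for (i in seq_len(length(xs) - 1L)) {
      thr <- (xs[i] + xs[i + 1]) / 2
      left <- data[[f]] <= thr
      n_left <- sum(left)
      if (n_left < minbucket || (n - n_left) < minbucket) next
      ssl <- sum(table(factor(y[left], levels = classes))^2)
      ssr <- sum(table(factor(y[!left], levels = classes))^2)
      score <- ssl / n_left + ssr / (n - n_left)
      if (score > best_score) {
        best_score <- score
        best <- list(feature = f, threshold = thr)
      }
    }
  }
  if (is.null(best) || !(best_score > ssp / n)) return(NULL)
  best
}

# Recursive growth using only the oracle split search and the stated
# stopping rules; returns a plain nested list.
oracle_grow <- function(data, features, label = "group", minsplit = 2L,
                        minbucket = 1L, max_depth = 30L, depth = 0L) {
  y <- data[[label]]
  counts <- table(y)
  node <- list(counts = as.integer(counts),
               class = names(counts)[which.max(counts)])
  pure <- max(counts) == nrow(data)
  if (pure || nrow(data) < minsplit || depth >= max_depth) return(node)
  sp <- oracle_best_split(data, features, label, minbucket)
  if (is.null(sp)) return(node)
  left <- data[[sp$feature]] <= sp$threshold
  node$feature <- sp$feature
  node$threshold <- sp$threshold
  node$left <- oracle_grow(data[left, , drop = FALSE], features, label,
                           minsplit, minbucket, max_depth, depth + 1L)
  node$right <- oracle_grow(data[!left, , drop = FALSE], features, label,
                            minsplit, minbucket, max_depth, depth + 1L)
  node
}

# Canonical description of a tree (engine cart_tree or oracle list) used to
# compare structures split for split.
tree_signature <- function(node) {
  if (inherits(node, "cart_tree")) node <- node$root
  if (is.null(node$feature)) {
    return(sprintf("leaf(%s|%s)", node$class,
                   paste(node$counts, collapse = ",")))
  }
  sprintf("[%s<=%.17g %s %s]", node$feature, node$threshold,
          tree_signature(node$left), tree_signature(node$right))
}

# All pruned subtrees of a tree, as (signature, error count, leaf count)
# plus the collapsed structure, by exhaustive enumeration.
oracle_enumerate_subtrees <- function(node) {
  leaf_version <- list(counts = node$counts, class = node$class)
  if (is.null(node$feature)) return(list(leaf_version))
  out <- list(leaf_version)
  for (l in oracle_enumerate_subtrees(node$left)) {
    for (r in oracle_enumerate_subtrees(node$right)) {
      out[[length(out) + 1L]] <- list(counts = node$counts,
                                      class = node$class,
                                      feature = node$feature,
                                      threshold = node$threshold,
                                      left = l, right = r)
    }
  }
  out
}

oracle_leaves <- function(node) {
  if (is.null(node$feature)) 1L
  else oracle_leaves(node$left) + oracle_leaves(node$right)
}

oracle_error <- function(node) {
  if (is.null(node$feature)) sum(node$counts) - max(node$counts)
  else oracle_error(node$left) + oracle_error(node$right)
}

# Cost-complexity pruning sequence by brute force: enumerate every pruned
# subtree, then walk alpha upward from 0, at each step taking the smallest
# subtree minimizing error + alpha * leaves. Alphas are reported relative
# to the root-stump error (same scale as prune_path()).
oracle_prune_path <- function(root) {
  subs <- oracle_enumerate_subtrees(root)
  errs <- vapply(subs, oracle_error, numeric(1))
  leaves <- vapply(subs, oracle_leaves, integer(1))
  root_err <- sum(root$counts) - max(root$counts)

  pick_smallest_opt <- function(alpha_count) {
    cost <- errs + alpha_count * leaves
    opt <- which(cost == min(cost))
    opt[which.min(leaves[opt])]
  }

  # alpha = 0: smallest subtree attaining the minimum error
  cur <- pick_smallest_opt(0)
  alphas <- 0
  chosen <- list(subs[[cur]])
  while (leaves[cur] > 1L) {
    cand <- which(leaves < leaves[cur])
    ratios <- (errs[cand] - errs[cur]) / (leaves[cur] - leaves[cand])
    a_next <- min(ratios)
    hit <- cand[ratios == a_next]
    cur <- hit[which.min(leaves[hit])]
    alphas <- c(alphas, a_next / root_err)
    chosen[[length(chosen) + 1L]] <- subs[[cur]]
  }
  list(alphas = alphas, trees = chosen,
       n_leaves = vapply(chosen, oracle_leaves, integer(1)),
       rel_error = vapply(chosen, oracle_error, numeric(1)) / root_err)
}

# Random small classification instances with deliberately discretized
# feature values, so threshold and score ties occur and tie-breaking is
# exercised.
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(20:60, 1)
  p <- sample(2:4, 1)
  k <- sample(2:3, 1)
  X <- as.data.frame(lapply(seq_len(p), function(j) {
    round(stats::rnorm(n, mean = sample(0:3, 1)), sample(0:1, 1))
  }))
  names(X) <- paste0("f", seq_len(p))
  X$group <- factor(sample(diagnostic_groups()[seq_len(k)], n,
                           replace = TRUE),
                    levels = diagnostic_groups()[seq_len(k)])
  X
}

# Cohort with well-separated groups for threshold-recovery tests: Table-2
# style means with shrunken spread.
separated_cohort <- function(seed, n_per_group = 100, sd_shrink = 4) {
  models <- default_group_models()
  models$sd <- models$sd / sd_shrink
  sizes <- stats::setNames(rep(n_per_group, 5), diagnostic_groups())
  generate_cohort(models, sizes, seed = seed)
}
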