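test_that("a stump prunes to a length-1 path", {
  d <- data.frame(sbr = rnorm(30), group = factor(rep("PD", 30)))
  fit <- grow_tree(d, "sbr")
  path <- prune_path(fit)
  expect_equal(nrow(path$table), 1)
  expect_equal(path$table$alpha, 0)
  expect_equal(path$table$n_leaves, 1)
})

test_that("prune paths end at the stump with increasing alphas and errors", {
  for (seed in c(2, 9, 14)) {
    co <- generate_cohort(seed = seed)
    fit <- grow_tree(co, minsplit = 10, minbucket = 3)
    path <- prune_path(fit)
    tab <- path$table
    expect_true(all(diff(tab$alpha) > 0))
    expect_true(all(diff(tab$n_leaves) < 0))
    expect_true(all(diff(tab$rel_error) >= 0))  # resub error monotone
    expect_equal(tab$n_leaves[nrow(tab)], 1)
    expect_equal(tab$rel_error[nrow(tab)], 1)
    # nested sequence: each subtree's leaf count matches its tree
    expect_equal(vapply(path$trees, n_leaves, integer(1)), tab$n_leaves)
  }
})

test_that("weakest-link pruning matches brute-force subtree enumeration", {
  for (seed in 1:20) {
    d <- random_instance(seed)
    feats <- setdiff(names(d), "group")
    fit <- grow_tree(d, features = feats, minsplit = 5, minbucket = 2,
                     max_depth = 5)
    path <- prune_path(fit)
    oracle <- oracle_prune_path(fit$root)
    expect_equal(path$table$alpha, oracle$alphas, info = paste("seed", seed))
    expect_equal(path$table$n_leaves, oracle$n_leaves,
                 info = paste("seed", seed))
    expect_equal(path$table$rel_error, oracle$rel_error,
                 info = paste("seed", seed))
    for (k in seq_along(oracle$trees)) {
      expect_identical(tree_signature(path$trees[[k]]),
                       tree_signature(oracle$trees[[k]]),
                       info = sprintf("seed %d subtree %d", seed, k))
    }
  }
})

test_that("cross-validation is deterministic under a fixed seed", {
  co <- generate_cohort(seed = 6)
  a <- cross_validate(co, folds = 5, seed = 10)
  b <- cross_validate(co, folds = 5, seed = 10)
  c <- cross_validate(co, folds = 5, seed = 11)
  expect_identical(a$table$xerror, b$table$xerror)
  expect_false(identical(a$table$xerror, c$table$xerror))
  expect_false(anyNA(a$table$xerror))
  expect_true(all(a$table$xstd >= 0))
  expect_error(cross_validate(co, folds = 1), "folds")
  expect_error(cross_validate(co[1:4, ], folds = 10), "exceed")
})

test_that("perfectly separable data cross-validates to near-zero xerror", {
  d <- data.frame(sbr = c(rnorm(60, 0), rnorm(60, 20)),
                  group = factor(rep(c("PD", "NPS"), each = 60),
                                 levels = c("NPS", "PD")))
  path <- cross_validate(d, features = "sbr", minsplit = 10, minbucket = 5,
                         folds = 5, seed = 2)
  expect_lt(min(path$table$xerror), 0.05)
})

test_that("permuted labels leave no cross-validatable structure", {
  co <- generate_cohort(sizes = c(NPS = 40, PD = 40), seed = 20)
  mins <- vapply(1:8, function(r) {
    set.seed(100 + r)
    co$group <- sample(co$group)
    path <- cross_validate(co, folds = 5, seed = r, minsplit = 10,
                           minbucket = 3)
    min(path$table$xerror)
  }, numeric(1))
  expect_gt(mean(mins), 0.85)
})

test_that("the Min-1SE rule picks the smallest subtree within one SE", {
  fake_path <- function(xerror, xstd) {
    k <- length(xerror)
    trees <- lapply(seq_len(k), function(i) structure(list(id = i),
                                                      class = "cart_tree"))
    structure(list(table = data.frame(alpha = seq(0, 1, length.out = k),
                                      n_leaves = rev(seq_len(k)),
                                      rel_error = NA_real_,
                                      xerror = xerror, xstd = xstd),
                   trees = trees),
              class = "prune_path")
  }
  # worked profile: min 0.35 with SE 0.05; 0.4 qualifies, 1.0 does not
  p <- fake_path(c(1.0, 0.4, 0.35, 0.36), c(0.2, 0.06, 0.05, 0.05))
  expect_equal(select_min_1se(p)$id, 4)  # 0.36 <= 0.40, smallest subtree
  p2 <- fake_path(c(1.0, 0.4, 0.35, 0.41), c(0.2, 0.06, 0.05, 0.05))
  expect_equal(select_min_1se(p2)$id, 3)  # 0.41 > 0.40; 0.35 is last to qualify
  # xerror strictly improving toward the stump: smallest subtree wins
  p3 <- fake_path(c(1.0, 0.6, 0.3, 0.1), c(0.01, 0.01, 0.01, 0.001))
  expect_equal(select_min_1se(p3)$id, 4)
  # xerror strictly worsening as the tree shrinks, tiny SE: keep full tree
  p3$table$xerror <- rev(p3$table$xerror)
  expect_equal(select_min_1se(p3)$id, 1)
  # flat profile: the stump qualifies
  p4 <- fake_path(rep(0.5, 4), rep(0.05, 4))
  expect_equal(select_min_1se(p4)$id, 4)
  expect_error(select_min_1se(fake_path(c(NA, 1), c(1, 1))),
               "cross-validated")
})

test_that("feature importance is normalized, zero off-tree, stump-flagged", {
  d <- data.frame(sbr = c(rnorm(30, 0), rnorm(30, 10)),
                  pcr = rnorm(60),
                  group = factor(rep(c("PD", "NPS"), each = 30),
                                 levels = c("NPS", "PD")))
  fit <- grow_tree(d, features = c("pcr", "sbr"), minsplit = 10,
                   minbucket = 5)
  imp <- feature_importance(fit)
  expect_equal(unname(imp[["sbr"]]), 1)
  expect_equal(unname(imp[["pcr"]]), 0)
  co <- generate_cohort(seed = 2)
  fit2 <- grow_tree(co)
  imp2 <- feature_importance(fit2)
  expect_equal(sum(imp2), 1, tolerance = 1e-9)
  expect_true(all(imp2 >= 0))
  expect_setequal(names(imp2), index_features())
  expect_true(all(imp2[setdiff(index_features(),
                               tree_features_used(fit2))] == 0))
  stump <- grow_tree(data.frame(sbr = rnorm(20),
                                group = factor(rep("PD", 20))), "sbr")
  expect_warning(imp3 <- feature_importance(stump), "stump")
  expect_true(all(imp3 == 0))
  expect_true(isTRUE(attr(imp3, "degenerate")))
})

test_that("pruning agrees with rpart's complexity table on a cohort", {
  skip_if_not_installed("rpart")
  co <- generate_cohort(seed = 23)
  fit <- grow_tree(co, minsplit = 20, minbucket = 7)
  path <- prune_path(fit)
  rp <- rpart::rpart(group ~ hm_early + hm_delay + wr + sbr + pcr + ai,
                     data = co, method = "class",
                     control = rpart::rpart.control(minsplit = 20,
                                                    minbucket = 7,
                                                    cp = 0, xval = 0))
  cp <- rp$cptable
  # same nested sizes and resubstitution errors along the path
  expect_equal(rev(path$table$n_leaves), unname(cp[, "nsplit"]) + 1)
  expect_equal(rev(path$table$rel_error), unname(cp[, "rel error"]),
               tolerance = 1e-10)
})
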