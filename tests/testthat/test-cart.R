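test_that("Gini impurity matches its closed form", {
  expect_equal(gini_impurity(c(10, 0, 0, 0, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  counts <- c(80, 90, 21, 16, 9)  # the five-group cohort composition
  expect_equal(gini_impurity(counts), 1 - sum((counts / 216)^2))
  expect_equal(gini_impurity(counts), 0.67254, tolerance = 1e-5)
  expect_error(gini_impurity(c(0, 0)), "positive")
  expect_error(gini_impurity(c(-1, 3)), "non-negative")
})

test_that("a perfectly separating feature is found with the full decrease", {
  d <- data.frame(x = c(1, 2, 3, 11, 12, 13),
                  z = c(5, 7, 5, 7, 5, 7),
                  group = factor(rep(c("NPS", "PD"), each = 3)))
  sp <- best_split(d, features = c("z", "x"), label = "group")
  expect_equal(sp$feature, "x")
  expect_equal(sp$threshold, 7)
  expect_equal(sp$decrease, gini_impurity(c(3, 3)))
})

test_that("constant or pure nodes return the no-split sentinel", {
  d <- data.frame(x = rep(1, 8),
                  group = factor(rep(c("NPS", "PD"), 4)))
  expect_null(best_split(d, "x"))
  d2 <- data.frame(x = rnorm(8), group = factor(rep("PD", 8),
                                                levels = c("NPS", "PD")))
  expect_null(best_split(d2, "x"))
})

test_that("best_split matches the exhaustive oracle on random instances", {
  for (seed in 1:40) {
    d <- random_instance(seed)
    feats <- setdiff(names(d), "group")
    got <- best_split(d, feats, minbucket = 2L)
    want <- oracle_best_split(d, feats, minbucket = 2L)
    if (is.null(want)) {
      expect_null(got, info = paste("seed", seed))
    } else {
      expect_equal(got$feature, want$feature, info = paste("seed", seed))
      expect_equal(got$threshold, want$threshold,
                   info = paste("seed", seed))
    }
  }
})

test_that("single-class data grows a single leaf", {
  d <- data.frame(sbr = rnorm(30), group = factor(rep("PD", 30)))
  fit <- grow_tree(d, features = "sbr", minsplit = 5)
  expect_equal(n_leaves(fit), 1)
  expect_equal(as.character(predict(fit, d)), rep("PD", 30))
})

test_that("linearly separable two-class data grows a depth-1 tree", {
  d <- data.frame(sbr = c(rnorm(20, 0), rnorm(20, 10)),
                  group = factor(rep(c("PD", "NPS"), each = 20),
                                 levels = c("NPS", "PD")))
  fit <- grow_tree(d, features = "sbr", minsplit = 5, minbucket = 2)
  expect_equal(n_leaves(fit), 2)
  expect_equal(sum(as.character(predict(fit, d)) != as.character(d$group)),
               0)
})

test_that("node class counts are conserved down every split", {
  co <- generate_cohort(seed = 3)
  fit <- grow_tree(co)
  check <- function(node) {
    if (parkcart:::is_leaf(node)) return(invisible())
    expect_identical(node$counts, node$left$counts + node$right$counts)
    expect_equal(node$class, names(node$counts)[which.max(node$counts)])
    check(node$left); check(node$right)
  }
  check(fit$root)
  # leaf sizes respect minbucket, and predictions over the data sum to n
  expect_equal(length(predict(fit, co)), nrow(co))
})

test_that("grown trees match the oracle grower split for split", {
  for (seed in c(1:25)) {
    d <- random_instance(seed)
    feats <- setdiff(names(d), "group")
    fit <- grow_tree(d, features = feats, minsplit = 5, minbucket = 2,
                     max_depth = 5)
    want <- oracle_grow(d, feats, minsplit = 5, minbucket = 2,
                        max_depth = 5)
    expect_identical(tree_signature(fit), tree_signature(want),
                     info = paste("seed", seed))
  }
})

test_that("prediction routes boundary values left and validates input", {
  d <- data.frame(sbr = c(1, 1, 2, 2),
                  group = factor(c("PD", "PD", "NPS", "NPS"),
                                 levels = c("NPS", "PD")))
  fit <- grow_tree(d, "sbr", minsplit = 2, minbucket = 1)
  expect_equal(fit$root$threshold, 1.5)
  expect_equal(as.character(predict(fit, data.frame(sbr = 1.5))), "PD")
  expect_equal(as.character(predict(fit, data.frame(sbr = 1.50001))), "NPS")
  expect_error(predict(fit, data.frame(pcr = 1)), "missing features")
  expect_error(predict(fit, data.frame(sbr = NA_real_)), "missing values")
})

test_that("planted thresholds are recovered inside the data gap", {
  set.seed(31)
  for (rep in 1:5) {
    thr <- runif(1, 2, 4)
    gap <- 0.6
    n <- 80
    lo <- runif(n, thr - 2, thr - gap / 2)
    hi <- runif(n, thr + gap / 2, thr + 2)
    d <- data.frame(sbr = c(lo, hi),
                    group = factor(rep(c("PD", "NPS"), each = n),
                                   levels = c("NPS", "PD")))
    fit <- grow_tree(d, "sbr", minsplit = 10, minbucket = 5)
    expect_gt(fit$root$threshold, max(lo))
    expect_lt(fit$root$threshold, min(hi))
  }
})

test_that("the engine agrees with rpart on the first split of a cohort", {
  skip_if_not_installed("rpart")
  co <- generate_cohort(seed = 17)
  fit <- grow_tree(co, minsplit = 20, minbucket = 7)
  rp <- rpart::rpart(group ~ hm_early + hm_delay + wr + sbr + pcr + ai,
                     data = co, method = "class",
                     control = rpart::rpart.control(minsplit = 20,
                                                    minbucket = 7,
                                                    cp = 0, xval = 0))
  expect_equal(fit$root$feature,
               as.character(rp$frame$var[1]))
  expect_equal(fit$root$threshold, unname(rp$splits[1, "index"]),
               tolerance = 1e-8)
})
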