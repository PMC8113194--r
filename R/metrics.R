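#' One-vs-rest confusion counts for one class
#'
#' Dichotomizes multiclass truth and prediction vectors against a single
#' class: TP = truth and prediction both equal the class, FP = prediction
#' equals the class but truth does not, FN = truth equals the class but the
#' prediction does not, TN = neither does.
#'
#' @param truth,predicted Equal-length label vectors (character or factor).
#' @param class_label The class to dichotomize against; must appear in the
#'   union of observed and allowed labels.
#' @return Named integer vector `c(TP, FP, FN, TN)` summing to the number
#'   of patients.
#' @export
confusion_counts <- function(truth, predicted, class_label) {
  if (length(truth) != length(predicted))
    stop_input("truth (%d) and predicted (%d) lengths differ",
               length(truth), length(predicted))
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (anyNA(truth) || anyNA(predicted))
    stop_input("labels must not contain missing values")
  known <- diagnostic_groups()
  bad <- setdiff(unique(c(truth, predicted)), known)
  if (length(bad))
    stop_input("unknown labels: %s", paste(bad, collapse = ", "))
  if (!class_label %in% known)
    stop_input("unknown class label '%s'", class_label)
  t_pos <- truth == class_label
  p_pos <- predicted == class_label
  c(TP = sum(t_pos & p_pos), FP = sum(!t_pos & p_pos),
    FN = sum(t_pos & !p_pos), TN = sum(!t_pos & !p_pos))
}

#' Diagnostic metrics from one-vs-rest confusion counts
#'
#' Sensitivity `100*TP/(TP+FN)`, specificity `100*TN/(TN+FP)`, positive and
#' negative predictive values `100*TP/(TP+FP)` / `100*TN/(TN+FN)`, and
#' accuracy `100*(TP+TN)/n`, all as percentages at full precision (use
#' [round_half_up()] for one-decimal display). A metric whose denominator
#' is zero is returned as `NA` (undefined), not as 0.
#'
#' @param counts Named vector with `TP`, `FP`, `FN`, `TN` (as from
#'   [confusion_counts()]), or the four counts in that order.
#' @return Named list with the four counts, `n`, and the five percentage
#'   metrics.
#' @export
#' @examples
#' class_metrics(c(TP = 70, FP = 5, FN = 10, TN = 131))$sensitivity  # 87.5
class_metrics <- function(counts) {
  if (is.null(names(counts))) names(counts) <- c("TP", "FP", "FN", "TN")
  need <- c("TP", "FP", "FN", "TN")
  if (!all(need %in% names(counts)))
    stop_input("counts must contain TP, FP, FN and TN")
  counts <- counts[need]
  if (any(counts < 0) || any(counts != round(counts)))
    stop_input("confusion counts must be non-negative integers")
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  fn <- counts[["FN"]]; tn <- counts[["TN"]]
  n <- tp + fp + fn + tn
  if (n == 0) stop_input("confusion counts sum to zero")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(TP = tp, FP = fp, FN = fn, TN = tn, n = n,
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn),
       accuracy = ratio(tp + tn, n))
}

#' Per-class diagnostic performance of a prediction vector
#'
#' One row per class: one-vs-rest confusion counts and the five derived
#' percentages. Classes the classifier can never predict (MSA under the
#' published tree) still get a row — their sensitivity is 0 and their PPV
#' undefined — and are flagged.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Classes to report; defaults to every group label present
#'   in `truth` (in [diagnostic_groups()] order).
#' @return Data frame with columns `class`, `TP`, `FP`, `FN`, `TN`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`,
#'   `never_predicted`.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' diagnostic_metrics(cohort$group, classify_cohort(cohort))
diagnostic_metrics <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) {
    classes <- intersect(diagnostic_groups(), unique(as.character(truth)))
  }
  rows <- lapply(classes, function(cl) {
    m <- class_metrics(confusion_counts(truth, predicted, cl))
    data.frame(class = cl, TP = m$TP, FP = m$FP, FN = m$FN, TN = m$TN,
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, npv = m$npv, accuracy = m$accuracy,
               never_predicted = !cl %in% as.character(predicted),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis comparison of one index across the diagnostic groups
#'
#' Rank-based omnibus test (with tie correction) of whether the
#' distribution of a quantitative index differs between the groups; wraps
#' `stats::kruskal.test`.
#'
#' @param cohort Cohort data frame with a `group` column and the index
#'   column.
#' @param index_name Name of the index column to test.
#' @return List with `statistic` (H), `df`, `p_value`, `index` and `n`.
#' @export
kruskal_wallis <- function(cohort, index_name) {
  if (!index_name %in% names(cohort))
    stop_input("cohort has no column '%s'", index_name)
  g <- factor(cohort$group)
  g <- droplevels(g)
  if (nlevels(g) < 2) stop_input("need at least two non-empty groups")
  ht <- stats::kruskal.test(cohort[[index_name]], g)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, index = index_name, n = nrow(cohort))
}

#' Pairwise post hoc comparisons with Bonferroni correction
#'
#' Follow-up to the Kruskal-Wallis omnibus test over all unordered group
#' pairs. The default is Dunn's rank-based z-test (large-sample z statistic
#' on the difference of mean ranks from the joint ranking, with tie
#' correction); pairwise two-sided Wilcoxon rank-sum tests are available as
#' an alternative. Raw p-values are multiplied by the number of pairs and
#' capped at 1.
#'
#' @param cohort Cohort data frame with a `group` column and the index.
#' @param index_name Name of the index column.
#' @param method `"dunn"` (default) or `"wilcoxon"`.
#' @return Data frame with one row per unordered group pair: `group1`,
#'   `group2`, `statistic` (z for Dunn, W for Wilcoxon), `p_raw`,
#'   `p_adjusted`.
#' @export
posthoc_bonferroni <- function(cohort, index_name,
                               method = c("dunn", "wilcoxon")) {
  method <- match.arg(method)
  if (!index_name %in% names(cohort))
    stop_input("cohort has no column '%s'", index_name)
  g <- droplevels(factor(cohort$group))
  if (nlevels(g) < 2) stop_input("need at least two non-empty groups")
  x <- cohort[[index_name]]
  if (anyNA(x)) stop_input("index '%s' contains missing values", index_name)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  n_pairs <- ncol(pairs)

  if (method == "dunn") {
    r <- rank(x)
    n <- length(x)
    nj <- table(g)
    rbar <- tapply(r, g, mean)
    ties <- table(x)
    tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
    res <- lapply(seq_len(n_pairs), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / nj[[a]] + 1 / nj[[b]]))
      z <- (rbar[[a]] - rbar[[b]]) / se
      p <- 2 * stats::pnorm(-abs(z))
      data.frame(group1 = a, group2 = b, statistic = z, p_raw = p,
                 stringsAsFactors = FALSE)
    })
  } else {
    res <- lapply(seq_len(n_pairs), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      wt <- suppressWarnings(stats::wilcox.test(x[g == a], x[g == b]))
      data.frame(group1 = a, group2 = b, statistic = unname(wt$statistic),
                 p_raw = wt$p.value, stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(1, out$p_raw * n_pairs)
  rownames(out) <- NULL
  out
}
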