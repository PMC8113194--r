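fixed_leaf <- function(class) {
  structure(list(n = NA_integer_, counts = NULL, class = class,
                 impurity = NA_real_, feature = NULL, threshold = NULL,
                 decrease = NULL, left = NULL, right = NULL),
            class = "cart_node")
}

fixed_split <- function(feature, threshold, left, right) {
  structure(list(n = NA_integer_, counts = NULL, class = NA_character_,
                 impurity = NA_real_, feature = feature,
                 threshold = threshold, decrease = NULL,
                 left = left, right = right),
            class = "cart_node")
}

#' The published optimal decision tree for Parkinsonian syndromes
#'
#' The fixed four-split classifier reported for the 216-patient clinical
#' cohort, using the putamen-to-caudate ratio, cardiac washout rate,
#' delayed heart-to-mediastinum ratio and striatal binding ratio with
#' cutoffs 0.81, 44.55, 2.26 and 0.91 (values at a cutoff route left, i.e.
#' with the low side):
#'
#' * PCR > 0.81 (preserved putaminal uptake): WR <= 44.55 gives NPS,
#'   WR > 44.55 gives DLB;
#' * PCR <= 0.81: H/M(Delay) <= 2.26 gives PD; H/M(Delay) > 2.26 with
#'   SBR <= 0.91 gives PSP, and with SBR > 0.91 gives PD.
#'
#' The early H/M ratio and the asymmetry index are never consulted, and
#' MSA is never an output label (the source cohort's tree could not
#' separate it). The exact arrangement of the two PD leaves is a
#' documented reconstruction: the residual leaf (PCR <= 0.81,
#' H/M(Delay) > 2.26, SBR > 0.91) is assigned PD by default and the whole
#' topology can be overridden via `file`.
#'
#' @param file Optional path to a tree JSON file (schema of
#'   [tree_to_json()]) replacing the built-in topology.
#' @return A `cart_tree` with class levels `NPS, PD, DLB, PSP, MSA`.
#' @export
#' @examples
#' classify_patient(c(pcr = 0.85, wr = 29.3, hm_delay = 2.72, sbr = 2.13))
published_tree <- function(file = NULL) {
  if (!is.null(file)) {
    tree <- tree_from_json(file)
    return(tree)
  }
  root <- fixed_split(
    "pcr", 0.81,
    left = fixed_split(
      "hm_delay", 2.26,
      left = fixed_leaf("PD"),
      right = fixed_split(
        "sbr", 0.91,
        left = fixed_leaf("PSP"),
        right = fixed_leaf("PD")
      )
    ),
    right = fixed_split(
      "wr", 44.55,
      left = fixed_leaf("NPS"),
      right = fixed_leaf("DLB")
    )
  )
  structure(list(root = root,
                 features = index_features(),
                 classes = diagnostic_groups(),
                 n = NA_integer_,
                 params = list(source = "published")),
            class = "cart_tree")
}

#' Classify one patient with the published tree
#'
#' @param x Named numeric vector, list, or one-row data frame with at
#'   least the indices the tree consults (`pcr`, `wr`, `hm_delay`, `sbr`);
#'   all four must be present and non-missing.
#' @param tree The classifier; defaults to [published_tree()].
#' @return A single factor label, one of NPS, PD, DLB, PSP (never MSA for
#'   the default tree).
#' @export
classify_patient <- function(x, tree = published_tree()) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop_input("x must describe exactly one patient")
  } else {
    x <- as.data.frame(as.list(x))
  }
  need <- tree_features_used(tree)
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop_input("patient is missing required indices: %s",
               paste(missing, collapse = ", "))
  if (anyNA(x[need]))
    stop_input("required indices contain missing values")
  predict(tree, x)[[1]]
}

#' Classify a cohort with the published tree
#'
#' @param cohort Cohort data frame (see [generate_cohort()]) with the
#'   index columns the tree consults.
#' @param tree The classifier; defaults to [published_tree()].
#' @return Factor of predicted labels, one per row of `cohort`.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' table(truth = cohort$group, predicted = classify_cohort(cohort))
classify_cohort <- function(cohort, tree = published_tree()) {
  if (!is.data.frame(cohort)) stop_input("cohort must be a data frame")
  if (nrow(cohort) == 0L)
    return(factor(character(0), levels = tree$classes))
  predict(tree, cohort)
}
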