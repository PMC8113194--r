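#' Generate a seeded synthetic cohort of quantitative indices
#'
#' Draws per-patient values of the six quantitative indices from independent
#' truncated normal distributions whose means and standard deviations come
#' from per-group marginal models (by default the built-in five-group
#' models of [default_group_models()]). Only marginal moments are modelled;
#' a between-index dependence structure can be imposed through a Gaussian
#' copula by supplying a correlation matrix, but none is assumed by default.
#'
#' Sampling is inverse-CDF on copula uniforms, so identical
#' `(models, sizes, seed, correlation)` produce bit-identical cohorts.
#'
#' @param models A `group_models` data frame (see [default_group_models()]).
#' @param sizes Named vector of per-group sample sizes; names must be a
#'   subset of the model's group labels, all sizes positive integers.
#' @param seed Integer seed controlling all randomness.
#' @param correlation Optional 6x6 between-index correlation matrix (rows
#'   and columns in [index_features()] order), or a named list of such
#'   matrices keyed by group. Must be symmetric positive semi-definite with
#'   unit diagonal. `NULL` (the default) means independent indices.
#' @return A data frame (the cohort table) with columns `patient_id`,
#'   `group` (factor with the five group levels) and the six index columns,
#'   one row per simulated patient, grouped in `names(sizes)` order.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' nrow(cohort)  # 216
generate_cohort <- function(models = default_group_models(),
                            sizes = default_group_sizes(),
                            seed = 1L,
                            correlation = NULL) {
  validate_group_models(models)
  idx <- index_features()
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop_input("sizes must be a named vector of per-group counts")
  unknown <- setdiff(names(sizes), unique(models$group))
  if (length(unknown))
    stop_input("sizes name groups absent from the models: %s",
               paste(unknown, collapse = ", "))
  if (any(!is.finite(sizes)) || any(sizes < 1) || any(sizes != round(sizes)))
    stop_input("all group sizes must be positive integers")

  corr_for <- function(group) {
    cm <- if (is.list(correlation)) correlation[[group]] else correlation
    if (is.null(cm)) return(NULL)
    validate_correlation(cm, length(idx))
    cm
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  pieces <- vector("list", length(sizes))
  for (g in seq_along(sizes)) {
    group <- names(sizes)[g]
    n <- as.integer(sizes[[g]])
    u <- copula_uniforms(n, length(idx), corr_for(group))
    m <- models[models$group == group, , drop = FALSE]
    m <- m[match(idx, m$index), , drop = FALSE]
    if (anyNA(m$index))
      stop_input("models for group %s must cover all six indices", group)
    x <- matrix(NA_real_, n, length(idx), dimnames = list(NULL, idx))
    for (j in seq_along(idx)) {
      x[, j] <- qtruncnorm(u[, j], m$mean[j], m$sd[j], m$lower[j], m$upper[j])
    }
    pieces[[g]] <- data.frame(group = group, x, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(nrow(out))),
                    out, stringsAsFactors = FALSE)
  out$group <- factor(out$group, levels = diagnostic_groups())
  rownames(out) <- NULL
  out
}

validate_correlation <- function(cm, p) {
  if (!is.matrix(cm) || !is.numeric(cm) || any(dim(cm) != p))
    stop_input("correlation must be a %dx%d numeric matrix", p, p)
  if (max(abs(cm - t(cm))) > 1e-10)
    stop_input("correlation matrix must be symmetric")
  if (max(abs(diag(cm) - 1)) > 1e-10)
    stop_input("correlation matrix must have unit diagonal")
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_input("correlation matrix must be positive semi-definite")
  invisible(cm)
}

# n x p matrix of copula uniforms: independent when corr is NULL, otherwise
# Gaussian-copula dependent via an eigendecomposition square root (tolerates
# exact semi-definiteness, unlike Cholesky).
copula_uniforms <- function(n, p, corr = NULL) {
  if (is.null(corr)) {
    return(matrix(stats::runif(n * p), n, p))
  }
  e <- eigen(corr, symmetric = TRUE)
  root <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors)
  z <- matrix(stats::rnorm(n * p), n, p) %*% root
  stats::pnorm(z)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Write / read a cohort table as CSV
#'
#' Plain CSV with header `patient_id,group,hm_early,hm_delay,wr,sbr,pcr,ai`.
#'
#' @param cohort A cohort data frame as returned by [generate_cohort()].
#' @param file Path to the CSV file.
#' @return `write_cohort_csv` returns `file` invisibly; `read_cohort_csv`
#'   returns the cohort data frame with `group` as a factor.
#' @export
write_cohort_csv <- function(cohort, file) {
  cols <- c("patient_id", "group", index_features())
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    stop_input("cohort is missing columns: %s", paste(missing, collapse = ", "))
  utils::write.csv(cohort[, cols], file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE)
  cols <- c("patient_id", "group", index_features())
  missing <- setdiff(cols, names(out))
  if (length(missing))
    stop_input("cohort CSV is missing columns: %s", paste(missing, collapse = ", "))
  bad <- setdiff(unique(out$group), diagnostic_groups())
  if (length(bad))
    stop_input("unknown group labels in cohort CSV: %s", paste(bad, collapse = ", "))
  out$group <- factor(out$group, levels = diagnostic_groups())
  out
}
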