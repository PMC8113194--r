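# Deterministic per-stage child seeds fanned out from the run seed, so each
# stage is independently reproducible: seed_stage = (seed * 1009 + offset)
# mod 2^31 - 1, with a fixed offset per stage name.
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 11L, noise = 23L, cv = 37L, stats = 53L)
  if (!stage %in% names(offsets)) stop_input("unknown stage '%s'", stage)
  as.integer((as.double(seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

#' Run the full diagnostic pipeline on a synthetic cohort
#'
#' Seeded end-to-end run: simulate a cohort from per-group marginal models,
#' classify it (with the published fixed tree, or with a tree fitted to the
#' cohort by CART + cross-validation + Min-1SE pruning, or with a tree
#' loaded from JSON), compute per-class diagnostic metrics and per-index
#' group statistics, and write every artifact to `out_dir`: the cohort CSV,
#' tree JSON and DOT, the pruning-path table, the feature-importance table,
#' the metrics CSV, the statistics report and a manifest recording the
#' resolved configuration.
#'
#' @param seed Integer run seed; per-stage child seeds are derived from it.
#' @param out_dir Output directory (created if needed); `NULL` computes
#'   everything in memory and writes nothing.
#' @param tree_source `"published"`, `"fit"`, or a path to a tree JSON
#'   file.
#' @param models Per-group marginal models (default
#'   [default_group_models()]).
#' @param sizes Named per-group sizes (default [default_group_sizes()]).
#' @param correlation Optional between-index correlation (see
#'   [generate_cohort()]).
#' @param minsplit,minbucket,max_depth,folds CART growth and
#'   cross-validation controls, used when `tree_source = "fit"`.
#' @param config Optional path to a YAML file supplying any of the above
#'   (explicit arguments win over the file).
#' @return Invisibly, a list with `cohort`, `tree`, `predictions`,
#'   `metrics`, `stats`, `importance` (fit mode only), `prune_table` (fit
#'   mode only) and `manifest`.
#' @export
#' @examples
#' run <- run_pipeline(seed = 1)
#' run$metrics
run_pipeline <- function(seed = 1L, out_dir = NULL,
                         tree_source = c("published", "fit"),
                         models = NULL, sizes = NULL, correlation = NULL,
                         minsplit = 20L, minbucket = 7L, max_depth = 30L,
                         folds = 10L, config = NULL) {
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    if (missing(seed) && !is.null(cfg$seed)) seed <- cfg$seed
    if (missing(tree_source) && !is.null(cfg$tree_source))
      tree_source <- cfg$tree_source
    if (is.null(sizes) && !is.null(cfg$sizes)) sizes <- unlist(cfg$sizes)
    if (missing(minsplit) && !is.null(cfg$minsplit)) minsplit <- cfg$minsplit
    if (missing(minbucket) && !is.null(cfg$minbucket)) minbucket <- cfg$minbucket
    if (missing(folds) && !is.null(cfg$folds)) folds <- cfg$folds
  }
  if (is.null(models)) models <- default_group_models()
  if (is.null(sizes)) sizes <- default_group_sizes()
  if (length(tree_source) > 1L || tree_source %in% c("published", "fit")) {
    tree_source <- match.arg(tree_source)
  }

  cohort <- generate_cohort(models, sizes, seed = stage_seed(seed, "cohort"),
                            correlation = correlation)

  importance <- NULL
  prune_table <- NULL
  if (identical(tree_source, "fit")) {
    path <- cross_validate(cohort, minsplit = minsplit,
                           minbucket = minbucket, max_depth = max_depth,
                           folds = folds, seed = stage_seed(seed, "cv"))
    tree <- select_min_1se(path)
    prune_table <- path$table
    importance <- feature_importance(tree)
  } else if (identical(tree_source, "published")) {
    tree <- published_tree()
  } else {
    tree <- published_tree(file = tree_source)
  }

  predictions <- classify_cohort(cohort, tree)
  metrics <- diagnostic_metrics(cohort$group, predictions,
                                classes = diagnostic_groups())
  stats_report <- lapply(index_features(), function(idx) {
    kw <- kruskal_wallis(cohort, idx)
    list(index = idx, kruskal_wallis = kw,
         pairwise = if (kw$p_value < 0.05)
           posthoc_bonferroni(cohort, idx))
  })
  names(stats_report) <- index_features()

  manifest <- list(
    seed = as.integer(seed),
    stage_seeds = list(cohort = stage_seed(seed, "cohort"),
                       cv = stage_seed(seed, "cv")),
    tree_source = tree_source,
    sizes = as.list(sizes),
    cart = list(minsplit = as.integer(minsplit),
                minbucket = as.integer(minbucket),
                max_depth = as.integer(max_depth),
                folds = as.integer(folds)),
    package_version = as.character(utils::packageVersion("parkcart"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    tree_to_json(tree, file.path(out_dir, "tree.json"))
    tree_to_dot(tree, file.path(out_dir, "tree.dot"))
    out_metrics <- metrics
    for (col in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
      out_metrics[[col]] <- round_half_up(out_metrics[[col]], 1)
    utils::write.csv(out_metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(prune_table))
      utils::write.csv(prune_table, file.path(out_dir, "prune_path.csv"),
                       row.names = FALSE)
    if (!is.null(importance))
      utils::write.csv(data.frame(feature = names(importance),
                                  importance = as.numeric(importance)),
                       file.path(out_dir, "importance.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      lapply(stats_report, function(s) {
        list(index = s$index,
             statistic = s$kruskal_wallis$statistic,
             df = s$kruskal_wallis$df,
             p_value = s$kruskal_wallis$p_value,
             pairwise = s$pairwise)
      }),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(cohort = cohort, tree = tree, predictions = predictions,
                 metrics = metrics, stats = stats_report,
                 importance = importance, prune_table = prune_table,
                 manifest = manifest))
}
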