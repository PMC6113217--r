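#' Default pipeline configuration
#'
#' Returns the resolved configuration for [run_pipeline()], with every
#' tunable at its default. Unknown keys in `...` are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param edges Path to the edge-list TSV.
#' @param positives Path to the positive gene list.
#' @param gaf Path to the GAF annotation file.
#' @param out_dir Output directory for all artifacts.
#' @param ... Overrides for the tunables: `repeats` (default 1001),
#'   `folds` (5), `cost` (1), `threshold` (0.5, CV confusion cutoff),
#'   `candidate_threshold` (0.9), `min_n` (5), `a` (1), `log_base`
#'   (`exp(1)`), `scale` (FALSE; see [assemble_features()]),
#'   `base_seed` (1), `sep` ("\t"), `header` (FALSE), `aspect` ("P").
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(edges, positives, gaf, out_dir, ...) {
  cfg <- list(edges = edges, positives = positives, gaf = gaf,
              out_dir = out_dir, repeats = 1001, folds = 5, cost = 1,
              threshold = 0.5, candidate_threshold = 0.9, min_n = 5,
              a = 1, log_base = exp(1), scale = FALSE, base_seed = 1,
              sep = "\t", header = FALSE, aspect = "P")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full prioritization pipeline
#'
#' Executes every stage end to end: load and clean the network, read the
#' seed genes and annotations, compute topology and GO features, screen
#' features by KS test, run the balanced negative-resampling evaluation,
#' select the median-AUC model, and rank the unlabeled genes. Every
#' intermediate artifact plus the resolved configuration is written under
#' `config$out_dir`; with a fixed `base_seed` two runs produce identical
#' outputs.
#'
#' @param config A `run_config` from [pipeline_config()].
#' @return Invisibly, a list with `features`, `ks`, `summary`,
#'   `manifest`, `best_run_index`, `predictions` and `paths` of the
#'   written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  net <- stage("graph_core", load_edge_list(config$edges,
                                            sep = config$sep,
                                            header = config$header))
  pos <- stage("graph_core", read_gene_list(config$positives))
  ann <- stage("go_scoring", load_gaf(config$gaf, aspect = config$aspect))

  universe <- igraph::V(net)$name
  topo <- stage("graph_core", topology_table(net, pos))
  ts <- stage("go_scoring",
              score_all_terms(ann, pos, universe, min_n = config$min_n,
                              a = config$a, base = config$log_base))
  gs <- stage("go_scoring", gene_go_scores(ann, ts, universe,
                                           positives = pos))
  feats <- stage("learning",
                 assemble_features(topo, gs, pos, scale = config$scale))
  ks <- stage("stats_compare", compare_groups(feats))

  rt <- stage("learning",
              resample_train(feats, repeats = config$repeats,
                             base_seed = config$base_seed,
                             folds = config$folds, cost = config$cost,
                             threshold = config$threshold))
  best <- stage("learning", select_median_auc_run(rt$runs))
  preds <- stage("predict",
                 predict_unlabeled(best$model, feats,
                                   threshold = config$candidate_threshold))

  paths <- list(
    config = file.path(config$out_dir, "config.json"),
    features = file.path(config$out_dir, "features.tsv"),
    term_scores = file.path(config$out_dir, "term_scores.tsv"),
    ks = file.path(config$out_dir, "ks_report.tsv"),
    manifest = file.path(config$out_dir, "run_manifest.tsv"),
    summary = file.path(config$out_dir, "summary.json"),
    predictions = file.path(config$out_dir, "predictions.tsv")
  )
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       digits = NA)
  write_tsv <- function(d, p) utils::write.table(
    d, p, sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(feats, paths$features)
  write_tsv(ts, paths$term_scores)
  write_tsv(ks, paths$ks)
  write_tsv(rt$manifest, paths$manifest)
  jsonlite::write_json(
    list(summary = rt$summary, best_run_index = best$run_index,
         n_candidates = sum(preds$candidate)),
    paths$summary, auto_unbox = TRUE, digits = NA)
  write_tsv(preds, paths$predictions)

  invisible(list(features = feats, ks = ks, summary = rt$summary,
                 manifest = rt$manifest, best_run_index = best$run_index,
                 predictions = preds, paths = paths))
}
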