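#' Build a label-conditional feature oracle
#'
#' Returns a function `f(positives)` that produces the full feature table
#' computed with respect to the given seed set. The label-independent
#' topology columns (degree, degree2, kcore, betweenness) are computed
#' once and cached; each call recomputes only the label-dependent
#' columns (`ratio1`, `ratio2`, `go_score`). Pass the result as
#' `feature_fn` to [cv_evaluate()] or [resample_train()] to evaluate in
#' fold-safe mode, where held-out genes' labels never reach the
#' features the model trains on.
#'
#' @param net An igraph network.
#' @param ann An `annotation_set`.
#' @param min_n,a,base Passed to [score_all_terms()].
#' @param loo Use leave-self-out GO scoring (see [gene_go_scores()])?
#' @return Function mapping a character vector of positives to a feature
#'   table (same shape as [assemble_features()] output).
#' @export
feature_builder <- function(net, ann, min_n = 5, a = 1, base = exp(1),
                            loo = TRUE) {
  genes <- sort(igraph::V(net)$name)
  base_topo <- topology_table(net, positives = character(0))
  nb1 <- igraph::adjacent_vertices(net, v = genes)
  nb1 <- lapply(nb1, function(v) v$name)
  nb2 <- igraph::ego(net, order = 2, nodes = genes, mindist = 2)
  nb2 <- lapply(nb2, function(v) v$name)

  function(positives) {
    topo <- base_topo
    topo$ratio1 <- vapply(nb1, function(nb) {
      if (length(nb) == 0) 0 else sum(nb %in% positives) / length(nb)
    }, numeric(1))
    topo$ratio2 <- vapply(nb2, function(nb) {
      if (length(nb) == 0) 0 else sum(nb %in% positives) / length(nb)
    }, numeric(1))
    ts <- score_all_terms(ann, positives, genes, min_n = min_n, a = a,
                          base = base)
    gs <- gene_go_scores(ann, ts, genes,
                         positives = if (loo) positives else NULL)
    assemble_features(topo, gs, positives)
  }
}
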