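#' Degree of a gene
#'
#' Number of direct interaction partners of the gene in the network.
#'
#' @param net An igraph network.
#' @param gene Gene identifier; must be a network node.
#' @return Non-negative integer degree.
#' @export
gene_degree <- function(net, gene) {
  assert_gene(net, gene)
  as.integer(igraph::degree(net, v = gene))
}

#' Second-step interaction partners
#'
#' Nodes at shortest-path distance exactly 2 from the gene: the gene
#' itself and its direct neighbors are excluded, so the second
#' neighborhood parallels the first (direct partners) at step two.
#'
#' @inheritParams gene_degree
#' @return Character vector of identifiers (possibly empty), sorted.
#' @export
second_neighbors <- function(net, gene) {
  assert_gene(net, gene)
  nb2 <- igraph::ego(net, order = 2, nodes = gene, mindist = 2)[[1]]
  sort(nb2$name)
}

#' K-core number of every node
#'
#' The core number of a node is the largest K such that the node survives
#' recursive removal of all nodes with degree less than K.
#'
#' @param net An igraph network.
#' @return Named integer vector, one entry per node.
#' @export
kcore_number <- function(net) {
  k <- igraph::coreness(net)
  storage.mode(k) <- "integer"
  k
}

#' Unnormalized betweenness centrality of every node
#'
#' For each node i, the sum over unordered pairs \{j, k\} (both distinct
#' from i) of the fraction of shortest j--k paths that pass through i.
#' Pairs with no connecting path contribute 0; values are not rescaled, so
#' on large networks they reach the tens of thousands.
#'
#' @param net An igraph network.
#' @return Named numeric vector, one entry per node.
#' @export
betweenness_centrality <- function(net) {
  igraph::betweenness(net, directed = FALSE, normalized = FALSE)
}

#' First- and second-neighborhood seed-gene ratios
#'
#' `ratio1` is the fraction of the gene's direct neighbors that are seed
#' (positive) genes; `ratio2` is the fraction of its distance-2 neighbors
#' that are seed genes. A gene's own label never enters either numerator
#' (its neighborhoods exclude itself by construction). Empty
#' neighborhoods give 0 rather than NaN so the feature stays total.
#'
#' @inheritParams gene_degree
#' @param positives Character vector of seed gene identifiers.
#' @return Named list with `ratio1` and `ratio2`.
#' @export
label_ratios <- function(net, positives, gene) {
  assert_gene(net, gene)
  nb1 <- igraph::neighbors(net, gene)$name
  nb2 <- second_neighbors(net, gene)
  r1 <- if (length(nb1) == 0) 0 else sum(nb1 %in% positives) / length(nb1)
  r2 <- if (length(nb2) == 0) 0 else sum(nb2 %in% positives) / length(nb2)
  list(ratio1 = r1, ratio2 = r2)
}

#' Per-gene topology feature table
#'
#' Assembles, for every network node, the five topology features used to
#' characterize disease genes: degree, number of distance-2 partners,
#' K-core number, unnormalized betweenness, and the first/second
#' seed-neighborhood ratios.
#'
#' @param net An igraph network.
#' @param positives Character vector of seed gene identifiers (entries
#'   absent from the network are ignored for coverage but still count as
#'   labels of neighbors they do not have, i.e. harmlessly).
#' @return A data.frame with columns `gene`, `degree`, `degree2`, `kcore`,
#'   `betweenness`, `ratio1`, `ratio2`, `label` ("positive" for nodes in
#'   `positives`, "unlabeled" otherwise), one row per node, ordered by
#'   gene identifier.
#' @export
topology_table <- function(net, positives) {
  genes <- sort(igraph::V(net)$name)
  deg <- igraph::degree(net)[genes]
  kc <- kcore_number(net)[genes]
  btw <- betweenness_centrality(net)[genes]
  is_pos <- genes %in% positives

  nb1_all <- igraph::adjacent_vertices(net, v = genes)
  nb2_all <- igraph::ego(net, order = 2, nodes = genes, mindist = 2)
  r1 <- vapply(seq_along(genes), function(i) {
    nb <- nb1_all[[i]]$name
    if (length(nb) == 0) 0 else sum(nb %in% positives) / length(nb)
  }, numeric(1))
  d2 <- vapply(nb2_all, length, integer(1))
  r2 <- vapply(seq_along(genes), function(i) {
    nb <- nb2_all[[i]]$name
    if (length(nb) == 0) 0 else sum(nb %in% positives) / length(nb)
  }, numeric(1))

  data.frame(
    gene = genes,
    degree = as.integer(deg),
    degree2 = as.integer(d2),
    kcore = as.integer(kc),
    betweenness = as.numeric(btw),
    ratio1 = r1,
    ratio2 = r2,
    label = ifelse(is_pos, "positive", "unlabeled"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
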