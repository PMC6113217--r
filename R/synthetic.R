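#' Specification for a synthetic prioritization benchmark
#'
#' The generator emulates the statistical structure the analysis assumes
#' of real disease genes on a PPI network: a heavy-tailed degree
#' distribution (preferential attachment), disease genes drawn toward
#' hubs (`hub_bias`), extra interactions among disease genes
#' (`intra_edge_boost`), and over-representation of disease genes in a
#' subset of annotation terms (`enrichment_odds`). Every stochastic
#' component draws from its own named substream of `seed`, so the
#' network, labels, boost edges and annotations can be regenerated
#' independently.
#'
#' @param n_genes Number of genes (network nodes).
#' @param attachment_m Edges added per new node in preferential
#'   attachment.
#' @param n_positives Number of disease (seed) genes.
#' @param hub_bias Exponent b >= 0: positives are sampled with
#'   probability proportional to degree^b (0 = uniform).
#' @param intra_edge_boost Extra edges added between random non-adjacent
#'   positive pairs.
#' @param n_terms Number of annotation terms.
#' @param genes_per_term Length-2 integer range of genes per term.
#' @param enriched_terms Number of terms in which positives are
#'   over-represented.
#' @param enrichment_odds Sampling-weight multiplier for positives in
#'   enriched terms (> 1 plants enrichment; 1 = null).
#' @param seed Master integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000, attachment_m = 3,
                           n_positives = 100, hub_bias = 1,
                           intra_edge_boost = 150, n_terms = 200,
                           genes_per_term = c(10, 100),
                           enriched_terms = 20, enrichment_odds = 5,
                           seed = 7) {
  stopifnot(n_positives < n_genes, enriched_terms <= n_terms,
            length(genes_per_term) == 2,
            genes_per_term[1] <= genes_per_term[2],
            hub_bias >= 0, enrichment_odds >= 1)
  structure(list(n_genes = n_genes, attachment_m = attachment_m,
                 n_positives = n_positives, hub_bias = hub_bias,
                 intra_edge_boost = intra_edge_boost, n_terms = n_terms,
                 genes_per_term = genes_per_term,
                 enriched_terms = enriched_terms,
                 enrichment_odds = enrichment_odds, seed = seed),
            class = "synthetic_spec")
}

# Named substreams of the master seed keep components independently
# regenerable; kept within 32-bit integer range.
substream <- function(seed, name) {
  off <- c(network = 101L, labels = 202L, boost = 303L,
           annotations = 404L)[[name]]
  as.integer((as.numeric(seed) + off) %% (.Machine$integer.max - 1L))
}

#' Generate a synthetic benchmark instance
#'
#' Builds the network, disease-gene labels and annotations described by
#' the spec, optionally writing them in exactly the formats the readers
#' consume (edge-list TSV, one-per-line gene list, GAF 2.2) plus a
#' ground-truth JSON manifest. Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Directory to write `edges.tsv`, `positives.txt`,
#'   `annotations.gaf` and `truth.json` into (created if missing);
#'   `NULL` skips writing.
#' @return List with `network` (igraph), `positives` (character),
#'   `annotations` (`annotation_set`), `enriched_term_ids` (character)
#'   and `spec`.
#' @export
generate_synthetic <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- sprintf("G%05d", seq_len(spec$n_genes))

  g <- with_seed(substream(spec$seed, "network"), {
    pa <- igraph::sample_pa(spec$n_genes, power = 1,
                            m = spec$attachment_m, directed = FALSE)
    igraph::set_vertex_attr(pa, "name", value = genes)
  })
  g <- igraph::simplify(g)

  deg <- igraph::degree(g)
  w <- if (spec$hub_bias == 0) rep(1, spec$n_genes) else deg^spec$hub_bias
  positives <- with_seed(substream(spec$seed, "labels"),
                         sort(sample(genes, spec$n_positives, prob = w)))

  if (spec$intra_edge_boost > 0) {
    pairs <- t(utils::combn(positives, 2))
    have <- igraph::get_edge_ids(g, t(pairs)) > 0
    open <- pairs[!have, , drop = FALSE]
    if (nrow(open) < spec$intra_edge_boost) {
      stop("intra_edge_boost (", spec$intra_edge_boost,
           ") exceeds the ", nrow(open),
           " available non-adjacent positive pairs")
    }
    pick <- with_seed(substream(spec$seed, "boost"),
                      sample(nrow(open), spec$intra_edge_boost))
    g <- igraph::add_edges(g, t(open[pick, , drop = FALSE]))
  }

  terms <- sprintf("GO:%07d", seq_len(spec$n_terms))
  enriched <- terms[seq_len(spec$enriched_terms)]
  term_genes <- with_seed(substream(spec$seed, "annotations"), {
    lapply(terms, function(tm) {
      s <- sample(seq(spec$genes_per_term[1], spec$genes_per_term[2]), 1)
      wt <- rep(1, spec$n_genes)
      if (tm %in% enriched) {
        wt[genes %in% positives] <- spec$enrichment_odds
      }
      sort(sample(genes, s, prob = wt))
    })
  })
  names(term_genes) <- terms
  ann <- structure(term_genes, class = "annotation_set", aspect = "P")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    el <- igraph::as_edgelist(g)
    utils::write.table(el, file.path(out_dir, "edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(positives, file.path(out_dir, "positives.txt"))
    write_gaf(ann, file.path(out_dir, "annotations.gaf"))
    jsonlite::write_json(
      list(positives = positives, enriched_term_ids = enriched,
           spec = unclass(spec)),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }

  list(network = g, positives = positives, annotations = ann,
       enriched_term_ids = enriched, spec = spec)
}

#' Write an annotation set as a GAF 2.2 file
#'
#' @param ann An `annotation_set`.
#' @param path Output file path.
#' @param aspect Aspect code written in column 9.
#' @export
write_gaf <- function(ann, path, aspect = "P") {
  rows <- unlist(lapply(names(ann), function(tm) {
    vapply(ann[[tm]], function(g) {
      paste(c("NETPRIO", g, g, "", tm, "NETPRIO:0001", "IEA", "", aspect,
              "", "", "protein", "taxon:9606", "20240101", "NETPRIO",
              "", ""), collapse = "\t")
    }, character(1))
  }), use.names = FALSE)
  writeLines(c("!gaf-version: 2.2", rows), path)
}

#' Worked-example micro-network
#'
#' A small fixed network holding the hand-checkable configuration used to
#' illustrate the first-neighborhood seed ratio: gene P05019 (IGF1) has
#' exactly 16 direct partners of which 9 are seed genes (ratio 9/16 =
#' 0.5625) and gene P01344 (IGF2) has 21 partners of which 12 are seeds
#' (ratio 12/21 = 0.5714). A few fixed filler edges connect the two
#' neighborhoods.
#'
#' @return List with `network` (igraph) and `positives` (character).
#' @export
worked_example_fixture <- function() {
  igf1 <- "P05019"
  igf2 <- "P01344"
  n1 <- sprintf("N%02d", 1:16)   # IGF1 partners; N01..N09 are seeds
  n2 <- sprintf("M%02d", 1:21)   # IGF2 partners; M01..M12 are seeds
  edges <- rbind(
    cbind(igf1, n1),
    cbind(igf2, n2),
    # filler links between the neighborhoods (do not touch IGF1/IGF2)
    cbind(c("N01", "N05", "N10", "N16"), c("M01", "M13", "M20", "M07"))
  )
  g <- edges_from_pairs(edges[, 1], edges[, 2])
  positives <- c(igf1, igf2, sprintf("N%02d", 1:9), sprintf("M%02d", 1:12))
  list(network = g, positives = positives)
}
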