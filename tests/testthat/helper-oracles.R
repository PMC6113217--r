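# Brute-force oracles, written against the adjacency matrix so they stay
# independent of the igraph-backed production code they check.

adj_matrix <- function(net) {
  m <- as.matrix(igraph::as_adjacency_matrix(net))
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

bf_degree <- function(adj) rowSums(adj)

# all-pairs shortest-path distances by plain BFS level expansion
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier) > 0) {
      lev <- lev + 1
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 &
                     is.infinite(d[s, ]))
      d[s, nxt] <- lev
      frontier <- nxt
    }
  }
  d
}

bf_second_neighbors <- function(adj, gene) {
  d <- bf_distances(adj)
  sort(colnames(adj)[d[gene, ] == 2])
}

# literal iterative pruning: a node's core number is the largest K at
# which it survives deleting all nodes of degree < K until stable
bf_kcore <- function(adj) {
  nodes <- rownames(adj)
  core <- stats::setNames(rep(0L, length(nodes)), nodes)
  for (K in seq_len(max(1, max(rowSums(adj))))) {
    keep <- rep(TRUE, nrow(adj))
    repeat {
      deg <- rowSums(adj[, keep, drop = FALSE]) * keep
      drop_now <- keep & deg < K
      if (!any(drop_now)) break
      keep[drop_now] <- FALSE
    }
    core[nodes[keep]] <- K
    if (!any(keep)) break
  }
  core
}

# shortest-path counts sigma(j, .) by dynamic programming over BFS levels
bf_sigma_from <- function(adj, s) {
  n <- nrow(adj)
  d <- bf_distances(adj)[s, ]
  sigma <- stats::setNames(rep(0, n), rownames(adj))
  sigma[s] <- 1
  for (lev in sort(unique(d[is.finite(d) & d > 0]))) {
    for (v in which(d == lev)) {
      prev <- which(adj[, v] > 0 & d == lev - 1)
      sigma[v] <- sum(sigma[prev])
    }
  }
  sigma
}

# betweenness as an explicit sum over unordered pairs: paths through i
# counted via sigma(j,i) * sigma(i,k) when d(j,i) + d(i,k) = d(j,k)
bf_betweenness <- function(adj) {
  nodes <- rownames(adj)
  n <- length(nodes)
  d <- bf_distances(adj)
  sigma <- t(vapply(seq_len(n), function(s) bf_sigma_from(adj, s),
                    numeric(n)))
  bc <- stats::setNames(rep(0, n), nodes)
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    if (!is.finite(d[j, k])) next
    for (i in seq_len(n)) {
      if (i == j || i == k) next
      if (d[j, i] + d[i, k] == d[j, k]) {
        bc[i] <- bc[i] + sigma[j, i] * sigma[i, k] / sigma[j, k]
      }
    }
  }
  bc
}

# seedable Erdos-Renyi edge list built by hand (not via igraph) so graph
# fixtures do not share machinery with the code under test
random_net <- function(n, p, seed) {
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  withr::with_seed(seed, {
    keep <- stats::runif(nrow(pairs)) < p
    # guarantee at least one edge
    if (!any(keep)) keep[sample(length(keep), 1)] <- TRUE
    netprio:::edges_from_pairs(pairs[keep, 1], pairs[keep, 2])
  })
}

# small clearly separable feature table for classifier tests
toy_feature_table <- function(n_pos = 20, n_unl = 60, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    n <- n_pos + n_unl
    genes <- sprintf("g%03d", seq_len(n))
    pos <- genes[seq_len(n_pos)]
    shift <- ifelse(genes %in% pos, gap, 0)
    data.frame(
      gene = genes,
      degree = stats::rnorm(n) + shift,
      kcore = stats::rnorm(n) + shift,
      betweenness = stats::rnorm(n, sd = 100) + shift * 100,
      ratio1 = stats::runif(n) / 2 + ifelse(genes %in% pos, 0.5, 0),
      ratio2 = stats::runif(n),
      go_score = stats::rnorm(n) + shift,
      label = ifelse(genes %in% pos, "positive", "unlabeled"),
      stringsAsFactors = FALSE
    )
  })
}

# default-spec synthetic feature table, built once per test session
synthetic_features <- local({
  cache <- new.env()
  function(spec = synthetic_spec()) {
    key <- paste(unlist(spec), collapse = "_")
    if (is.null(cache[[key]])) {
      sim <- generate_synthetic(spec)
      universe <- igraph::V(sim$network)$name
      topo <- topology_table(sim$network, sim$positives)
      ts <- score_all_terms(sim$annotations, sim$positives, universe)
      gs <- gene_go_scores(sim$annotations, ts, universe,
                           positives = sim$positives)
      cache[[key]] <- list(
        sim = sim,
        features = assemble_features(topo, gs, sim$positives),
        term_scores = ts
      )
    }
    cache[[key]]
  }
})
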