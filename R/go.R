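#' Load GO annotations from a GAF 2.x file
#'
#' Reads a Gene Association File and returns the gene sets of each GO
#' term, restricted to one ontology aspect (default biological process).
#' Annotations carrying a NOT qualifier are dropped; duplicate gene-term
#' rows collapse to one. Only the columns the scoring needs are consumed:
#' DB object id (2), qualifier (4), GO id (5), aspect (9).
#'
#' @param path Path to a GAF 2.1/2.2 file.
#' @param aspect One of "P" (biological process, default), "F", "C".
#' @return A named list of character vectors: `term_to_genes[[go_id]]` is
#'   the set of gene identifiers annotated to that term. Class
#'   `"annotation_set"`.
#' @export
load_gaf <- function(path, aspect = "P") {
  stopifnot(aspect %in% c("P", "F", "C"))
  if (!file.exists(path)) stop("GAF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!startsWith(lines, "!") & nzchar(lines))
  if (length(body_idx) == 0) stop("GAF file has no annotation rows: ", path)
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  bad <- which(nf < 15L)
  if (length(bad) > 0) {
    stop("malformed GAF row at line ", body_idx[bad[1]],
         " (", nf[bad[1]], " fields, need >= 15)")
  }
  gene <- vapply(parts, `[[`, character(1), 2L)
  qualifier <- vapply(parts, `[[`, character(1), 4L)
  go_id <- vapply(parts, `[[`, character(1), 5L)
  asp <- vapply(parts, `[[`, character(1), 9L)

  keep <- asp == aspect & !grepl("(^|\\|)NOT(\\||$)", qualifier)
  gene <- gene[keep]
  go_id <- go_id[keep]
  pairs <- unique(data.frame(gene = gene, term = go_id,
                             stringsAsFactors = FALSE))
  term_to_genes <- split(pairs$gene, pairs$term)
  term_to_genes <- lapply(term_to_genes, unique)
  structure(term_to_genes, class = "annotation_set", aspect = aspect)
}

#' Log-odds enrichment score of one GO term
#'
#' The score compares the frequency with which seed (disease) genes are
#' annotated to a term against the genome-wide seed frequency:
#' \deqn{\log\frac{(m+a)/(n+a)}{m_0/n_0}}
#' where `m` of the term's `n` annotated genes are seeds, `m0` of the
#' `n0` universe genes are seeds, and `a > 0` is a correction factor that
#' keeps the score finite at `m = 0`. The natural logarithm is used by
#' default; pass `base` to change it.
#'
#' @param m Seed genes annotated to the term.
#' @param n All universe genes annotated to the term (`n >= m`).
#' @param m0 Seed genes in the universe (`> 0`).
#' @param n0 Universe size (`>= m0`, `> 0`).
#' @param a Correction factor, default 1.
#' @param base Logarithm base, default `exp(1)`.
#' @return The log-odds score (finite real).
#' @export
term_log_odds <- function(m, n, m0, n0, a = 1, base = exp(1)) {
  if (any(m0 <= 0) || any(n0 <= 0)) stop("m0 and n0 must be positive")
  if (any(a <= 0)) stop("correction factor a must be positive")
  if (any(n < m) || any(m < 0)) stop("need n >= m >= 0")
  log(((m + a) / (n + a)) / (m0 / n0), base = base)
}

#' Score every sufficiently annotated GO term
#'
#' Counts annotations within the given gene universe only, drops terms
#' annotating fewer than `min_n` universe genes, and computes the
#' log-odds score of each remaining term.
#'
#' @param ann An `annotation_set` from [load_gaf()].
#' @param positives Character vector of seed gene identifiers.
#' @param universe Character vector defining the gene universe (typically
#'   the network's nodes after cleanup); `n0 = |universe|`,
#'   `m0 = |positives` \eqn{\cap} `universe|`.
#' @param min_n Minimum universe genes per term (default 5).
#' @param a Correction factor passed to [term_log_odds()].
#' @param base Logarithm base.
#' @return data.frame with columns `term`, `m`, `n`, `score`, ordered by
#'   decreasing score.
#' @export
score_all_terms <- function(ann, positives, universe, min_n = 5, a = 1,
                            base = exp(1)) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  m0 <- length(intersect(positives, universe))
  if (m0 == 0) stop("no positive genes in the universe")
  n0 <- length(universe)

  term_genes <- lapply(unclass(ann), function(g) intersect(g, universe))
  n <- vapply(term_genes, length, integer(1))
  keep <- n >= min_n
  term_genes <- term_genes[keep]
  n <- n[keep]
  m <- vapply(term_genes, function(g) length(intersect(g, positives)),
              integer(1))
  out <- data.frame(
    term = names(term_genes),
    m = as.integer(m),
    n = as.integer(n),
    score = term_log_odds(m, n, m0, n0, a = a, base = base),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out <- out[order(-out$score, out$term), , drop = FALSE]
  attr(out, "m0") <- m0
  attr(out, "n0") <- n0
  attr(out, "a") <- a
  attr(out, "base") <- base
  out
}

#' Summed GO score per gene
#'
#' A gene annotated to several qualifying terms receives the sum of their
#' log-odds scores; a gene with no qualifying annotation scores 0.
#'
#' When `positives` is supplied, each gene's contribution from a term is
#' scored *leaving the gene itself out* of the counts: for gene i the
#' term's score is recomputed with `m - 1` (if i is a seed), `n - 1`,
#' and the universe counts reduced accordingly. This parallels the rule
#' that a gene's own label never enters its own neighborhood ratios --
#' without it, seed genes inflate the very term counts that score them,
#' and the feature separates the classes even when annotations carry no
#' signal. Omitting `positives` gives the plain sum of the published
#' term scores (the label-leaky variant).
#'
#' @param ann An `annotation_set` from [load_gaf()].
#' @param term_scores data.frame from [score_all_terms()] (computed over
#'   the same universe).
#' @param universe Character vector of genes to report (each gets a row).
#' @param positives Seed genes for leave-self-out scoring, or `NULL`
#'   (default) for the plain sum.
#' @return data.frame with columns `gene`, `go_score`, one row per
#'   universe gene, ordered by gene identifier.
#' @export
gene_go_scores <- function(ann, term_scores, universe, positives = NULL) {
  universe <- sort(unique(universe))
  total <- stats::setNames(numeric(length(universe)), universe)
  ann_l <- unclass(ann)
  loo <- !is.null(positives)
  if (loo) {
    m0 <- attr(term_scores, "m0")
    n0 <- attr(term_scores, "n0")
    a <- attr(term_scores, "a")
    base <- attr(term_scores, "base")
    if (is.null(m0) || is.null(n0)) {
      stop("term_scores lacks the universe counts needed for ",
           "leave-self-out scoring; recompute with score_all_terms()")
    }
    if (m0 < 2) stop("leave-self-out scoring needs at least 2 positives")
  }
  for (i in seq_len(nrow(term_scores))) {
    g <- intersect(ann_l[[term_scores$term[i]]], universe)
    if (!loo) {
      total[g] <- total[g] + term_scores$score[i]
    } else {
      m <- term_scores$m[i]
      n <- term_scores$n[i]
      is_pos <- g %in% positives
      s_pos <- if (any(is_pos)) {
        term_log_odds(m - 1, n - 1, m0 - 1, n0 - 1, a = a, base = base)
      } else 0
      s_bg <- if (any(!is_pos)) {
        term_log_odds(m, n - 1, m0, n0 - 1, a = a, base = base)
      } else 0
      total[g] <- total[g] + ifelse(is_pos, s_pos, s_bg)
    }
  }
  data.frame(gene = universe, go_score = as.numeric(total),
             stringsAsFactors = FALSE, row.names = NULL)
}
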