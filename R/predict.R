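#' Rank unlabeled genes by posterior probability
#'
#' Scores every unlabeled gene with a trained model and returns the full
#' ranking, flagging genes whose posterior exceeds the candidate
#' threshold. Posterior ties share their order lexicographically by gene
#' identifier so the ranking is reproducible.
#'
#' @param model A `netprio_model` (e.g. the median-AUC run's model).
#' @param table Feature table from [assemble_features()].
#' @param threshold Candidate cutoff on the posterior, default 0.9.
#' @return data.frame with `gene`, `posterior`, `rank` (1-based, by
#'   descending posterior) and `candidate` (posterior > threshold),
#'   ordered by rank.
#' @export
predict_unlabeled <- function(model, table, threshold = 0.9) {
  unl <- table[table$label != "positive", , drop = FALSE]
  if (nrow(unl) == 0) stop("no unlabeled genes to score")
  p <- posterior_probs(model, unl)
  ord <- order(-p, names(p))
  out <- data.frame(gene = names(p)[ord], posterior = unname(p)[ord],
                    rank = seq_along(p), stringsAsFactors = FALSE)
  out$candidate <- out$posterior > threshold
  rownames(out) <- NULL
  out
}

#' Independent cross-list validation
#'
#' Trains on one curated disease-gene list and asks how many genes that
#' appear only in a second, independent list are recovered. The feature
#' table is relabeled with the training positives, the balanced
#' resampling protocol is rerun from scratch, the median-AUC run's model
#' scores the exclusive test genes, and recovered genes are counted at
#' each posterior threshold.
#'
#' Note that label-dependent features (`ratio1`, `ratio2`, `go_score`)
#' should be computed with respect to the training positives before
#' calling this function; the function only relabels rows.
#'
#' @param train_positives Character vector: training disease genes.
#' @param test_positives Character vector: the independent list; genes
#'   shared with `train_positives` are excluded before counting.
#' @param table Feature table covering the gene universe, with features
#'   computed with respect to `train_positives`.
#' @param thresholds Posterior cutoffs, default `c(0.5, 0.8, 0.9)`.
#' @param repeats Resampling runs (odd), default 1001.
#' @param base_seed Seed for the resampling protocol.
#' @param folds,cost,features Passed to [resample_train()].
#' @return List with `recalled` (named integer vector, one entry per
#'   threshold), `n_test` (size of the exclusive test set),
#'   `posteriors` (named vector over the exclusive test genes), and
#'   `median_auc`.
#' @export
cross_list_validate <- function(train_positives, test_positives, table,
                                thresholds = c(0.5, 0.8, 0.9),
                                repeats = 1001, base_seed = 1, folds = 5,
                                cost = 1,
                                features = CLASSIFIER_FEATURES) {
  test_only <- setdiff(intersect(test_positives, table$gene),
                       train_positives)
  if (length(test_only) == 0) {
    stop("exclusive test set is empty: every test gene is in the ",
         "training list (or absent from the table)")
  }
  tab <- table
  tab$label <- ifelse(tab$gene %in% train_positives, "positive",
                      "unlabeled")
  # the exclusive test genes must not be drawn as pseudo-negatives
  pool <- tab[!(tab$gene %in% test_only) | tab$label == "positive", ,
              drop = FALSE]
  rt <- resample_train(pool, repeats = repeats, base_seed = base_seed,
                       folds = folds, cost = cost, features = features,
                       keep_models = TRUE)
  best <- select_median_auc_run(rt$runs)
  p <- posterior_probs(best$model, tab[tab$gene %in% test_only, ,
                                       drop = FALSE])
  recalled <- vapply(thresholds, function(thr) sum(p > thr), integer(1))
  names(recalled) <- as.character(thresholds)
  list(recalled = recalled, n_test = length(test_only), posteriors = p,
       median_auc = rt$summary$auc$median)
}
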