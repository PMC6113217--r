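#' Default feature set fed to the classifier
#'
#' Degree, K-core, betweenness, the two seed-neighborhood ratios, and the
#' summed GO log-odds score. `degree2` is computed by [topology_table()]
#' but enters the model only as the denominator of `ratio2`; include it
#' explicitly if wanted.
#' @export
CLASSIFIER_FEATURES <- c("degree", "kcore", "betweenness",
                         "ratio1", "ratio2", "go_score")

# Run code with a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Join topology and GO features into one per-gene table
#'
#' @param topo data.frame from [topology_table()].
#' @param go data.frame from [gene_go_scores()]; must cover exactly the
#'   same genes.
#' @param positives Character vector of seed genes; rows are labeled
#'   "positive" if their gene is listed, "unlabeled" otherwise.
#' @param scale Standardize every feature column to zero mean / unit
#'   variance across the whole table? Off by default: model fitting
#'   rescales from its own training rows (see [cv_evaluate()]), which is
#'   the leak-free place to do it.
#' @return data.frame with `gene`, the feature columns, and `label`.
#' @export
assemble_features <- function(topo, go, positives, scale = FALSE) {
  miss_t <- setdiff(go$gene, topo$gene)
  miss_g <- setdiff(topo$gene, go$gene)
  if (length(miss_t) > 0 || length(miss_g) > 0) {
    stop("feature universes differ; only in GO table: ",
         paste(utils::head(miss_t, 5), collapse = ", "),
         "; only in topology table: ",
         paste(utils::head(miss_g, 5), collapse = ", "))
  }
  tab <- merge(topo[setdiff(names(topo), "label")], go, by = "gene")
  tab <- tab[order(tab$gene), , drop = FALSE]
  tab$label <- ifelse(tab$gene %in% positives, "positive", "unlabeled")
  if (scale) {
    for (cn in setdiff(names(tab), c("gene", "label"))) {
      v <- tab[[cn]]
      s <- stats::sd(v)
      tab[[cn]] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Draw a balanced pseudo-negative sample
#'
#' Uniform sample without replacement from the unlabeled genes,
#' reproducible from the seed.
#'
#' @param table Feature table with a `label` column.
#' @param k Number of genes to draw (typically the number of positives).
#' @param seed Integer seed.
#' @return Character vector of `k` gene identifiers.
#' @export
sample_negatives <- function(table, k, seed) {
  pool <- table$gene[table$label != "positive"]
  if (k > length(pool)) {
    stop("requested ", k, " negatives but only ", length(pool),
         " unlabeled genes are available")
  }
  with_seed(seed, sample(pool, k))
}

#' Precision, recall and F1 from pooled confusion counts
#'
#' Degenerate denominators give 0 by convention so the metrics stay
#' total.
#'
#' @param tp,fn,tn,fp Non-negative counts.
#' @return List with `precision`, `recall`, `f1`.
#' @export
metrics_from_counts <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1)
}

# Sigmoid (Platt) calibration of decision values, fitted by the
# regularized Newton method of Lin, Weng & Keerthi (2007) -- the same
# mechanism behind LIBSVM's "-b 1" posterior probabilities, implemented
# here so that calibration is deterministic given the training data.
platt_fit <- function(dv, y, max_iter = 100L, min_step = 1e-10,
                      sigma = 1e-12, eps = 1e-5) {
  y <- as.integer(y)
  prior1 <- sum(y == 1L)
  prior0 <- length(y) - prior1
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y == 1L, hi, lo)
  A <- 0
  B <- log((prior0 + 1) / (prior1 + 1))

  fval <- function(A, B) {
    fApB <- dv * A + B
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  f <- fval(A, B)
  for (it in seq_len(max_iter)) {
    fApB <- dv * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(dv * d1)
    g2 <- sum(d1)
    if (abs(g1) < eps && abs(g2) < eps) break
    h11 <- sigma + sum(dv * dv * d2)
    h22 <- sigma + sum(d2)
    h21 <- sum(dv * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= min_step) {
      newA <- A + step * dA
      newB <- B + step * dB
      newf <- fval(newA, newB)
      if (newf < f + 1e-4 * step * gd) {
        A <- newA; B <- newB; f <- newf
        break
      }
      step <- step / 2
    }
    if (step < min_step) break
  }
  c(A = A, B = B)
}

platt_prob <- function(dv, ab) {
  fApB <- dv * ab[["A"]] + ab[["B"]]
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

# Decision values oriented so larger means more positive-like, whatever
# label LIBSVM happened to see first.
decision_values <- function(svm_fit, X) {
  pr <- stats::predict(svm_fit, X, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  cn <- colnames(attr(pr, "decision.values"))[1]
  first <- strsplit(cn, "/", fixed = TRUE)[[1]][1]
  if (first != "positive") dv <- -dv
  unname(dv)
}

#' Fit a calibrated linear-kernel SVM on labeled rows
#'
#' Trains a linear-kernel support vector machine (cost `c`, LIBSVM via
#' e1071) on the given positive and pseudo-negative genes, learns feature
#' scaling from those training rows, and fits a Platt sigmoid on the
#' training decision values so that predictions come back as posterior
#' probabilities of the positive class.
#'
#' @param table Feature table from [assemble_features()].
#' @param negatives Character vector of pseudo-negative gene identifiers
#'   (disjoint from the positives).
#' @param cost SVM cost parameter, default 1.
#' @param features Feature columns to use.
#' @return An object of class `netprio_model`; use [posterior_probs()] to
#'   score genes.
#' @export
fit_linear_svm <- function(table, negatives, cost = 1,
                           features = CLASSIFIER_FEATURES) {
  missing_f <- setdiff(features, names(table))
  if (length(missing_f) > 0) {
    stop("feature table lacks columns: ", paste(missing_f, collapse = ", "))
  }
  pos_genes <- table$gene[table$label == "positive"]
  if (length(intersect(pos_genes, negatives)) > 0) {
    stop("negative set overlaps the positives")
  }
  train <- table[table$gene %in% c(pos_genes, negatives), , drop = FALSE]
  y <- factor(ifelse(train$gene %in% pos_genes, "positive", "negative"),
              levels = c("negative", "positive"))
  X <- as.matrix(train[features])
  # scale only non-constant columns; a constant column carries no signal
  # and would otherwise make the internal scaling warn
  scale_cols <- apply(X, 2, stats::sd) > 0
  fit <- e1071::svm(X, y, kernel = "linear", cost = cost,
                    scale = scale_cols, probability = FALSE)
  dv <- decision_values(fit, X)
  ab <- platt_fit(dv, y == "positive")
  structure(list(svm = fit, platt = ab, features = features,
                 cost = cost, n_train = nrow(train)),
            class = "netprio_model")
}

#' Posterior probabilities from a fitted model
#'
#' @param model A `netprio_model` from [fit_linear_svm()].
#' @param table Feature table whose rows to score (must carry the
#'   training feature columns).
#' @return Numeric vector of posterior probabilities of the positive
#'   class, named by gene.
#' @export
posterior_probs <- function(model, table) {
  missing_f <- setdiff(model$features, names(table))
  if (length(missing_f) > 0) {
    stop("feature table lacks columns the model was trained on: ",
         paste(missing_f, collapse = ", "))
  }
  X <- as.matrix(table[model$features])
  dv <- decision_values(model$svm, X)
  stats::setNames(platt_prob(dv, model$platt), table$gene)
}

# Rank-based (Mann-Whitney) AUC; ties count half.
auc_from_scores <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Cross-validated evaluation of one resampling run
#'
#' Combines the positive genes with one balanced pseudo-negative set,
#' splits them into stratified folds, trains a calibrated linear SVM on
#' each training fold and scores the held-out fold. Confusion counts at
#' the posterior threshold are pooled across folds before computing
#' precision, recall and F1; AUC is computed from the pooled posteriors.
#' A final model is also trained on all positives + negatives for use in
#' prediction.
#'
#' @param table Feature table from [assemble_features()].
#' @param negatives Pseudo-negative gene identifiers, one per positive.
#' @param folds Number of CV folds, default 5.
#' @param seed Integer seed (fold assignment).
#' @param cost SVM cost parameter, default 1.
#' @param threshold Posterior cutoff for confusion counts, default 0.5.
#' @param features Feature columns to use.
#' @param keep_model Keep the final trained model in the result?
#' @param feature_fn Optional fold-safe feature oracle: a function taking
#'   a character vector of positives and returning the full feature table
#'   computed with respect to those positives only (see
#'   [feature_builder()]). When supplied, each fold's label-dependent
#'   features are recomputed from its training-fold positives, so no
#'   label information about held-out genes reaches the model. `NULL`
#'   (default) uses `table` as-is: features computed once from all
#'   positives, the protocol real analyses of this kind typically follow.
#' @return A list of class `resampling_run`: `negatives`, `seed`,
#'   `fold_counts` (per-fold tp/fn/tn/fp), `precision`, `recall`, `f1`,
#'   `auc`, `predictions` (pooled gene/truth/posterior), and `model`.
#' @export
cv_evaluate <- function(table, negatives, folds = 5, seed = 1, cost = 1,
                        threshold = 0.5, features = CLASSIFIER_FEATURES,
                        keep_model = TRUE, feature_fn = NULL) {
  pos_genes <- table$gene[table$label == "positive"]
  if (length(pos_genes) < folds || length(negatives) < folds) {
    stop("need at least ", folds, " samples per class for ", folds,
         "-fold CV")
  }
  train_tab <- table[table$gene %in% c(pos_genes, negatives), , drop = FALSE]
  train_tab <- train_tab[order(train_tab$gene), , drop = FALSE]
  truth <- train_tab$gene %in% pos_genes

  fold_of <- integer(nrow(train_tab))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(truth == cls)
      fold_of[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })

  pooled <- data.frame(gene = character(0), truth = logical(0),
                       posterior = numeric(0), fold = integer(0))
  fold_counts <- data.frame(fold = seq_len(folds), tp = 0L, fn = 0L,
                            tn = 0L, fp = 0L)
  for (f in seq_len(folds)) {
    tr <- train_tab[fold_of != f, , drop = FALSE]
    te <- train_tab[fold_of == f, , drop = FALSE]
    if (!is.null(feature_fn)) {
      fold_pos <- intersect(tr$gene, pos_genes)
      safe_tab <- feature_fn(fold_pos)
      tr <- safe_tab[match(tr$gene, safe_tab$gene), , drop = FALSE]
      te <- safe_tab[match(te$gene, safe_tab$gene), , drop = FALSE]
    }
    tr$label <- ifelse(tr$gene %in% pos_genes, "positive", "unlabeled")
    mod <- fit_linear_svm(tr, negatives = tr$gene[!(tr$gene %in% pos_genes)],
                          cost = cost, features = features)
    p <- posterior_probs(mod, te)
    te_truth <- te$gene %in% pos_genes
    pred_pos <- p >= threshold
    fold_counts$tp[f] <- sum(pred_pos & te_truth)
    fold_counts$fn[f] <- sum(!pred_pos & te_truth)
    fold_counts$tn[f] <- sum(!pred_pos & !te_truth)
    fold_counts$fp[f] <- sum(pred_pos & !te_truth)
    pooled <- rbind(pooled, data.frame(gene = te$gene, truth = te_truth,
                                       posterior = unname(p), fold = f))
  }
  m <- metrics_from_counts(sum(fold_counts$tp), sum(fold_counts$fn),
                           sum(fold_counts$tn), sum(fold_counts$fp))
  auc <- auc_from_scores(pooled$posterior, pooled$truth)
  model <- if (keep_model) {
    fit_linear_svm(train_tab, negatives = setdiff(train_tab$gene, pos_genes),
                   cost = cost, features = features)
  }
  structure(list(run_index = NA_integer_, negatives = sort(negatives),
                 seed = seed, fold_counts = fold_counts,
                 precision = m$precision, recall = m$recall, f1 = m$f1,
                 auc = auc, predictions = pooled, model = model),
            class = "resampling_run")
}

#' Balanced negative resampling with median aggregation
#'
#' The core evaluation protocol: draw `repeats` balanced pseudo-negative
#' sets from the unlabeled genes, evaluate a calibrated linear SVM on
#' each by stratified cross-validation, and aggregate each performance
#' metric by its median over the runs (with an odd `repeats`, every
#' median is an attained run value). Run `i` uses seed `base_seed + i`,
#' so any single run is reproducible from its recorded seed alone.
#'
#' @inheritParams cv_evaluate
#' @param repeats Number of resampling runs, default 1001 (use 101 for
#'   desk-scale work).
#' @param base_seed Integer; run `i` is seeded with `base_seed + i`.
#' @param keep_models Keep each run's trained model? (Needed for
#'   median-AUC model selection.)
#' @return List with `runs` (list of `resampling_run`), `manifest`
#'   (data.frame run_index/seed/precision/recall/f1/auc), and `summary`
#'   (per-metric median and quartiles).
#' @export
resample_train <- function(table, repeats = 1001, base_seed = 1,
                           folds = 5, cost = 1, threshold = 0.5,
                           features = CLASSIFIER_FEATURES,
                           keep_models = TRUE, feature_fn = NULL) {
  n_pos <- sum(table$label == "positive")
  if (n_pos == 0) stop("feature table has no positive rows")
  runs <- vector("list", repeats)
  for (i in seq_len(repeats)) {
    seed_i <- base_seed + i
    negs <- sample_negatives(table, n_pos, seed = seed_i)
    run <- cv_evaluate(table, negs, folds = folds, seed = seed_i,
                       cost = cost, threshold = threshold,
                       features = features, keep_model = keep_models,
                       feature_fn = feature_fn)
    run$run_index <- i
    runs[[i]] <- run
  }
  manifest <- data.frame(
    run_index = seq_len(repeats),
    seed = base_seed + seq_len(repeats),
    precision = vapply(runs, `[[`, numeric(1), "precision"),
    recall = vapply(runs, `[[`, numeric(1), "recall"),
    f1 = vapply(runs, `[[`, numeric(1), "f1"),
    auc = vapply(runs, `[[`, numeric(1), "auc")
  )
  summ <- lapply(c(precision = "precision", recall = "recall",
                   f1 = "f1", auc = "auc"), function(mn) {
    v <- manifest[[mn]]
    list(median = stats::median(v),
         q1 = unname(stats::quantile(v, 0.25)),
         q3 = unname(stats::quantile(v, 0.75)))
  })
  list(runs = runs, manifest = manifest, summary = summ)
}

#' Select the run whose AUC is the median order statistic
#'
#' With an odd number of runs the median AUC is attained by at least one
#' run; ties on that value are broken by the lowest run index so the
#' choice is reproducible.
#'
#' @param runs List of `resampling_run` objects (odd length).
#' @return The selected `resampling_run`.
#' @export
select_median_auc_run <- function(runs) {
  r <- length(runs)
  if (r %% 2 == 0) {
    stop("median-AUC selection needs an odd number of runs (got ", r,
         "); use an odd repeat count")
  }
  aucs <- vapply(runs, `[[`, numeric(1), "auc")
  med <- sort(aucs)[(r + 1) / 2]
  idx <- which(aucs == med)[1]
  runs[[idx]]
}
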