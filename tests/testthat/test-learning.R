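test_that("feature assembly joins universes, labels positives and can standardize", {
  net <- random_net(15, 0.25, seed = 2)
  genes <- igraph::V(net)$name
  pos <- genes[1:4]
  topo <- topology_table(net, pos)
  gs <- data.frame(gene = genes, go_score = seq_along(genes))
  ft <- assemble_features(topo, gs, pos)
  expect_equal(nrow(ft), length(genes))
  expect_true(all(CLASSIFIER_FEATURES %in% names(ft)))
  expect_equal(sum(ft$label == "positive"), length(pos))
  expect_setequal(ft$gene[ft$label == "positive"], pos)

  fts <- assemble_features(topo, gs, pos, scale = TRUE)
  for (cn in CLASSIFIER_FEATURES) {
    expect_lt(abs(mean(fts[[cn]])), 1e-9)
  }

  expect_error(assemble_features(topo, gs[-1, ], pos), "universes differ")
})

test_that("negative sampling is uniform, seed-reproducible and bounded", {
  tab <- toy_feature_table(n_pos = 5, n_unl = 100, seed = 8)
  s1 <- sample_negatives(tab, 10, seed = 77)
  s2 <- sample_negatives(tab, 10, seed = 77)
  expect_identical(s1, s2)
  expect_length(s1, 10)
  expect_true(all(s1 %in% tab$gene[tab$label != "positive"]))

  all_unl <- sort(tab$gene[tab$label != "positive"])
  expect_setequal(sample_negatives(tab, 100, seed = 1), all_unl)
  expect_error(sample_negatives(tab, 101, seed = 1), "only 100")

  # chi-square goodness of fit of per-gene draw frequencies
  counts <- table(unlist(lapply(1:2000, function(i)
    sample_negatives(tab, 10, seed = 10000 + i))))
  expect_length(counts, 100)
  expected <- 2000 * 10 / 100
  chi2 <- sum((counts - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 99))
})

test_that("precision/recall/F1 follow the counting formulas with 0 conventions", {
  expect_equal(metrics_from_counts(5, 5, 0, 5),
               list(precision = 0.5, recall = 0.5, f1 = 0.5))
  expect_equal(metrics_from_counts(0, 3, 4, 0)$precision, 0)
  expect_equal(metrics_from_counts(0, 0, 4, 3)$recall, 0)
  expect_equal(metrics_from_counts(0, 3, 4, 2)$f1, 0)
  withr::with_seed(13, {
    for (i in 1:25) {
      k <- sample(0:30, 4, replace = TRUE)
      m <- metrics_from_counts(k[1], k[2], k[3], k[4])
      p <- if (k[1] + k[4] > 0) k[1] / (k[1] + k[4]) else 0
      r <- if (k[1] + k[2] > 0) k[1] / (k[1] + k[2]) else 0
      expect_equal(m$precision, p)
      expect_equal(m$recall, r)
      if (p + r > 0) expect_equal(m$f1, 2 * p * r / (p + r))
    }
  })
})

test_that("Platt calibration recovers a sigmoid and yields probabilities in (0,1)", {
  withr::with_seed(5, {
    dv <- rnorm(400, sd = 2)
    y <- runif(400) < plogis(1.5 * dv)
  })
  ab <- netprio:::platt_fit(dv, y)
  p <- netprio:::platt_prob(dv, ab)
  expect_true(all(p > 0 & p < 1))
  # recovered slope close to the generating logistic (A ~ -1.5)
  expect_equal(unname(ab["A"]), -1.5, tolerance = 0.25)
  # higher decision value -> higher posterior
  expect_true(all(diff(p[order(dv)]) >= 0))
})

test_that("rank AUC agrees with an exhaustive pairwise comparison", {
  withr::with_seed(6, {
    for (i in 1:10) {
      truth <- c(rep(TRUE, 15), rep(FALSE, 25))
      scores <- rnorm(40) + truth * runif(1, 0, 2)
      if (i %% 2 == 0) scores <- round(scores)  # ties
      pairs <- expand.grid(p = which(truth), n = which(!truth))
      oracle <- mean((scores[pairs$p] > scores[pairs$n]) +
                       0.5 * (scores[pairs$p] == scores[pairs$n]))
      expect_equal(netprio:::auc_from_scores(scores, truth), oracle,
                   tolerance = 1e-12)
      # and with the standard ROC implementation
      expect_equal(
        netprio:::auc_from_scores(scores, truth),
        as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                       direction = "<"))),
        tolerance = 1e-12)
    }
  })
})

test_that("cross-validation is perfect on separable data and chance-level on shuffled labels", {
  tab <- toy_feature_table(n_pos = 25, n_unl = 100, gap = 8, seed = 10)
  negs <- sample_negatives(tab, 25, seed = 3)
  run <- cv_evaluate(tab, negs, seed = 3)
  expect_equal(run$precision, 1)
  expect_equal(run$recall, 1)
  expect_equal(run$f1, 1)
  expect_equal(run$auc, 1)
  # pooled-count metrics equal metrics recomputed from the pooled
  # prediction list
  pred <- run$predictions
  tp <- sum(pred$posterior >= 0.5 & pred$truth)
  fp <- sum(pred$posterior >= 0.5 & !pred$truth)
  fn <- sum(pred$posterior < 0.5 & pred$truth)
  m <- metrics_from_counts(tp, fn, sum(!pred$truth) - fp, fp)
  expect_equal(run$precision, m$precision)
  expect_equal(run$recall, m$recall)

  # label shuffling destroys the signal: AUC near 0.5 on average
  aucs <- vapply(1:12, function(i) {
    shuf <- tab
    shuf$label <- withr::with_seed(400 + i, sample(shuf$label))
    negs_i <- sample_negatives(shuf, sum(shuf$label == "positive"),
                               seed = 500 + i)
    cv_evaluate(shuf, negs_i, seed = 500 + i)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)

  expect_error(cv_evaluate(tab, negs[1:3]), "per class")
})

test_that("resampling protocol is reproducible and median-aggregated", {
  tab <- toy_feature_table(n_pos = 12, n_unl = 60, gap = 2, seed = 20)
  rt1 <- resample_train(tab, repeats = 5, base_seed = 9)
  rt2 <- resample_train(tab, repeats = 5, base_seed = 9)
  expect_identical(rt1$manifest, rt2$manifest)
  expect_identical(rt1$summary, rt2$summary)
  expect_equal(rt1$manifest$seed, 9 + 1:5)

  # medians are the middle order statistic of an odd run count
  for (mn in c("precision", "recall", "f1", "auc")) {
    expect_equal(rt1$summary[[mn]]$median, sort(rt1$manifest[[mn]])[3])
  }

  # each run reproducible from its recorded seed alone
  run3 <- rt1$runs[[3]]
  negs <- sample_negatives(tab, 12, seed = run3$seed)
  expect_identical(sort(negs), run3$negatives)
  re <- cv_evaluate(tab, negs, seed = run3$seed)
  expect_equal(re$auc, run3$auc)
  expect_equal(re$fold_counts, run3$fold_counts)
})

test_that("median-AUC run selection picks the attained middle value with index tie-break", {
  mk <- function(auc, idx) structure(list(auc = auc, run_index = idx),
                                     class = "resampling_run")
  runs <- list(mk(0.6, 1), mk(0.8, 2), mk(0.7, 3))
  expect_equal(select_median_auc_run(runs)$run_index, 3)
  ties <- list(mk(0.7, 1), mk(0.7, 2), mk(0.7, 3))
  expect_equal(select_median_auc_run(ties)$run_index, 1)
  expect_error(select_median_auc_run(runs[1:2]), "odd")

  withr::with_seed(31, {
    aucs <- runif(101)
    runs <- lapply(seq_along(aucs), function(i) mk(aucs[i], i))
    picked <- select_median_auc_run(runs)
    expect_equal(picked$auc, sort(aucs)[51])
  })
})
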