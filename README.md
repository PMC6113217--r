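# netprio

Network-based disease-gene prioritization with balanced negative
resampling.

`netprio` is for geneticists and bioinformaticians who have (a) a
protein–protein interaction (PPI) network, (b) a curated list of genes
known to be involved in a disease, and (c) GO biological-process
annotations, and who want a ranked list of new candidate genes with a
calibrated probability attached to each. It was built around the
observation, repeatedly made for complex diseases such as polycystic
ovary syndrome, that known disease genes sit near the network center,
interact with each other, and concentrate in certain biological
processes.

## Method at a glance

For every gene *i* the package computes six features:

* degree *K¹ᵢ* and K-core number (centrality), unnormalized betweenness
  Σ σ(j,i,k)/σ(j,k) over unordered pairs (bottleneck-ness);
* the 1st and 2nd **seed ratios** — the fraction of *i*'s distance-1
  and distance-2 neighbors that are known disease genes (a gene's own
  label never counts toward its own ratios);
* a summed **GO log-odds score**: each biological-process term with
  n ≥ 5 annotated genes scores ln[((m+a)/(n+a))/(m₀/n₀)] (m of its n
  genes are seeds; m₀ of the n₀ universe genes are seeds; a = 1), and a
  gene sums the scores of its terms, computed leave-self-out so a seed
  gene does not inflate its own feature.

Each feature is screened by a two-sample Kolmogorov–Smirnov test
(seeds vs background). Because only positives are known, the classifier
is trained under **balanced negative resampling**: an equal number of
pseudo-negatives is drawn uniformly from the unlabeled genes, a
linear-kernel SVM (cost 1) with Platt-calibrated posteriors is
evaluated by stratified 5-fold cross-validation, the draw is repeated
(1001 times canonically, 101 at desk scale), and precision / recall /
F1 / AUC are aggregated by their medians. The run attaining the median
AUC supplies the final model, which scores every unlabeled gene;
posteriors above 0.9 define the candidate list.

A seedable synthetic-data generator (`generate_synthetic()`) emits
networks, gene lists and GAF files with exactly the planted structure
above, so the whole pipeline runs and is tested without any download.

## Worked example

The hand-checkable micro-network ships with the package: gene P05019
(IGF1) has 16 interaction partners of which 9 are disease genes, and
gene P01344 (IGF2) has 21 partners of which 12 are:

```r
library(netprio)
fx <- worked_example_fixture()
label_ratios(fx$network, fx$positives, "P05019")$ratio1
#> [1] 0.5625        # = 9/16
label_ratios(fx$network, fx$positives, "P01344")$ratio1
#> [1] 0.5714286     # = 12/21
```

## The analysis workflow

The numbered scripts under `analysis/` run the full study on the
default synthetic benchmark (2,000 genes, 100 seed genes) and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # network + seeds + GAF annotations
Rscript analysis/02_features.R   # feature table + KS screen
Rscript analysis/03_train.R      # 101 resampling runs, median metrics
Rscript analysis/04_predict.R    # median-AUC model, candidate list
Rscript analysis/05_validate.R   # cross-list validation on a held-out half
```

Output of stage 2 (the KS screen; all six features separate the
classes):

```
      feature d_stat  p_value n_pos n_neg mean_pos mean_neg
1      degree  0.583 0.00e+00   100  1900 1.44e+01    5.710
2       kcore  0.788 0.00e+00   100  1900 3.98e+00    3.192
3 betweenness  0.507 0.00e+00   100  1900 1.24e+04 2306.594
4      ratio1  0.602 0.00e+00   100  1900 3.58e-01    0.102
5      ratio2  0.389 6.08e-13   100  1900 1.58e-01    0.108
6    go_score  0.559 0.00e+00   100  1900 4.32e+00    1.649
```

Stages 3–5 then print:

```
median over 101 resampling runs:
  precision 0.915  recall 0.960  F1 0.938  AUC 0.981

scored 1900 unlabeled genes; 16 candidates at posterior > 0.9

trained on 50 genes; testing 50 held-out module genes
  posterior > 0.5: 46 / 50 recovered
  posterior > 0.8: 40 / 50 recovered
  posterior > 0.9: 35 / 50 recovered
```

Read: on data where disease genes really are hub-biased,
interconnected and functionally concentrated, the classifier separates
them from the background almost perfectly (median AUC 0.98), 16
unlabeled genes look disease-gene-like enough to pass the 0.9 posterior
bar, and a model trained on half the module recovers 46 of the 50
held-out genes at the 0.5 threshold, with the count shrinking as the
bar rises. With the planted structure switched off the same protocol
returns a median AUC near 0.5 (see the acceptance checks), confirming
the features — including the label-dependent ones — carry no mechanical
leakage.

At the reference scale of the motivating study (a 16,982-protein /
193,949-edge PPI network and 306 disease genes) the same protocol is
reported to reach median precision/recall/F1/AUC around
0.81/0.71/0.75/0.80; real curated inputs plug into the identical
readers (`load_edge_list()`, `read_gene_list()`, `load_gaf()`).

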