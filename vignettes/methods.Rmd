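---
title: "Methods: network and annotation features for disease-gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network and annotation features for disease-gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprio)
```

## The problem

Given a protein–protein interaction (PPI) network, a curated list of
genes known to be involved in a disease (the *seed* or positive genes,
e.g. genes implicated in polycystic ovary syndrome), and GO
biological-process annotations, rank every other gene in the network by
how disease-gene-like it looks. The premise, which holds for many
complex diseases, is that disease genes (i) sit nearer the network
center, (ii) interact with each other more than chance allows, and
(iii) concentrate in a limited set of biological processes. `netprio`
turns each of those premises into a per-gene feature, verifies the
premises on the data at hand with a distributional test, and combines
the features in a calibrated linear classifier trained under a balanced
negative-resampling protocol.

## Features

For each gene $i$ in the (undirected, simple) network:

* **degree** $K_i^1$ — number of direct interaction partners;
* **degree-2** $K_i^2$ — number of partners at shortest-path distance
  exactly 2. We exclude the gene itself and its direct neighbors: a
  "partner at step 2" parallels a partner at step 1, and including
  direct neighbors would make $K_i^2 \ge K_i^1$ trivially;
* **K-core** — the largest $K$ such that $i$ survives recursively
  deleting all nodes of degree $< K$; a depth-of-embedding measure;
* **betweenness** — $\sum_{\{j,k\}: j \ne i \ne k}
  \sigma(j,i,k)/\sigma(j,k)$, the sum over unordered node pairs of the
  fraction of their shortest paths that pass through $i$. We keep it
  unnormalized (counts, not fractions of pairs); pairs in different
  components contribute 0;
* **1st and 2nd seed ratios** — the fraction of $i$'s distance-1 and
  distance-2 neighborhoods made up of seed genes. A gene's own label
  never enters its own numerators (its neighborhoods exclude itself),
  and empty neighborhoods score 0 rather than NaN so the feature table
  is total;
* **GO score** — for every biological-process term with at least
  $n \ge 5$ annotated genes in the universe, the log-odds enrichment
  score
  $$\mathrm{score}(t) = \ln \frac{(m+a)/(n+a)}{m_0/n_0}, \qquad a = 1,$$
  where $m$ of the term's $n$ genes are seeds and $m_0$ of the $n_0$
  universe genes are seeds; a gene's GO score is the sum over the
  qualifying terms that annotate it. The universe is the set of network
  genes after cleanup. The logarithm base is natural by default and
  configurable; the correction factor $a$ keeps scores finite at
  $m = 0$.

### Leave-self-out GO scoring

The summed GO score is label-dependent: the seed genes themselves
define $m$. If gene $i$'s own membership is left inside the counts,
every seed gene inflates exactly the terms that score it, and the
feature separates seeds from background even when annotations carry no
disease signal at all — on a null benchmark (no planted structure) we
measured a single-feature AUC of 0.77 from this artifact alone. The
package therefore scores gene $i$'s terms *leaving $i$ out*: if $i$ is
a seed the term contributes
$\ln\frac{(m-1+a)/(n-1+a)}{(m_0-1)/(n_0-1)}$, otherwise
$\ln\frac{(m+a)/(n-1+a)}{m_0/(n_0-1)}$. This is the same principle the
ratio features follow (a gene's own label never counts toward its own
feature) and restores chance-level behavior under the null. The plain
label-leaky sum remains available (`gene_go_scores(..., positives =
NULL)`) so the size of the bias can be measured.

GO-DAG ancestor propagation is deliberately not implemented: the
scoring operates on the annotations as given, and propagation is listed
as a non-goal.

## Feature screen

Each feature is compared between seed and background genes with a
two-sample Kolmogorov–Smirnov test (`compare_groups()`). The statistic
is the sup-distance between empirical CDFs, evaluated directly on the
ECDFs (ties from integer features get no further correction); p-values
use the asymptotic distribution, appropriate at hundreds-vs-thousands
sample sizes, with an exact option behind a flag. Cumulative-frequency
curves per class are exported for plotting.

## Classifier and resampling protocol

Only positive examples exist; everything else is unlabeled, and most
unlabeled genes are true negatives. The protocol therefore draws a
pseudo-negative set of the same size as the seed set, uniformly at
random from the unlabeled genes, and repeats the draw many times (1001
by default; any odd count works, and 101 is used for desk-scale runs in
the analysis scripts — the scale at which all numbers in this package's
documentation are computed). Each run:

1. pairs the seed genes with its pseudo-negatives (balanced classes),
2. splits them into 5 stratified folds from the run's own seed
   (`base_seed + run_index`, making every run reproducible in
   isolation),
3. trains a linear-kernel SVM (cost $c = 1$, via LIBSVM/e1071) on each
   training fold — feature standardization is learned from the
   training rows inside each fit, never from held-out rows,
4. calibrates a Platt sigmoid on the training decision values and
   scores the held-out fold as posterior probabilities,
5. pools the per-fold confusion counts at posterior threshold 0.5 into
   precision $TP/(TP+FP)$, recall $TP/(TP+FN)$ and
   $F1 = 2PR/(P+R)$ (degenerate denominators give 0), and computes AUC
   from the pooled posteriors by the rank (Mann–Whitney) formula.

Each metric is aggregated as the **median over runs**; with an odd run
count the median is an attained run, and the run attaining the median
AUC supplies the final model (`select_median_auc_run()`, ties broken by
lowest run index). That model, retrained on all seeds plus its run's
pseudo-negatives, scores every unlabeled gene; genes with posterior
above 0.9 are reported as candidates, and the full ranking is always
emitted with ties ordered lexicographically by identifier.

The Platt calibration is implemented in the package (the regularized
Newton method of Lin, Weng & Keerthi) rather than through LIBSVM's
`-b 1` training: LIBSVM's internal calibration shuffles with its own C
`rand()` stream, which R cannot seed, and the protocol's contract is
that a fixed `base_seed` reproduces the identical run manifest across
invocations. The two mechanisms fit the same sigmoid model.

### Label leakage and the fold-safe mode

The ratio and GO features are functions of the full seed list, so in
the default mode a fold's held-out seed genes have already influenced
the features the model trains on — the protocol real analyses of this
kind typically follow, and the leave-self-out scoring above removes its
dominant, mechanical component. For a strictly leak-free estimate,
`feature_builder()` plus the `feature_fn` argument of
`resample_train()` recompute `ratio1`, `ratio2` and `go_score` inside
every fold from the training-fold positives only. The gap between the
two modes measures the residual leakage; both are exercised in the test
suite.

### Cross-list validation

`cross_list_validate()` emulates validation against an independent
second gene list: relabel the table with the training list, rerun the
whole resampling protocol from scratch, and count how many genes
exclusive to the second list exceed posterior 0.5 / 0.8 / 0.9 under the
median-AUC model. The exclusive test genes are excluded from the
pseudo-negative pool — they are known disease genes of the second list,
and drawing them as negatives would corrupt both the training and the
count being reported.

## The synthetic benchmark

`generate_synthetic()` produces instances with the statistical
structure the method assumes, in exactly the file formats the readers
consume, so the pipeline is testable end to end without any database:

* a preferential-attachment network (heavy-tailed degrees, the
  qualitative shape of real PPI networks) — default 2,000 genes, 3
  edges per new node;
* 100 seed genes sampled with probability $\propto$ degree
  (`hub_bias = 1`), planting the centrality effect;
* 150 extra edges between random non-adjacent seed pairs
  (`intra_edge_boost`), planting the interconnection effect
  independently of hubness so either can be ablated;
* 200 annotation terms of 10–100 genes; in 20 of them seed genes are
  sampled with 5× odds (`enrichment_odds`), planting the functional
  concentration.

All randomness flows from one spec seed through named substreams
(network, labels, boost edges, annotations). Setting `hub_bias = 0`,
`intra_edge_boost = 0`, `enrichment_odds = 1` gives the matched null
generator. The default sizes keep a full 101-run evaluation around half
a minute on a laptop while leaving hundreds of genes per annotation
stratum; term sizes of 10–100 on 2,000 genes mirror the mid-size
biological-process terms that drive the score on real data.

What the generator does **not** emulate: study-bias-correlated degrees
(well-studied genes have more recorded interactions *and* more
annotations), false-positive/negative edges, the GO DAG's nesting, or
identifier mismatches between network and annotations. Passing
benchmarks here shows the machinery recovers planted structure of the
assumed kind; it does not certify performance on any real disease.

A second fixture, `worked_example_fixture()`, is a fixed micro-network
holding a hand-checkable configuration: gene P05019 with 16 partners of
which 9 are seeds (ratio $9/16 = 0.5625$) and gene P01344 with 21
partners of which 12 are seeds (ratio $12/21 \approx 0.5714$).

## Numerical and design choices

* Edge cleanup collapses self-loops and duplicate edges, counting
  reversed pairs $\{b,a\}$ as duplicates of $\{a,b\}$; the loader
  reports removal counts for auditing.
* The term-size filter is $n \ge 5$ (configurable); the universe for
  $m_0, n_0$ is the network's gene set after cleanup.
* Leave-self-out GO scoring requires at least two seed genes in the
  universe and errors otherwise rather than guessing.
* `degree2` is computed and reported but excluded from the default
  classifier feature set: it enters the model only as the denominator
  of `ratio2`, and the six screened features are the ones fed forward.
  `CLASSIFIER_FEATURES` makes the set explicit and overridable.
* Posterior threshold 0.5 for confusion counts (the natural balanced
  default), 0.9 for candidate calling; both configurable.
* Medians/quartiles use the standard R definitions; with odd run
  counts the median needs no interpolation.
* Degenerate inputs fail fast with named errors (empty files,
  malformed rows with line numbers, unknown genes, unknown config
  keys, even run counts, single-class tables).

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the package's own acceptance
checks run the default 2,000-gene benchmark with 101 resampling runs,
its matched null, and a 50/50 split of the planted module for
cross-list validation; the graph-measure oracle checks sweep 100 random
graphs of up to 50 nodes against brute-force enumerations. These sizes
are the package's chosen desk-scale study conditions; every number
quoted in the README is recomputed by those scripts.

## Known limitations

* The 1:1 positive:negative design estimates performance under a
  balanced prior; real genomes are far from balanced, so reported
  precision does not translate directly to a genome-wide screen.
* Pseudo-negatives may contain yet-undiscovered disease genes, biasing
  performance estimates downward.
* Degree-correlated study bias in real PPI data can make centrality
  features proxies for research attention; the synthetic benchmark
  cannot detect this.
* Weighted, directed or confidence-scored networks are out of scope;
  edges are taken at face value.
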