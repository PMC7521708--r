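# essnet — essential gene prediction from sequence and network features

Essential genes are the genes a cell cannot survive or reproduce without.
`essnet` predicts gene essentiality — an archetypal *imbalanced*
classification problem, since only ~10% of human genes are essential — by
integrating two kinds of cheaply available evidence:

* **Sequence features (S, 89 per gene)** from the coding and protein
  sequences: the 64 normalized codon frequencies, GC content, gene length,
  codon adaptation index (CAI) and maximum relative synonymous codon usage
  (RSCUmax), plus the 20 amino-acid frequencies and protein length.
* **Network features (N, 64 per gene)**: node embeddings of a
  protein–protein interaction (PPI) network, learned by biased
  second-order random walks fed to a skip-gram model with negative
  sampling (node2vec-style), capturing the neighborhood structure behind
  the centrality–lethality rule.

The two blocks are concatenated (153 features) and classified by a
cost-sensitive multilayer perceptron, with the minority (essential) class
up-weighted in the loss. Evaluation follows the imbalanced-learning
protocol: per repetition, negatives are downsampled to a 1:4
positive:negative ratio and the data split 80/10/10 stratified by class;
sensitivity, specificity, PPV, accuracy, ROC-AUC and average precision are
averaged over repetitions. Top-K rankings by degree, betweenness,
eigenvector and closeness centrality serve as classical baselines.

## The model

Sequence side, for codon $i$ in an $n$-fold synonymous family with counts
$X$:

$$\mathrm{RSCU}_i = \frac{X_i}{\tfrac1n \sum_{j\in\text{fam}} X_j},
\qquad
\mathrm{CAI} = \Big(\prod_{k=1}^{L} r_k\Big)^{1/L},\quad
r_i = \frac{\mathrm{RSCU}_i}{\mathrm{RSCU}_{\max,\text{fam}}},$$

with $L$ the codon count excluding Met, Trp and stops.

Classifier: $y = \sigma(W_i\,x_{i-1} + b_{i-1})$ per layer — ReLU hidden
layers of 128/256/512 units with dropout 0.2, a sigmoid output head, and
class-weighted binary cross-entropy (essential:nonessential = 4:1)
minimized by Adam (learning rate 0.001, batch 32, ≤100 epochs with
early stopping on validation loss).

A seeded synthetic-cohort generator plants both signals at controllable
strength — class-biased codon usage in translation-consistent gene models,
and a degree-corrected block-model interactome in which essential genes
are hubs and cluster together — so the full pipeline is testable offline.
See the methods vignette (`vignettes/essential-gene-prediction.Rmd`) for
the modelling decisions and their rationale.

## Worked example

```r
library(essnet)

cohort <- simulate_cohort(sim_params(n_genes = 300, seed = 1))
cohort
#> Synthetic cohort: 300 genes (60 essential), 2392 edges, 16 screens

feats  <- build_feature_matrix(cohort$genes)        # 300 x 89
net    <- ppi_network(cohort$edges)
emb    <- node2vec_embed(net, node2vec_params(seed = 2))   # 300 x 64
ds     <- assemble_features(feats, emb, NULL, cohort$labels, "N+S")

plans  <- make_splits(ds$labels, n_reps = 3, seed = 3)
report <- run_experiment(ds$x, ds$labels, plans)
report
#> Evaluation over 3 repetitions (threshold 0.50):
#>     Sn     Sp    PPV     Ac    AUC     AP
#> 0.9444 1.0000 1.0000 0.9889 0.9907 0.9778
```

The report says: averaged over three repeated holdouts, the classifier
recovers 94% of held-out essential genes (Sn) with no false positives
(Sp, PPV = 1), ranks essentially all positives above negatives
(AUC 0.99), and keeps precision high across the whole recall range
(AP 0.98) — the planted codon bias and hub/module structure at their
default strengths are strong signals, so near-ceiling numbers are
expected here.

The centrality baselines on the same cohort:

```r
cent <- centralities(net)
labs <- cohort$labels[cent$gene_id]
topk_centrality_eval(cent, labs, k = sum(labs == "essential"))
#>   measure        Ac       PPV        Sn
#> 1      DC 1.0000000 1.0000000 1.0000000
#> 2      BC 0.9933333 0.9833333 0.9833333
#> 3      EC 1.0000000 1.0000000 1.0000000
#> 4      CC 1.0000000 1.0000000 1.0000000
```

Individual models are ordinary fitted objects:

```r
fit <- essnet_mlp(scale(ds$x), ds$labels, seed = 1)
print(fit); summary(fit); plot(fit)      # architecture, losses, history
head(predict(fit, scale(ds$x)))          # essentiality scores in [0, 1]
```

A thin command-line front end over the same functions is included at
`inst/cli/essnet-cli.R`
(`simulate | features | embed | centrality | evaluate | run-all`).

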