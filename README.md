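# atacembed

Region-token embeddings for single-cell ATAC-seq, in R.

Chromatin-accessibility assays report which genomic regions are open in
each cell, but the raw output — fragment files, peak sets, peak-by-cell
count matrices — is high-dimensional, sparse, and hard to compare across
datasets. `atacembed` treats a cell as an unordered set of discrete region
tokens drawn from a fixed vocabulary `U = {v_1, ..., v_V}` of
non-overlapping consensus regions, and learns dense embeddings of both
cells and individual cis-regulatory regions with a transformer encoder
that uses **no positional encodings**: a region set has no intrinsic
order, so per-token outputs are permutation-equivariant and the
mean-pooled cell embedding `E_cell = (1/k) Σ_j h_j` is
permutation-invariant by construction.

It is written for computational biologists who want a self-contained,
inspectable implementation of this model family — tokenization through
pretraining to downstream regulatory statistics — that runs on a laptop
against a bundled synthetic-data generator, with no external downloads.

What the package provides:

* **IO and tokenization** — BED, 10x-style `fragments.tsv(.gz)`,
  MatrixMarket count matrices, GTF (TSS extraction), bedGraph signal;
  strict interval-intersection tokenization
  `I_c = {v ∈ U : ∃r ∈ R_c, r ∩ v ≠ ∅}` with truncate/sample context
  policies, plus a coverage-cutoff consensus builder for vocabularies.
* **Pretraining** — ELECTRA-style replaced-token detection: positions are
  corrupted with probability `p = 0.45` by uniform vocabulary draws
  (`δ_j ~ Bernoulli(p)`, `z_j ~ Unif(U)`) and the model minimizes the
  binary cross-entropy `−Σ_j [δ_j log ŷ_j + (1−δ_j) log(1−ŷ_j)]`,
  `ŷ_j = σ(w_o·h_j + b)`, with AdamW. The transformer forward/backward
  pass is hand-written matrix code validated against finite differences.
* **Fine-tuning** — triplet margin loss
  `max(d(a,p) − d(a,n) + margin, 0)` (margin 1.0, Euclidean distance) on
  cell-type labels; a CLIP-style dual encoder aligning ATAC and RNA cell
  embeddings by symmetric InfoNCE with learnable temperature; an RNA
  decoder imputing expression from ATAC embeddings.
* **Analysis** — seeded k-means++ clustering evaluated by ARI/AMI/
  homogeneity (implemented from their contingency-table definitions),
  Spearman's `ρ = 1 − 6Σd_i²/(n(n²−1))`, TSS-distance and cCRE annotation
  of the vocabulary, the TSS distribution score (correlation of a
  region's TSS distance with its embedding distance to the pELS
  centroid), inferred-cryptic-TSS (icTSS) detection, and empirical
  enrichment tests against vocabulary-sampled nulls.
* **Synthetic data** — seeded generators for multi-cell-type atlases,
  paired multiome cells, annotated toy vocabularies, planted cryptic
  promoters, and signal tracks, so every claim is testable against known
  truth.

## Worked example

Generate a 5-type synthetic atlas, pretrain a small encoder, and compare
clustering before and after triplet fine-tuning:

```r
library(atacembed)

gv    <- generate_vocabulary(genome_length = 1e6, V = 500, seed = 1)
cfg   <- synthetic_atlas_config(n_cell_types = 5, markers_per_type = 40,
                                cells_per_type = 60, seed = 1)
atlas <- generate_cells(gv$vocab, cfg)

model <- init_model(model_config(vocab_size = 500, d_model = 32,
                                 n_layers = 2, n_heads = 2, ffn_dim = 64),
                    seed = 1)
fit <- pretrain(model, atlas$cells, pretrain_config(epochs = 4, seed = 1))
round(fit$history, 4)
#>   epoch train_loss holdout_loss holdout_auroc
#> 1     0         NA       0.6931        0.5000
#> 2     1     0.6857       0.6656        0.6857
#> 3     2     0.6358       0.6090        0.7201
#> 4     3     0.5886       0.5775        0.7469
#> 5     4     0.5691       0.5783        0.7486

emb <- cell_embedding(encode(fit$model, atlas$cells))
ari(atlas$truth$labels, kmeans_cluster(emb, 5, seed = 1))
#> [1] 0.063

ft <- finetune_triplet(fit$model, atlas$cells, atlas$truth$labels,
                       epochs = 3, lr = 1e-4, seed = 1)
emb_ft <- cell_embedding(encode(ft$model, atlas$cells))
ev <- clustering_eval(atlas$truth$labels, kmeans_cluster(emb_ft, 5, seed = 1))
c(ari = ev$ari, ami = ev$ami, homogeneity = ev$homogeneity)
#>         ari         ami homogeneity
#>       0.992       0.989       0.989
```

Reading the numbers: the held-out detection loss starts at exactly
`ln 2 ≈ 0.6931` (an untrained model cannot distinguish replaced tokens, and
the zero-initialized head predicts 0.5 everywhere) and falls as the model
learns which tokens co-occur; the replacement-detection AUROC rises
accordingly. The self-supervised base model alone clusters this atlas
poorly (ARI 0.06 after 4 short epochs), while three epochs of triplet
fine-tuning on the labels reorganize the space so that k-means recovers
the cell types almost perfectly (ARI 0.99).

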