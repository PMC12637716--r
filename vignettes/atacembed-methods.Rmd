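---
title: "Methods: region-token embeddings for chromatin accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-token embeddings for chromatin accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its model and the choices behind
it: what is computed, under which assumptions, with which defaults, and what
the bundled synthetic data can and cannot demonstrate.

## The model

A single cell profiled by scATAC-seq is treated as an unordered set of
accessible genomic intervals — a "bag of co-accessible regions". Analysis
starts from a fixed **vocabulary** `U = {v_1, ..., v_V}` of sorted,
non-overlapping consensus regions; each region is one token. **Tokenization**
maps a cell's raw intervals to the vocabulary by strict interval
intersection: a token is present iff some input interval shares at least one
base with the vocabulary region (book-ended intervals do not match, because
the intersection of half-open intervals touching at a point is empty). The
result is a set: duplicates collapse, read counts and input order carry no
information.

The encoder is a stack of `L` transformer layers over the token embeddings,
with **no positional encodings of any kind**. This is a deliberate modeling
statement, not an omission: the information content of a region set does not
depend on the order in which its regions are listed, so per-token outputs
must be permutation-equivariant and the pooled cell embedding
permutation-invariant. Both properties are exact in this implementation
(verified to 1e-5 relative tolerance in the test suite; the residual is
floating-point reassociation from reordered summations).

Pretraining is **replaced-token detection** (ELECTRA-style). Each position
`j` of a cell's token sequence is independently flagged with probability
`p = 0.45`; flagged positions are replaced by ids drawn uniformly from the
vocabulary. The model scores every position with a linear head on its final
contextual embedding, `y_hat_j = sigmoid(w_o . h_j + b)`, and minimizes
binary cross-entropy against the replacement indicators `delta_j`. Two
details worth naming:

* `delta` labels the *draw*, not the outcome: a replacement that collides
  with the original id (probability `1/V`) is still labeled replaced. This
  is the literal reading of the corruption process and keeps the labels
  independent of the token values.
* There is no generator network. Binary detection against uniform
  replacements needs none, and it avoids the cost of a full softmax over
  the vocabulary — the reason this objective suits region vocabularies far
  larger than natural-language ones.

A cell embedding is the arithmetic mean of the cell's contextual token
embeddings. Per-token ("contextualized region") embeddings are exposed
before pooling; the same vocabulary id embedded in different cells yields
different vectors.

## Fine-tuning and multimodal alignment

**Triplet fine-tuning** pulls same-cell-type embeddings together: for mined
triplets (anchor, positive of the same type, negative of another type),
`L = max(d(a,p) - d(a,n) + margin, 0)` with `margin = 1.0` and Euclidean
distance (`p = 2`), batch-averaged. Mining is uniform within the labeled
corpus (no hard-negative mining — unspecified upstream, and uniform mining
is the simplest defensible default). Labels with fewer than two cells
cannot supply anchor/positive pairs and are excluded with a warning.

The **dual encoder** aligns ATAC and RNA cell embeddings in a shared latent
space with a CLIP-style symmetric InfoNCE loss: L2-normalized projections,
cosine-similarity logits scaled by a learnable temperature (initialized at
0.07), cross-entropy against the diagonal averaged over both directions.
The configuration defaults follow the published recipe (15 epochs, linear
learning-rate decay from a peak of 5e-5). At desk scale both towers are
trained from scratch rather than initialized from large pretrained models,
so the experiments in the test suite pass a larger peak rate (1e-3); with
5e-5 and random initialization the alignment signal is real but far from
converged within 15 epochs. The RNA tower bundled here is a small
feed-forward expression encoder behind a pluggable interface — any encoder
with the same forward/backward contract can replace it.

The **RNA decoder** maps an ATAC-derived cell embedding through a fully
connected ReLU layer into a latent space and from there through one hidden
layer to the gene-expression vector, trained by mean-squared error on
normalized expression (the regression default; the upstream loss is not
specified). Held-out quality is reported as per-cell Spearman correlation
between observed and imputed profiles.

## Analysis statistics

Clustering uses seeded k-means (k-means++ initialization, Lloyd iterations,
10 restarts) with `k` set to the number of annotated cell types, evaluated
by ARI, AMI (permutation-model expected-MI adjustment, max-entropy
normalization), and homogeneity. These metrics are implemented from their
definitions and are tested against independent enumeration oracles (all
partition pairs of small sets, chance terms by enumerating every
permutation of the predicted labels).

Spearman correlation ranks both vectors (average ranks on ties) and applies
`rho = 1 - 6*sum(d_i^2)/(n(n^2-1))` when ties are absent, the
product-moment correlation of ranks otherwise.

The **TSS distribution score** asks whether embedding space is organized by
promoter proximity: compute the centroid of the proximal-enhancer-like
(pELS) regions, each region's Euclidean distance to that centroid, and the
correlation of that distance with annotated TSS distance. The correlation
method defaults to Spearman but Pearson is exposed: the upstream definition
and the upstream figure caption disagree on which was used, so the package
surfaces the choice rather than resolving it. Distances use raw
(unnormalized) embeddings, matching the Euclidean metric of the triplet
loss.

**Inferred cryptic TSSs (icTSSs)** are regions annotated as highly distal
from any TSS whose embeddings nevertheless sit near the pELS centroid —
candidate unannotated promoters. Thresholds are empirical quantiles
(defaults 0.25 and 0.25, always recorded in the output) because the
upstream selection is shown only graphically. Selections are monotone in
both quantiles.

**Enrichment** of a region set in a signal track is tested against an
empirical null: the observed statistic is the mean over target regions of
each region's length-weighted mean signal (uncovered bases count as zero),
and the null redraws same-sized region sets uniformly without replacement
from the vocabulary (500 repetitions by convention). The p-value uses the
plus-one correction `(1 + #{null >= obs}) / (1 + n_reps)` so the smallest
attainable value is `1/(n_reps + 1)`; a flag restores the uncorrected
convention, under which an observed value exceeding every null reports 0.

TSS distances use half-open coordinates: distance 0 when the TSS lies in
`[start, end)`, otherwise `max(start - pos, pos - end, 0)`; equidistant
TSSs resolve to the first in sorted order. cCRE labels are assigned by
largest overlap with ties broken by a fixed class priority
(PLS > pELS > dELS > CTCF > DNase-H3K4me3 > others).

## The synthetic generator

Real atlas-scale corpora (hundreds of thousands of cells, a ~900k-region
genome-wide vocabulary, 8,192-token contexts) are out of desk scope, so
every claim is exercised on a generator with known truth:

* **Vocabulary**: `V` non-overlapping regions on a toy chromosome; a TSS is
  placed near a configurable fraction of regions (half inside, half within
  200 bp downstream), and cCRE classes are derived from the *realized* TSS
  distances (0 → PLS, ≤200 bp → pELS, else dELS), so annotations are
  coherent by construction.
* **Cells**: each cell type owns a disjoint set of marker regions opened
  independently with `marker_open_prob`; all non-marker regions form a
  shared background opened with `background_open_prob`. This
  Bernoulli-per-region form replaces the external bulk-downsampling
  simulation it emulates: it preserves the one property the method needs —
  type-specific co-accessibility — and makes token-count expectations
  available in closed form for testing.
* **Paired multiome cells**: the ATAC side as above; the RNA side is a
  shared baseline profile with marker genes elevated in their own type,
  plus seeded Gaussian noise, clamped non-negative.
* **Planted icTSSs**: the most TSS-distal dELS regions are marked as latent
  promoters, added to one cell type's accessible program, and given high
  values in an emitted promoter-mark-like signal track — so end-to-end
  recovery (train → embed → detect → enrich) can be scored against truth.

Default conditions are 5 cell types × 200 cells, `V = 2000`, 100 markers
per type, `marker_open_prob = 0.9`, `background_open_prob = 0.02` (about
120 tokens per cell). These were fixed a priori by an information
calculation rather than by tuning: under these conditions the Bayes-optimal
detection loss is ≈0.38 nats and the achievable replacement-detection AUROC
tops out near 0.88, because background tokens are statistically similar to
uniform replacements while marker tokens are recognizable from their
cell-type context. A model that learns the co-accessibility structure can
therefore clearly beat the ln 2 ≈ 0.693 uninformative baseline, and a model
that ignores context cannot reach the ceiling — which is exactly the
property pretraining is supposed to demonstrate.

What passing these tests does *not* show: robustness to sequencing depth
variation, Tn5 bias, doublets, batch structure, continuous differentiation
trajectories, or non-disjoint regulatory programs — none of which the
generator emulates. Results on the generator establish correctness of the
machinery and learnability of planted structure, not biological performance.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere in memory (BED
  convention); GTF input is converted once at the boundary. Chromosome
  names match exactly — no silent "chr" normalization.
* **Encoder internals**: pre-normalization layers with exact (erf-based)
  GELU, a final layer norm, and dimension-preserving attention
  (`d_model` split over heads). Pre-norm trains stably at small scale;
  the upstream architecture leaves these internals (and `d_model`, `L`)
  unstated, so the desk preset `d_model = 64`, `L = 4`, 4 heads,
  `ffn_dim = 4*d_model`, context 256 is this package's own.
* **Embeddings** are looked up without `sqrt(d)` scaling (the simplest
  reading of the embedding step). The detection head is zero-initialized,
  so an untrained model predicts exactly 0.5 and the initial loss is
  exactly `ln 2` — a useful built-in calibration check.
* **Padding**: one PAD id is reserved after the `V` region ids, but batches
  are processed as ragged sequences, so padded positions are never
  materialized — the contract that PAD carries no gradient and is excluded
  from pooling and loss holds by construction. Empty cells pool to the
  zero vector with a warning.
* **Training** is plain AdamW (decoupled decay on 2-D weight matrices
  only), seeded shuffling and corruption, single-threaded deterministic
  BLAS operations: identical seeds give identical histories. All
  forward/backward passes are hand-written matrix code validated against
  finite differences (1e-4 absolute tolerance on a tiny configuration).
* **Probability clamping**: detection probabilities are clamped to
  `[1e-7, 1 - 1e-7]` inside the loss for numerical safety.
* **Context policies**: `sample` (default, preserves heterogeneity) or
  `truncate`. Truncation keeps the first `C` tokens in ascending id
  (genomic) order — whether "first" means file order or genomic order is
  ambiguous upstream; genomic order is fixed here because token sequences
  are canonically id-sorted. Sampling derives its RNG stream from the
  policy seed plus a hash of the token content, so it is deterministic
  given (tokens, policy) without collapsing all cells onto one subset.
* **Consensus vocabulary**: a coverage-cutoff sweep over sorted start/end
  events (bases covered by ≥ `min_support` merged peak sets), checked
  against a per-base oracle. The upstream universe pipeline additionally
  involves external peak calling, coverage tracks, and an HMM variant with
  unstated parameters; those are outside this package's scope, and
  `min_support` is an explicit configuration value.
* **Problem sizes in the test suite** (the package's own choices for
  laptop-scale runs): the pretraining learnability check uses the full
  desk preset (V = 2000, 1000 cells, 3 epochs); fine-tuning, alignment,
  imputation, and icTSS recovery use a smaller preset (V = 400–500,
  300–400 cells, `d_model = 32`, `L = 2`) where the same claims hold with
  large margins.

## Known limitations

Attention is exact and dense (`O(n^2)` per cell), so paper-scale contexts
of 8,192 tokens are outside the intended envelope of this implementation.
The tokenizer holds inputs in memory (no tabix streaming). The RNA tower is
a small MLP, not a pretrained transcriptome model; absolute alignment
quality on real multiome data would depend on that component. The icTSS
analysis presumes the embedding space is already organized by regulatory
class — it inherits any failure of pretraining to achieve that.
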