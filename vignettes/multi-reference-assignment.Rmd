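---
title: "Multi-reference cell-type assignment by multitask deep metric learning"
author: "scMultiRef"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-reference cell-type assignment by multitask deep metric learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Reference-based cell-type annotation labels each cell of an unlabeled
scRNA-seq *query* by comparing its expression profile with annotated
*reference* cells. With public single-cell data accumulating, several
labeled references for the same tissue are usually available — measured on
different platforms, in different labs, with different batch effects and
different (overlapping) sets of cell types. Two families of strategies
exist:

* **data-level integration** merges the references into one batch-corrected
  matrix first and assigns against the merged reference; over-correction
  can erase genuine rare populations;
* **decision-level integration**, the strategy implemented here, never
  merges expression matrices. Each reference keeps its identity; a query
  cell is scored against every reference separately and takes the label of
  the overall best match.

The contribution of this package sits in how the comparison space is
learned: a single embedding network is trained **jointly** on all
references by deep metric learning, so that the biological structure the
references share is reinforced while batch-specific variation — which is
not shared — is not.

## Model

### Preprocessing

Each reference is filtered and normalized independently:

1. **Cell quality control** — a cell is kept only if it detects more than
   500 genes, has more than 1500 total UMIs, and has a mitochondrial count
   fraction below 10% (all inequalities strict; boundary cells fail).
   Mitochondrial genes are recognized by the case-insensitive identifier
   prefix `MT-` (configurable). QC is always applied to references and is
   optional for queries.
2. **Rare-type filtering** — cell types with fewer than 10 cells are
   removed; so few cells cannot define a reliable centroid.
3. **Normalization** — counts are scaled to 10 000 per cell and transformed
   with the natural `log(x + 1)`. After this step
   `sum(exp(v) - 1) == 10000` holds per cell, a useful invariant for
   testing.
4. **Gene-union formatting** — the feature space is the union of all
   reference gene identifiers, sorted lexicographically (byte order) so
   the column order is machine-independent. Genes absent from a dataset
   become all-zero columns; the union is frozen at training time, and
   query-only genes are dropped.

### Embedding network and N-pair loss

The embedding kernel \(f(\cdot;\theta)\) is a two-layer perceptron: input
dimension = |gene union|, a 500-node rectified hidden layer, and a linear
20-dimensional output. Embeddings are deliberately **not**
length-normalized, because the loss below uses raw inner products.

Training batches implement the N-pair construction. From one reference
with \(N\) cell types, one *anchor* \(x_i\) and one *positive* \(x_i^+\)
(a different cell of the same type) are drawn per type, uniformly without
replacement. Writing \(f_i = f(x_i)\), \(f_i^+ = f(x_i^+)\), the loss is

\[
L \;=\; \frac{1}{N}\sum_{i=1}^{N}
\log\!\Big(1 + \sum_{j \neq i}
\exp\big(f_i^\top f_j^+ - f_i^\top f_i^+\big)\Big).
\]

Each anchor is thus pushed toward its own positive and away from the
positives of all other types simultaneously. The implementation shifts the
log-sum by the row maximum, so very large inner products cannot overflow;
the identical-embedding value \(\log N\) and the \(L \to 0\) limit for
well-separated pairs are asserted in the test suite, and the vectorized
form is checked against a scalar double-loop oracle.

### Multitask training

With \(m\) references, each reference is one *task*. Every iteration
samples one N-pair batch per task, sums the \(m\) losses, and applies one
optimizer step to the **fully shared** parameters — no task-specific
layers, no task weights. Labels never cross task boundaries, so references
may use different cell-type vocabularies; what is shared is only the
embedding geometry. Optimization uses Adam (initial learning rate
5e-4) with an L2 regularization rate of 0.05, applied as a decoupled
weight-decay coefficient, for 300 epochs by default.

Two conventions the underlying description leaves open are fixed here and
exposed as parameters:

* **epoch size** — `batchesPerEpoch` defaults to
  \(\lceil \max_t\, n_t / (2N_t) \rceil\), so one epoch visits roughly
  every cell of the largest task once;
* **initialization / activation** — He-initialized weights, zero biases,
  rectifier hidden activation, linear output.

Training runs single-threaded on a CPU; the forward/backward pass and the
optimizer inner loop are compiled (RcppArmadillo). Given a seed, runs are
bit-reproducible.

### Assignment

After training, every reference is embedded and collapsed to one centroid
per cell type (plain arithmetic mean of its cells' embeddings — with
unnormalized embeddings the plain mean is the natural choice). A query
cell is embedded once and its Pearson correlation with every centroid of
every reference in the *decision set* (default: all references) is
computed; the cell takes the label and source reference of the maximal
similarity. Every cell is assigned — there is no "unassigned" outcome and
no rejection threshold. Ties are broken deterministically by (reference
name, cell type) lexicographic order. A degenerate constant embedding
(possible with dead rectifier units) yields similarity `-Inf` plus a
warning, so it can never win.

Restricting the decision set is what makes the cross-species protocol
possible: auxiliary references (say, another species) participate in
*training* and shape the embedding, but only the within-species reference
is consulted at decision time.

### Evaluation

Performance is summarized by the macro-F1 score: per cell type,
\(F1_i = 2 P_i R_i / (P_i + R_i)\) from that type's precision and recall,
averaged without weights over the \(N\) types present in the truth. A
type that is never predicted contributes \(F1_i = 0\) (0/0 terms are
defined as 0); predicted-only labels add no class of their own. The
implementation is verified against an independent confusion-matrix oracle.

## The synthetic test bed

No public accession is required for testing: `simulateBatches()` generates
multi-batch count data with controlled biology and batch structure.

* per-gene baseline means are log-normal (`meanlog = 1`, log-sd 1), with a
  10-gene mitochondrial block at 4x baseline so QC mito fractions are
  realistic (~4–6%);
* each type up-regulates its marker genes by `exp(markerLogFold)`
  (default log-fold 2);
* each batch multiplies every gene mean by a fixed log-normal factor with
  log-sd `batchSeverity` (default 0.5) — the "batch effect";
* cells carry a log-normal library-size factor (log-sd 0.2), and counts
  are gamma-Poisson (negative binomial, dispersion 0.3).

The defaults were calibrated once so that a simulated cell passes the
*default* QC thresholds (median ~790 detected genes, ~5300 UMIs): the full
pipeline, including QC at its standard settings, can therefore run
unmodified on synthetic data. The generator emulates type signal,
batch-specific multiplicative distortion, library-size variation and
overdispersion; it does **not** model dropout-expression coupling,
realistic library-size distributions, doublets or ambient RNA, so passing
tests demonstrate correctness of the method's machinery and the direction
of its comparative claims — not performance on real tissues.

### Preset designs

Four canonical configurations (`presetConfig()`) drive the package's
experiments; they are also the problem sizes used by the test suite and by
`scripts/acceptance.R`:

* **separable** — 4 batches x 4 types x 60 cells, marker log-fold 2,
  severity 0.5. Leave-one-batch-out training (50 epochs) recovers held-out
  labels with macro-F1 above 0.95 across seeds.
* **confusable** — types A and B share half of their 16 markers at full
  strength; their own markers are attenuated to 30% of the log-fold;
  severity 0.6. The design intent is a pair *confusable within any single
  batch but jointly separable*: the weak distinct signal is deliberately
  spread over several genes, because a signal concentrated on one or two
  genes is the same size as the per-gene batch distortion and no amount of
  pooling can recover it, whereas a spread-out signal averages out
  independent batch noise across tasks. With one reference the pair is
  near the edge of separability; trained jointly on three references (100
  epochs — the weak-signal regime needs more optimizer steps than the
  separable one) the multitask model scores higher on the pair than the
  best single-reference model.
* **scaling** — the separable design with 6 batches, used to measure
  macro-F1 as a function of the number of references (r = 2..5, one batch
  held out, reference subsets drawn without replacement).
* **crossSpecies** — the confusable design with 150 cells per type. One
  batch is the "target species"; a stratified 10% split of it (after QC)
  is the only in-decision reference and the remainder is the query, while
  the other batches — simulated with doubled batch severity to stand in
  for a related species — join training only (60 epochs). 150 cells per type ensures
  the 10% split still clears the rare-type filter.

## Numerical and design choices

* **Strict QC inequalities** — boundary cells (exactly 500 genes, exactly
  1500 UMIs, exactly 10% mito) are removed.
* **Natural logarithm** for the log-transform.
* **Duplicate gene identifiers** are collapsed by summation at read time.
* **Stability** — the loss uses a max-shifted log-sum; gradients are
  analytic and are checked against central finite differences (relative
  error < 1e-4 on a small network).
* **Determinism** — one integer seed fixes initialization, batch sampling
  and simulation; two runs with the same seed produce identical loss
  histories and identical weights.
* **Degenerate inputs** — zero-total cells are rejected before
  normalization; constant embeddings get `-Inf` similarity; a query with
  no genes in common with the union runs (all-zero input) but warns
  prominently.
* **Model archive** — a versioned named list (RDS) holding weights, gene
  union, centroids and the resolved configuration; loading verifies the
  format tag and fails loudly on truncated files.

## Limitations

* The comparison of integration strategies on real tissues is out of
  scope here; the synthetic designs establish internal correctness and
  qualitative behavior only.
* No alternative metric-learning losses, deeper architectures, early
  stopping or task weighting are provided.
* Assignment is strictly centroid-based; a k-nearest-cells mode is
  deliberately not offered.
* There is no rejection option: cells of a type absent from every
  reference will still receive some label.

## Session info

```{r}
sessionInfo()
```
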