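# scMultiRef

Cell-type assignment for single-cell RNA-seq queries using **multiple
labeled reference datasets at once**. One embedding network is trained
jointly on all references by deep metric learning with the N-pair loss
(one task per reference, fully shared parameters); query cells are then
assigned at the **decision level**: each cell takes the label of the
cell-type centroid — across all transformed references — with the highest
Pearson correlation to its embedding. Reference matrices are never merged
or batch-corrected, so the over-correction risk of data-level integration
does not arise, while information shared between references still improves
the embedding.

Intended users: bioinformaticians annotating scRNA-seq data who have
several labeled references for the same tissue (different labs, platforms
or even species) and want one model that exploits all of them.

## Method in brief

Per reference, cells pass quality control (> 500 detected genes, > 1500
UMIs, < 10% mitochondrial counts; all strict), rare types (< 10 cells) are
dropped, counts are scaled to 10 000 and log-transformed, and all datasets
are aligned to the lexicographic union of reference genes (absent genes
zero-filled). The embedding kernel *f*(·; θ) is a two-layer network
(500-node rectified hidden layer, 20-d linear output) trained with the
N-pair loss over anchors x_i and positives x_i⁺ drawn per cell type:

    L = (1/N) Σ_i log(1 + Σ_{j≠i} exp(f_iᵀ f_j⁺ − f_iᵀ f_i⁺))

With *m* references the per-task losses are summed each iteration and the
shared parameters updated by Adam (lr 5e-4, weight-decay 0.05, 300 epochs
by default). Assignment scores each query embedding against every
reference's per-type centroids by Pearson correlation and takes the
argmax; an optional restricted *decision set* supports cross-species use
(auxiliary references train the embedding but are not consulted at
decision time). Accuracy is reported as macro-F1.

## Worked example

Train on three simulated reference batches and assign the held-out batch
(the built-in generator produces multi-batch counts with type signal and
batch distortion; no downloads needed):

```r
library(scMultiRef)

batches <- simulateBatches(presetConfig("separable", seed = 1))
batches[[2]]
#> ScBatch 'batch2': 1000 genes x 240 cells (raw counts)
#>   4 cell types: A (60), B (60), C (60), D (60)

prep  <- preprocessReferences(batches[-1])        # QC, filters, union
model <- trainModel(prep$refs, trainParams(epochs = 50, seed = 1))
model
#> MultiRefModel: 3 reference task(s), 1000-gene union, 20-d embedding
#>   - batch2: 4 cell types
#>   - batch3: 4 cell types
#>   - batch4: 4 cell types
#>   loss: 12.7951 (epoch 1) -> 0.0077 (epoch 50)

res <- assignCells(model, batches[[1]])           # held-out query batch
head(res, 3)
#>        cell_id predicted_type best_similarity source_reference
#> 1 batch1_c0001              A       0.8791450           batch3
#> 2 batch1_c0002              A       0.8869552           batch2
#> 3 batch1_c0003              A       0.9058889           batch2

truth <- cellTypes(batches[[1]]); names(truth) <- colnames(batches[[1]])
macroF1(truth[res$cell_id], res$predicted_type)$macroF1
#> [1] 0.995833
```

Each row of `res` is one query cell: the winning cell type, the Pearson
similarity of the cell's embedding to the winning centroid, and which
reference supplied that centroid. The macro-F1 of 0.996 means the held-out
cells of every type were recovered almost perfectly — the expected outcome
on the well-separated preset; the `confusable` and `crossSpecies` presets probe
the harder regimes (see the vignette).

## Command line

A thin script over the same functions is installed with the package:

```sh
Rscript inst/scripts/scmultiref.R simulate --out refs/ --seed 1
Rscript inst/scripts/scmultiref.R train    --refs refs/ --model-out model.rds --seed 1
Rscript inst/scripts/scmultiref.R assign   --model model.rds --query refs/batch1.counts.tsv --out assign.tsv
Rscript inst/scripts/scmultiref.R evaluate --truth refs/batch1.labels.tsv --pred assign.tsv
```

Exit codes: 0 success, 2 usage error, 1 runtime error. Defaults follow the
standard setting above; a flat YAML config (`--config`) overrides them.

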