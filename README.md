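# txseg

Reference-guided cell segmentation for imaging-based spatial
transcriptomics by reinforcement learning.

Imaging-based spatial transcriptomics (MERFISH, Xenium, CosMx, MERSCOPE)
localises individual mRNA molecules but leaves open which cell each
molecule belongs to. `txseg` assigns molecules to cells directly from the
molecule table and an scRNA-seq reference — no stain images required. A
policy network scores each molecule against its *m* nearest candidate cell
centers and a binary noise head; sampled assignments are rewarded by

```
reward_i = NDS_i * CDS_i * ESS_i          (non-noise action)
           (1 - NDS_i) * CDS_i * ESS_i    (noise action)
```

where `NDS` measures local transcript density (quantile-rectified mean
distance to the 100 nearest molecules), `CDS` proximity to the assigned
cell's center (re-estimated each step as the mean of its molecules), and
`ESS` expression feedback from a deconvolution network that learns, per
candidate cell, a predicted profile as an adaptive mixture of
reference-derived cell-type states. The policy is trained by the score
function (REINFORCE) estimator `-(1/n) Σ reward_i [ln P(G_i) + ln
P(H_i)]`, alternating each epoch with 30 Adam iterations of the
deconvolution's cosine alignment loss. Afterwards, cell boundaries are
traced as alpha shapes of the assigned molecules, and whole-transcriptome
profiles are imputed as occurrence-weighted convex combinations of the
most similar reference cells.

The package also provides candidate-center seeding (marker scoring, grid
density features, DBSCAN → K-means → mean-shift), a nuclear-boundary prior
mode, a sequencing-based (spot matrix) adaptation, benchmarking metrics
(expression similarity, boundary IoU, morphology density agreement,
masked-gene imputation accuracy, label transfer), and a synthetic
tissue + reference generator with ground truth. For whom: analysts of
imaging ST data who have a matched scRNA-seq reference and want
segmentation-free transcript assignment, and method developers who need a
transparent, fully deterministic CPU implementation with ground-truth
validation.

## Worked example

Simulate a 100-cell tissue with a matched reference, segment it, and
inspect the result (about 45 seconds on one CPU core):

```r
library(txseg)

spec <- synthetic_spec(n_cells = 100, n_types = 6, seed = 42)
ds   <- simulate_dataset(spec)
res  <- segment_cells(ds$tissue$transcripts, ds$reference$counts,
                      ds$reference$cell_type,
                      config = seg_config(epochs = 50, seed = 42))

mean(!res$assignment$noise)        # fraction of molecules assigned
sum(rowSums(res$E) > 0)            # cells recovered
assignment_accuracy(res$assignment$cell, ds$tissue$truth$true_cell)
```

```
molecules: 10683
assigned fraction: 0.775
cells with molecules: 94
assignment accuracy vs truth: 0.869
```

94 of the 100 generated cells are recovered; 86.9% of assigned molecules
land in their true generating cell, against 83.5% for the
nearest-candidate baseline — the expression feedback is what re-routes
boundary molecules.
Label transfer and imputation complete the picture:

```r
lt  <- label_transfer(res$E[rowSums(res$E) > 0, ], res$reference)
table(lt$type)
imp <- impute_transcriptome(res$E[rowSums(res$E) > 0, ], res$reference)
res$polygons[[1]][c("area", "girth")]
```

```
type1 type2 type3 type4 type5 type6
   16    17    16    18    17    10
imputed matrix: 94 cells x 100 genes
first cell polygon: area 88.7 um^2, girth 50.5 um, roundness 0.438
```

A command-line interface wraps the same functions
(`exec/txseg simulate | estimate-candidates | segment | impute |
evaluate`), reading delimited molecule tables (with Xenium/CosMx/MERFISH
column presets) and MatrixMarket references, and writing assignment CSVs,
count matrices, GeoJSON polygons and JSON-lines run logs.

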