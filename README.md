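# sublocr

Sub-organellar localisation of proteins from amino-acid sequence
representations.

Assigning a protein to an organelle is a well-served prediction task;
placing it *within* the organelle is not. `sublocr` addresses two such
problems: deciding whether a peroxisomal protein resides in the granular
**matrix** or on the **membrane** (binary mode), and assigning a
mitochondrial protein to one of the four compartments — **o**uter
membrane, **i**nner membrane, in**t**ermembrane space, **m**atrix
(4-class mode).

## Approach

A protein sequence of length *L* is converted into fixed-length
per-protein feature blocks:

* **1HOT** — each residue is a 1×20 indicator vector (columns in
  alphabetical one-letter order, so alanine is `1` followed by nineteen
  `0`s); the *L*×20 matrix is mean-pooled to the amino-acid composition
  vector.
* **PROP** — each residue maps to the ten orthogonal physico-chemical
  factors of Kidera and co-workers (*L*×10, mean-pooled).
* **PSSM** — per-position substitution scores parsed from a PSI-BLAST
  ASCII profile, mapped into (0,1) by the logistic sigmoid
  1/(1+e^−x), then mean-pooled (*L*×20).
* **UNIREP / SEQVEC** — per-protein language-model embeddings consumed
  as delimited tables (contracted widths 1900 and 1024; their
  concatenation is the 2924-dimensional representation).

The best block combination is found by **step-forward selection**: each
block is scored alone, the best is kept, blocks are added one at a time
and an addition is accepted only on strict improvement of the inner
score. This search runs inside the calibration loop of a **stratified
double cross-validation** (5 outer × 5 inner folds): the inner loop
also tunes classifier hyperparameters and per-class weights
(metaparameters for the 132:28 class imbalance typical of curated
peroxisomal sets); the outer loop reports unbiased performance on
untouched validation folds.

Classifiers: SVM (`e1071`), random forest (`ranger`), penalised
logistic regression (`glmnet`), and a package-native **PLS-DA**
(partial least squares regression on a 0/1 dummy response; a test score
Y ≥ 0.5 means class 1).

Performance is reported as ACC, macro F1, BACC = (TPR+TNR)/2, and
MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)), with per-class
one-vs-rest MCC in 4-class mode. Zero-denominator cases are flagged
undefined, never silently zeroed.

## Worked example

Everything below runs offline: the synthetic module generates
class-conditional Gaussian embedding blocks (here a 60-wide informative
block with a 3-sd class shift and a 40-wide noise block) for the
132:28 binary preset.

```r
library(sublocr)

sp <- synthetic_spec(preset = "pero", dims = c(UNIREP = 60, SEQVEC = 40),
                     informative_blocks = "UNIREP", delta = 3, seed = 0,
                     length_range = c(50, 400))
ds <- gen_sequences(sp)
ds
#> labeled_dataset: 160 proteins; 2 classes ( matrix:28, membrane:132 )

blocks <- gen_embeddings(ds$records$id, ds$labels, sp)
spec <- classifier_spec("SVM",
                        grid = list(cost = c(0.01, 1, 100), kernel = "linear"),
                        class_weights = c("uniform", "balanced",
                                          "minority2", "minority5"))
cfg <- dcv_config(outer_folds = 5, inner_folds = 5, seed = 0)
res <- run_dcv(lapply(blocks, function(b) b$vectors),
               unname(ds$labels), spec, cfg, ids = ds$records$id)
res
#> dcv_result: 5 outer folds; modal selection: UNIREP
#>   F1(inner) 0.865
#>   F1(outer) 0.864 ± 0.065
#>   BACC(outer) 0.864 ± 0.052
#>   MCC(outer) 0.736 ± 0.124
#>   ACC(outer) 0.919 ± 0.046
```

The forward selection keeps the informative block (modal selection
`UNIREP`) and discards the noise block; the outer-fold summary shows
what an unseen-protein evaluation of that configuration looks like:
accuracy 0.92 is flattered by the 82% majority class, while BACC 0.86
and MCC 0.74 reflect performance on both classes.

From a shell, the same steps are available as commands
(`exec/sublocr`): `simulate`, `encode`, `evaluate`, `train`, `predict`,
e.g.

```sh
sublocr predict --fasta candidates.fasta \
  --embeddings UNIREP=unirep.tsv --embeddings SEQVEC=seqvec.tsv \
  --model pero_model.rds --out predictions.tsv
```

writes one `id<TAB>matrix|membrane` line per candidate in FASTA order.

## Working with real data

Real embedding tables are produced with the upstream UniRep and SeqVec
embedders (per-protein level; 1900-/1024-wide rows keyed by sequence
id) and consumed as `id<TAB>v1<TAB>...` tables — `sublocr` never runs
the neural networks. PSSM profiles come from
`psiblast -out_ascii_pssm` (three iterations against UniRef90, e-value
0.001 is the setting the packaged parser was written against). A
curated training set of the kind this tool targets is built from
UniProtKB/SwissProt by selecting reviewed, non-fragment entries with an
experimentally supported sub-organellar location annotation, clustering
at 40% identity (Cd-hit) keeping cluster representatives, and retaining
proteins with at least one localisation-specific publication; that
curation is documented here as a recipe, not executed by the package.

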