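# mcomplete

Dropout imputation for single-cell RNA-seq by low-rank matrix
completion.

scRNA-seq count matrices are riddled with *dropouts* — zeros caused by
transcripts that failed capture or amplification, not by absent
expression. Because genes are coupled through shared regulatory
programs, the cell-by-gene expression matrix is approximately low rank,
and recovering dropouts becomes a matrix-completion problem: treat the
non-zero entries as observations `Y = A(X)` of a complete low-rank
matrix `X` (with `A` the binary sampling mask) and solve

    min_X  || Y − A(X) ||_F²  +  λ_eff || X ||_*

by iterative singular-value soft-thresholding under a non-negativity
constraint (`nnm_impute()`; `||·||_*` is the nuclear norm, the convex
surrogate for rank). A rank-constrained alternating-least-squares
factorization solver (`mf_impute()`) is included for comparison. No
distribution is assumed for expression or for the dropout mechanism.

The package is aimed at people building or benchmarking scRNA-seq
pipelines: it bundles the full preprocessing chain with exact inverses
(so imputed matrices come back on the log, normalized and count
scales), a ground-truthed synthetic-data generator, and the evaluation
battery used to judge imputation quality (held-out recovery error,
cell-type separability, clustering ARI, zero-fraction binning against a
bulk reference, CV–mean relation, silhouette, rank-sum DE with ROC
AUC).

## Worked example

```r
library(mcomplete)

sim <- generate_scrnaseq(seed = 1)   # 500 cells x 300 genes, 3 clusters,
                                     # planted rank 6, ~22% dropouts
imp <- impute_dropouts(sim$observed, method = "nnm", filter = FALSE)
imp$result
#> <ImputationResult> method = nnm, 162 iterations (converged),
#>   objective 1.36405e+06 -> 10137.1

obs_log <- log_transform(library_size_normalize(sim$observed))
cts_score(obs_log, sim$labels, "cluster1", "cluster2")$cts   # 0.5730
cts_score(imp$log, sim$labels, "cluster1", "cluster2")$cts   # 0.7734
```

Imputation raises the cell-type separability score (within-group median
Spearman correlation minus cross-group) from 0.57 to 0.77: cells of the
same type resemble each other more once dropouts are filled. True
biological zeros are better preserved than dropouts under the
"values in [0, 0.5) are zeros" convention:

```r
mean(imp$counts$values[sim$structural_zero_mask == 1] < 0.5)  # 0.0370
mean(imp$counts$values[sim$dropout_mask == 1] < 0.5)          # 0.0091
```

A command-line wrapper ships in `inst/cli/mcomplete`:

```sh
Rscript inst/cli/mcomplete simulate --cells 200 --genes 150 --seed 7 --out-prefix sim
Rscript inst/cli/mcomplete impute --input sim.counts.csv --no-filter --out-prefix imp
Rscript inst/cli/mcomplete eval-recovery --input sim.counts.csv --ratios 0.4,0.6 --seeds 1,2,3 --out rec.csv
```

See `vignettes/low-rank-imputation.Rmd` for the model, the solver
details (MM surrogate, scale-free λ, stopping rules), the generator's
design and its limits, and the numerical choices.

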