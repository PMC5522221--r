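# chromexpr

Estimating the effects of transcription-factor (TF) binding, histone
modifications (HMs) and DNase-I hypersensitivity on gene expression.

Gene expression is predictable to a striking degree from the chromatin
context of the promoter alone. This package implements a complete
analysis pipeline for quantifying that predictability and — the part
that matters biologically — dissecting the *statistical redundancy*
among the predictors: which factors carry unique information, which are
interchangeable, and whether TFs and HMs inform expression through a
shared signal or through separate ones. It is aimed at computational
biologists working with ChIP-seq/DNase-seq tag tracks and RNA-seq
expression, and it ships a ground-truth synthetic-data generator so
every estimator can be validated end to end.

## The model

For gene $i$ and TF $k$, tags are counted in 100 bins of 200 bp spanning
TSS ± 10 kb and depth-normalized,
$N^k_{ij} = n^k_{ij}\,10^9 / (n^k_{\mathrm{tag}}\,200)$; HMs and DNase
use TSS ± 2 kb in 20 bins. Binned signal collapses to per-gene
association strengths

$$a_{ik} = \sum_{j=1}^{100} N^k_{ij}\,F_k(d_j), \qquad
  b_{il} = \sum_{m=1}^{20} H^l_{im},$$

where $F_k$ is a normalized Gaussian kernel of the bin-midpoint distance
$d_j$ with Silverman rule-of-thumb bandwidth, followed by
$\log_2(x + \sigma)$. Expression is modelled as

$$\log_2(L_i + \sigma) = \nu + \sum_k \alpha_k a'_{ik}
  + \sum_l \beta_l b'_{il}$$

by ordinary least squares, and nonparametrically by epsilon-SVR with an
RBF kernel (libSVM via `e1071`), both under 10-fold cross-validation.
Downstream: exhaustive factor-subset ("combination mode") evaluation
with max-PCC curves and top-mode over-representation; TF-only vs HM-only
cross-model prediction correlation; a Schäfer–Strimmer shrinkage
partial-correlation network over factors + expression with
leave-genes-out robustness; and gene-set-level banding of the TF/HM
predictive-power ratio among highly expressed genes.

## Worked example

```r
library(chromexpr)

cfg   <- sim_config(seed = 1)            # 2000 genes, 5 TFs, 4 HMs + DNase
genes <- simulate_genes(cfg)
tracks <- simulate_tracks(genes, cfg)
assoc <- associate_tracks(tracks, genes) # bin + kernel/sum + log2
y     <- log_expression(genes)

fit_svr(assoc, y, seed = 1)
#> svr model on 10 features: R2 = 0.885, CV-R2 = 0.799, PCC = 0.894
fit_log_linear(assoc, y, seed = 1)
#> log_linear model on 10 features: R2 = 0.821, CV-R2 = 0.819, PCC = 0.905
```

The SVR recovers an all-factor cross-validated PCC of 0.89 here because
the ten synthetic factors jointly generate expression with noise sd
equal to each factor's effect; class-only models reach CV-R² ≈ 0.4
(`analysis/03_expression_models.R` prints the full table). On the
natural RPKM scale — where the truth is a convex function of the
features — the SVR clearly beats the linear model (CV-PCC 0.69 vs 0.58).

The numbered scripts under `analysis/` run the whole study on synthetic
data and write their tables to `results/`:

1. `01_simulate.R` — generate genes, tracks, ground truth (and verify
   10/10 coefficients are recovered within 2 SE).
2. `02_signal_features.R` — binned signal → association matrix.
3. `03_expression_models.R` — log-linear vs SVR per feature class;
   stepwise selection of 15 TFs from a 20-candidate pool.
4. `04_combination_modes.R` — all 31 modes per class under engineered
   redundancy: the max-PCC curve flattens at four factors (0.784 of
   0.800 for TFs) and redundant partners rarely co-occur in top modes.
5. `05_redundancy_network.R` — correlation heatmap, cross-model PCC,
   12-edge partial-correlation network (expression links recovered for
   9 of 10 informative factors; mean Jaccard 0.96 across 50 replicates
   removing 200 genes).
6. `06_geneset_ratios.R` — TF/HM PCC ratio bands for biased gene sets:
   TF-favoured sets band TF-superior (median ratio 1.49), HM-favoured
   band HM-superior (median 0.57).

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

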