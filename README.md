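# metabotree

Two-stage hierarchical classification of lung-cancer type from metabolite
molecular descriptors.

## The problem

Lung cancers fall into two major histopathologic categories — non-small-cell
(NS) and small-cell (SC) carcinoma — and NS further splits into
adenocarcinoma (AD) and squamous cell carcinoma (SQ), which need different
chemotherapy regimens. Metabolite biomarkers measured in patient sera carry
a signature of the cancer type: each candidate metabolite can be described
by a vector of molecular descriptors computed from its structure (SMILES),
and a classifier over descriptor space can assign it to the cancer profile
it matches.

`metabotree` implements the full pipeline for this task as a tested,
reusable R package, for computational biologists who want to reproduce,
probe, or extend hierarchical metabolomics classifiers:

1. **Filtering** — keep metabolites with differential-abundance
   *p* ≤ 0.05 and fold change ≥ 1.2 (inclusive, configurable);
2. **Normalization** — column-wise min–max scaling
   x' = (x − min x)/(max x − min x);
3. **Feature selection** — information gain
   IG(T, a) = H(T) − H(T|a), with H(T) = −Σ P log₂ P, computed over
   discretized descriptors; the top k = 170 descriptors are kept
   (the headline configuration reduces 1083 PaDEL-style descriptors to 170);
4. **Dimensionality reduction** — PCA by eigendecomposition of the sample
   covariance Cov(X) = (X−E X)(X−E X)ᵀ/(N−1), and t-SNE implemented from
   first principles: per-point Gaussian bandwidths calibrated to a target
   perplexity by binary search, symmetrized similarities
   sᵢⱼ = (Pr(i|j)+Pr(j|i))/(2N), Student-t low-dimensional affinities
   Qᵢⱼ, and gradient descent on KL(S‖Q);
5. **Classification** — feedforward networks (hidden layers 300-400-300,
   ReLU, dropout 0.5, Adam, learning rate 0.01 · 0.96^min(s, 10000),
   500 full-batch epochs) arranged as a tree: stage 1 separates NS from SC;
   samples predicted NS are routed to stage 2, which separates AD from SQ;
6. **Evaluation** — stratified 5-fold cross-validation and independent-set
   protocols; the overall accuracy combines the stages by the
   class-fraction-weighted product rule

   overall = SC% · acc₁ + NS% · acc₁ · acc₂

   (an NS sample must survive both stages — error propagation), plus a naive
   flat multiclass baseline for comparison.

A seeded synthetic-data generator produces hierarchically labeled datasets
(a nonlinear concentric "shells" NS/SC split and an AD/SQ mean shift inside
NS, planted in high-dimensional descriptor space) so every stage of the
pipeline is testable without any external data.

## Worked example

```r
library(metabotree)
mt_verbose(FALSE)

sim <- generate_hierarchical_dataset(synthetic_spec(seed = 42))
rep <- cross_validate(sim$dataset, k = 5, config = pipeline_config(),
                      seed = 7, baseline = TRUE)
print(rep)
```

```
<evaluation_report> protocol: cv5
  stage 1 (NS/SC): 0.976 +/- 0.022
  stage 2 (AD/SQ): 1.000 +/- 0.000
  class fractions: NS 0.720 / SC 0.280
  overall accuracy: 0.976
  naive multiclass baseline: 0.984
```

Reading the output: stage 1 classified 97.6% ± 2.2% of held-out metabolites
correctly as NS vs SC across the five folds; stage 2 separated AD from SQ
perfectly on held-out true-NS rows; with 72% NS / 28% SC in the data the
product rule gives 0.280·0.976 + 0.720·0.976·1.000 = 0.976 overall. On this
strongly separated synthetic world the flat 3-class baseline is equally
accurate — see the methods vignette for why the two approaches only diverge
when the flat task is materially harder.

The published configuration's arithmetic reproduces directly:

```r
overall_accuracy(0.962, 0.911, 0.487, 0.513)
#> [1] 0.920304
```

## Command line

```sh
Rscript inst/cli/metabotree simulate --out data/ --seed 1
Rscript inst/cli/metabotree cv --table data/table.csv --matrix data/descriptors.csv --out results/
Rscript inst/cli/metabotree baseline --table data/table.csv --matrix data/descriptors.csv
Rscript inst/cli/metabotree combine-accuracy --stage1 0.962 --stage2 0.911 --ns-frac 0.487 --sc-frac 0.513
```

`cv`/`run`/`evaluate` accept `--config config.json` (see
`pipeline_config()` for the schema; the run writes a `config_echo.json`
sufficient to reproduce it bit-for-bit).

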