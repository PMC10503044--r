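# tensorfe

Unsupervised selection of differentially expressed features from omics
tensors, for transcriptomics datasets whose samples have a crossed
structure (replicates × ordered conditions) and for multiomics datasets
whose layers share a sample axis. No supervised model is fitted and no
labels enter the single-tensor path: components are chosen by what a
meaningful sample pattern should look like, and features are tested
against a calibrated Gaussian null.

## Method

A feature × replicate × condition tensor $x_{ijk}$ is decomposed by
higher-order singular value decomposition (Tucker/HOSVD):

$$x_{ijk} = \sum_{\ell_1}\sum_{\ell_2}\sum_{\ell_3}
  G(\ell_1\ell_2\ell_3)\,u_{\ell_1 i}\,u_{\ell_2 j}\,u_{\ell_3 k}$$

The replicate-mode component most constant across replicates and the
condition-mode component most monotone in the ordinal condition are
selected (override flags replace the interactive inspection this stands
in for); the feature-mode component $\ell_1$ sharing the
largest-magnitude core weight $G(\ell_1,\ell_2,\ell_3)$ with them is then
identified, and each feature is assigned

$$P_i = P_{\chi^2}\!\left[>\left(u_{\ell_1 i}/\sigma_{\ell_1}\right)^2\right]
\quad (1 \text{ d.o.f.})$$

with $\sigma_{\ell_1}$ optimized so the scores look as Gaussian as
possible (flatness of the $1-P$ histogram outside the signal tail).
$P$-values are Benjamini–Hochberg adjusted; features with adjusted
$P < 0.01$ are selected.

For $K$ omics layers $x_{i_k j}$ sharing $M$ samples, the sample-space
Gram tensor $x_{jj'k} = \sum_{i_k} x_{i_k j} x_{i_k j'}$
($M × M × K$; memory never scales with feature counts) is decomposed
instead; the sample-mode singular vector tracking the phenotype labels is
back-projected onto each layer's features
($u_{\ell_1 i_k} = \sum_j u_{\ell_1 j} x_{i_k j}$), and the same null
model selects features per layer with a per-layer $\sigma$.

See the vignette (`vignettes/tensor-feature-extraction.Rmd`) for the
null-model calibration details, component-scoring statistics, numerical
conventions and known limitations.

## Worked example

Generate a synthetic staged-expression tensor (1,000 features × 9
replicates × 4 ordered conditions, 100 features carrying a planted
monotone trend) and run the pipeline:

```r
library(tensorfe)

sim <- make_deg_tensor(synthetic_spec(seed = 7))
res <- run_deg(sim$tensor)
res
#> deg_result: components (l1, l2, l3) = (2, 1, 2); 102 / 1000 features
#>   selected at adjusted P < 0.01

head(res$selection$table, 3)
#>   feature_id   score_u      p_value   adjusted_p selected
#> 1        f58 0.1175830 2.036056e-55 2.036056e-52     TRUE
#> 2       f726 0.1121601 1.382777e-50 5.782157e-48     TRUE
#> 3       f571 0.1120469 1.734647e-50 5.782157e-48     TRUE
```

The run chose replicate component 1 (constancy score 81.5, all others
below 0.02) and condition component 2 (Spearman monotonicity 1.0 with a
genuine trend spread), coupled those to feature component 2 via the core
tensor, and optimized the null SD to 0.0075 on that singular vector's
1,000 entries. Of the 102 selected features, 100 are the planted ones
(F1 = 0.99 against ground truth).

The multiomics path, on three layers (500/300/200 features) sharing 40
samples with a 4-level ordinal phenotype:

```r
ms <- make_multiomics_set(synthetic_spec(seed = 7))
mr <- run_multiomics(ms$set, ms$labels)
mr
#> multiomics_result: component l1 = 1
#>   layer1: 50 / 500 selected (sigma = 0.9663)
#>   layer2: 30 / 300 selected (sigma = 0.9995)
#>   layer3: 20 / 200 selected (sigma = 1.175)
```

Each layer's 10% planted features are recovered essentially exactly.

A thin command-line interface wraps the same functions
(`inst/cli/tensorfe.R`; subcommands `hosvd`, `deg`, `multiomics`,
`simulate`), reading TSV/CSV/MatrixMarket matrices plus a
`sample_id / replicate / condition` design sheet and writing feature
tables and a JSON run manifest.

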