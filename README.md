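# nmfimpute

Missing-value imputation for mass-spectrometry metabolomics abundance
matrices, built on an ensemble of masked non-negative matrix factorizations,
with the simulation and evaluation machinery needed to benchmark imputers
under controlled missingness.

## Who this is for

Metabolomics data analysts facing the usual 10–20% of missing entries in a
metabolite × sample intensity table, where missingness mixes random dropouts
(MCAR/MAR) with censoring below the limit of detection (MNAR), and where a
complete matrix is required before any multivariate statistics.

## The method

For a non-negative abundance matrix $X_{I\times J}$ with observed set
$\Omega$, a masked NMF minimizes

$$L=\sum_{(i,j)\in\Omega}\Big(x_{ij}-\sum_{k=1}^{K}b_{ik}c_{kj}\Big)^2,
\qquad B,C\ge 0,$$

by multiplicative updates restricted to $\Omega$. Rather than committing to
one component count, `nmf_impute()` fits $N=20$ models at consecutive $K$
centred on the data's estimated rank, weights each reconstruction by a
softmax of its observed mean absolute error,
$w_K = e^{-d_K}/\sum_K e^{-d_K}$, and imputes each missing cell from the
weighted reconstruction $\hat X=\sum_K w_K\hat X^K$ (observed cells are
passed through untouched). Everything operates on log10 abundances with a
recorded non-negativity offset and returns to the raw scale on output.

The package also provides:

* missingness simulators — MCAR, below-LOD MNAR, and the 20/80 mixed
  pattern — plus a 5σ outlier injector, all exactly seeded;
* baseline imputers: metabolite mean, half-minimum, sample-wise kNN, and an
  iterative random-forest adapter over `randomForest`;
* evaluation metrics: NRMSE on the simulated missing set, correlation-
  network (CCN) precision/recall/F1, and the mean score of ranking (MSR);
* a config-driven benchmark driver (`run_benchmark()`) and a thin CLI
  (`inst/scripts/nmfbench.R`).

See `vignettes/nmf-imputation.Rmd` for the full methods account.

## Worked example

A complete synthetic truth (100 metabolites × 30 samples, latent rank 5),
25% mixed missingness, ensemble imputation, and all three metrics:

```r
library(nmfimpute)

truth <- generate_fixture(100, 30, rank = 5, noise_sd = 0.01, seed = 1)
lod   <- determine_lod(truth)                      # log10 LOD surrogate
sim   <- simulate_mm(truth, x_pct = 25, r_pct = 0, lod = lod, seed = 2)
sim
#> simulated_dataset: pattern MM, x = 25%, r = 0%, |Theta_s| = 750

fit <- nmf_impute(sim$masked, seed = 3)
fit
#> imputation_result (nmf): 100 x 30, 750 entries imputed
head(fit$ensemble$models, 3)
#>    K      d weight
#> 1 11 0.0153   0.05
#> 2 12 0.0164   0.05
#> 3 13 0.0157   0.05

nrmse(sim$truth, fit, sim$theta_s)                          # 0.2014
nrmse(sim$truth, impute_half_min(sim$masked), sim$theta_s)  # 0.7450

msr(sim$truth, list(nmf = fit,
                    halfmin = impute_half_min(sim$masked)), sim$theta_s)
#>     nmf halfmin
#>   1.016   1.984

sc <- network_scores(build_ccn(fit), build_ccn(truth))
c(precision = sc$precision, recall = sc$recall, f1 = sc$f1)
#> precision    recall        f1
#>     0.957     0.999     0.978
```

Reading the numbers: the ensemble's per-model errors `d` are nearly equal,
so the softmax spreads weight almost evenly (0.05 each over 20 models).
NRMSE is the root mean square *relative* error over the 750 artificially
removed entries — 0.20 for the NMF ensemble versus 0.75 for half-minimum.
MSR near 1 means the NMF imputation is closer to the truth than half-min at
almost every missing cell, and the F1 of 0.98 says the metabolite
correlation network rebuilt from the imputed matrix recovers the true
network almost perfectly.

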