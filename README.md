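# hierfcn

Hierarchical sub-network estimation of low- and high-order functional
connectivity from resting-state ROI time series, with a t-test + LASSO +
linear-SVM classification pipeline evaluated by repeated nested
cross-validation. Written for researchers who work with parcellated
rs-fMRI signals (time × ROI matrices) and want, per subject, both the
classic pairwise connectivity *and* a principled estimate of how whole
connectivity patterns co-vary over the scan — without fitting an
intractably high-dimensional model.

## The model

A sliding window (width $l_w$, step $l_s$) over the $M$ time points yields
$K = \lfloor (M - l_w)/l_s \rfloor + 1$ Pearson correlation matrices
$W^{(1)}, \dots, W^{(K)}$. Each is treated as a draw from a matrix-variate
normal with equal Kronecker factors,

$$W^{(k)} \sim \mathcal{MN}(M_u,\, C_u,\, C_u), \qquad
  \operatorname{Cov}[\operatorname{vec} W] = C_u \otimes C_u ,$$

so the MLE mean $M_u$ (elementwise average) is the **low-order**
connectivity and the factor $C_u$ — estimated by a scale-balanced flip-flop
iteration $C \leftarrow \frac{1}{K N_u}\sum_k (W^{(k)}-M_u)\,C^{-1}
(W^{(k)}-M_u)^{\top}$ — is the **high-order** connectivity. Because fitting
all $N = 116$ AAL ROIs at once is hopeless (sample dimension $N^2$ vs at
most $M$ windows), the model is fitted *within* each of six functional
sub-networks (DMN, EAN, SMN, visual, subcortical, cerebellum) and, for
between-network information, on the six network-mean time series. The four
resulting feature blocks are min-max normalised per block, fused, filtered
by a two-sample t-test, sparsified by LASSO and classified by a linear SVM
inside repeated, stratified, nested five-fold cross-validation.

A seeded synthetic-cohort generator (block correlation, optional
state-switching dynamics, controllable group effect) stands in for clinical
data, so the whole pipeline is testable offline.

## Worked example

```r
library(hierfcn)

part <- subnet_partition(list(SMN = 1:4, DMN = 5:8, Visual = 9:12),
                         paste0("r", 1:12))
spec <- cohort_spec(n_per_group = 20, M_time = 120, partition = part,
                    rho_within = 0.5, rho_between = 0.1,
                    effect_network = "DMN", effect_delta = -0.25,
                    n_states = 2, state_dwell = 30, noise_sd = 0.5,
                    seed = 201)
cohort <- generate_cohort(spec)

feats <- extract_features(cohort$timeseries, part, window_spec(30, 6))
res <- nested_cv(feats, cohort$labels,
                 selection_config(p_grid = c(0.05, 0.10),
                                  lambda_grid = c(0.3, 0.6),
                                  cost_grid = c(0.25, 1, 4),
                                  repeats = 2, seed = 301))
res
#> <cv_result> 2 repeats x 5 outer folds
#>   acc: 0.975 +/- 0.053
#>   npv: 1.000 +/- 0.000
#>   ppv: 0.960 +/- 0.084
#>   tnr: 0.950 +/- 0.105
#>   tpr: 1.000 +/- 0.000

contribution_trace(res)
#> # A tibble: 3 x 3
#>   network credit   rate
#>   <chr>    <dbl>  <dbl>
#> 1 DMN       52   0.8
#> 2 SMN        9.5 0.146
#> 3 Visual     3.5 0.0538
```

The cohort plants a connectivity drop of 0.25 on the within-DMN edges of
the patient group. The classifier separates the groups far above the
chance band for 40 subjects (±0.155 around 0.5), and tracing the selected
features back through their provenance attributes 80% of the selection
credit to DMN — the pipeline recovers both the discriminability and its
anatomical source. `dimension_report(aal_subnetworks(), 170)` shows why
the sub-network division is needed at full scale: the sample-dimension
ratio drops from 79.2 (116 ROIs) to at most 4.0 (26 ROIs).

For file-based workflows, `cmd_simulate()`, `cmd_extract()` and
`cmd_classify()` run the same stages against TSV/JSON artefacts on disk
(see `run_config()`), and `inst/cli/hierfcn.R` wraps them as a command-line
tool.

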