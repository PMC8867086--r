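---
title: "The hierarchical sub-network method: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hierarchical sub-network method: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierfcn)
```

## The estimation problem

Resting-state functional connectivity is usually summarised, per subject, by
the Pearson correlation matrix of the ROI time series — a *low-order*
description: one number per ROI pair. Sliding a window of width $l_w$ and
step $l_s$ over the $M$ time points produces a sequence of
$K = \lfloor (M - l_w)/l_s \rfloor + 1$ correlation matrices
$W^{(1)}, \dots, W^{(K)}$, which additionally carries how connectivity
fluctuates over the scan.

This package treats each windowed connectivity matrix as one draw from a
matrix-variate normal distribution,
$$W^{(k)} \sim \mathcal{MN}(M,\; C,\; C), \qquad
  \operatorname{Cov}[\operatorname{vec} W] = C \otimes C,$$
with both Kronecker factors equal because $W$ is symmetric. The MLE of the
mean is the elementwise average of the sequence (`fit_mean()`), and is the
low-order connectivity estimate; the factor $C$ (`fit_factor()`) captures
how whole connectivity matrices co-vary across windows — a *high-order*
description involving many ROIs at once — and both are estimated
simultaneously from the same model.

Fitting this model to all $N = 116$ AAL ROIs at once is hopeless at typical
scan lengths: one vectorised sample has dimension $N^2 = 13456$ while at
most $M$ windows exist (ratio $116^2/170 \approx 79$). The hierarchical
strategy divides the ROIs into $U = 6$ functional sub-networks (DMN, EAN,
SMN, visual, subcortical, cerebellum) and fits the model *within* each
sub-network, where the worst ratio drops to $26^2/170 \approx 4$
(`dimension_report()` prints these diagnostics). Connectivity *between*
sub-networks is then recovered by averaging the ROI series within each
sub-network (`mean_series()`) and fitting the same model to the $U$ mean
series. Each subject therefore yields four tagged feature blocks —
intra-low, intra-high, inter-low, inter-high — vectorised from the fitted
matrices' lower triangles.

## The flip-flop iteration and its numerical guards

The factor MLE satisfies the fixed-point equation
$$C = \frac{1}{K N_u} \sum_{k=1}^K (W^{(k)} - M)\, C^{-1}\, (W^{(k)} - M)^{\!\top}.$$

Three choices the estimating equation does not dictate:

* **Initialisation** is the identity, which is scale-free and makes the
  first iterate the average squared-residual matrix.
* **Scale balancing.** With both factors constrained equal, the raw
  substitution $C \leftarrow f(C)$ alternates the overall scale between the
  two (conceptual) factors — in the $1 \times 1$ case it is exactly the
  2-periodic map $c \mapsto s/c$. Each iterate is therefore rescaled by the
  closed-form likelihood maximiser along the scale direction,
  $\alpha^2 = q/(K n^2)$ with $q$ the quadratic form at the new iterate.
  With this step the scalar case converges in one iteration to
  $c = \sqrt{s}$, the square root of the MLE variance.
* **Stopping** at relative Frobenius change $< 10^{-6}$ or 100 iterations
  (both configurable); every iterate is symmetrised to suppress
  floating-point drift, and the sign is fixed by $\operatorname{tr} C > 0$
  (the factor is identified only up to sign).

When $K < N_u$ the likelihood is unbounded and $C$ may become numerically
singular; a scaled ridge ($10^{-6} \cdot \overline{\operatorname{diag} C}$,
recorded in the fit) is added *only* when inversion needs it. The
log-likelihood is recorded at every iterate; as a safeguard for the
unbounded regimes, an iterate that would *decrease* the log-likelihood is
rejected and the iteration stops at the previous one, so the reported trace
is non-decreasing by construction and the monotonicity test exercises
whether the safeguard ever needs to fire on well-posed inputs (it does not,
on 100 random instances).

## Features, normalisation, selection, classification

Low-order blocks vectorise the strict lower triangle (the diagonal is
identically 1); high-order blocks include the diagonal, which carries
variance information. Triangle traversal is row-major over $i > j$, fixed
so feature indices are stable. Blocks are fused in the order intra-high,
intra-low, inter-high, inter-low.

Min-max normalisation operates on a whole block (the block's own minimum
and maximum), not per feature — the block is a single feature vector in the
normalisation formula. Inside cross-validation the block statistics are
computed on training subjects only and applied to held-out subjects; test
values may fall outside $[0, 1]$ and are not clipped. A `global` mode
pools over all subjects instead, for comparison with protocols that
normalise before splitting; the fold-wise default prevents information
leakage, which the tests verify directly by corrupting held-out rows and
checking the fitted selection is unchanged.

Selection is two-stage: a pooled-variance two-sample t-test filter at
threshold $p$, then LASSO
($\tfrac12\sum_l (I^l - f_l^{\top} w)^2 + \lambda \lVert w \rVert_1$, no
intercept, labels coded patient $= +1$, control $= -1$) whose nonzero
support is the final feature set for a linear soft-margin SVM. Evaluation
is repeated, stratified, nested five-fold cross-validation; the inner loop
grid-searches $(p, \lambda, \text{cost})$ by mean inner accuracy with ties
broken toward the simpler model (larger $p$, larger $\lambda$, smaller
cost — the direction of stronger shrinkage and weaker filtering). The
default grids are $p \in \{0.01, \dots, 0.10\}$,
$\lambda \in \{0.1, \dots, 0.9\}$ and cost $\in \{2^{-4}, \dots, 2^4\}$.
Since the kernel is linear, the SVM's only free hyperparameter is the
soft-margin cost. If no feature survives selection the classifier falls
back to the training majority class rather than crashing a fold.

Selected features are traced back through their provenance: an
intra-network feature credits its sub-network with weight 1, an
inter-network feature credits each endpoint with 1/2; rates are normalised
to sum to one (`contribution_trace()`). `top_edges()` ranks low-order
ROI-pair features by selection frequency, ties broken lexicographically.

## What the synthetic cohort does and does not emulate

`generate_cohort()` draws each subject's series from a block-structured
multivariate normal: within-network correlation `rho_within`,
between-network `rho_between`, optional state switching (fixed dwell
segments cycling through states whose within-network correlation is offset
by equally spaced values in `[-state_amp, state_amp]`; fixed dwell rather
than Markov switching keeps window alignment reproducible), a group effect
shifting the patient group's within-`effect_network` correlations by
`effect_delta` (projected back to the nearest positive-definite correlation
matrix by eigenvalue clipping at $10^{-6}$), and independent Gaussian
measurement noise added last. Identical spec and seed give a bit-identical
cohort, and the ground-truth record (perturbed edges, state sequence) makes
recovery testable.

This emulates the *shape* of a resting-state cohort — block correlation,
dynamics, a connectivity-level group difference — but none of its
physiology: no haemodynamic autocorrelation, no low-frequency drifts, no
motion artefacts, no site heterogeneity, and a homogeneous effect over all
edges of one network. Passing tests therefore demonstrate that the
estimator and the selection pipeline recover what they are designed to
recover under the stated model, not that any particular clinical accuracy
is attainable on real data; published cohort-level accuracies require the
original cohort, which this package deliberately does not depend on.

## Problem sizes used by the tests and the acceptance script

Chosen once, as a balance between statistical resolution and a suite that
runs on a laptop:

* Null calibration: 60 subjects (30 + 30), three 4-ROI sub-networks,
  $M = 120$, window $(30, 6)$, reduced grid
  ($p \in \{0.05, 0.10\}$, $\lambda \in \{0.3, 0.6\}$,
  cost $\in \{0.25, 1, 4\}$), 20 repeats; the mean accuracy is compared
  against the 95% binomial chance band for 60 subjects,
  $0.5 \pm 1.96\sqrt{0.25/60}$.
* Effect recovery: same geometry, 40 subjects, `effect_delta = -0.25` on
  DMN (a drop of half the baseline within-network correlation, in line with
  reported default-mode hypoconnectivity), 10 seeded replicates; we require
  the mean accuracy above the chance band and DMN ranked first in at least
  9 of 10 replicates.
* Estimator recovery: 500 draws from a known $4 \times 4$ matrix-normal,
  scale-aligned relative Frobenius error below 10%; monotonicity over 100
  random instances with $n \in [2,6]$, $K \in [5,40]$.

## Known limitations

* Only the symmetric equal-factor matrix-normal is implemented; rectangular
  data with distinct row/column factors is out of scope.
* The bundled six-network AAL division reconstructs region membership from
  standard AAL names under published network *sizes*; analyses that depend
  on exact membership should supply their own partition JSON.
* High-order features cannot be traced to individual ROI pairs in the edge
  report (the factor covariance couples all pairs); only low-order features
  appear in `top_edges()`.
* With very few windows the factor estimate is ridge-stabilised and should
  be read as regularised, not as a pure MLE; the fit records `ridge_used`.
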