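---
title: "High-order functional connectivity networks: models, estimation, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-order functional connectivity networks: models, estimation, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hofcn)
```

## The problem

A functional connectivity network (FCN) describes statistical dependencies
between the BOLD time series of brain regions (ROIs).  A *high-order* FCN
(HoFCN) goes one step further: it describes dependencies among the
*connectivity patterns themselves*, estimated from how windowed ("dynamic")
low-order networks co-fluctuate over the scan.  Because each sliding window
contains few volumes, windowed networks are noisy, and the high-order
estimate inherits that noise.  This package implements a two-stage remedy:

1. estimate an initial high-order network $\Omega_0$ by maximum likelihood
   under a matrix-variate normal model of the windowed network sequence, and
2. refine it by seeking the nearest network to $\Omega_0$ that satisfies a
   *sparsity* prior (few edges) or a *modularity* prior (few edges arranged
   in dense blocks), via proximal optimisation.

The package also ships the complete evaluation harness used in this line of
work (edge features, $t$-test screening, linear SVM, nested leave-one-out
cross-validation) and a seeded synthetic-data generator, so every claim in
the test suite is reproducible from code alone.

## Low-order estimators

With $X \in \mathbb{R}^{V \times P}$ the column-standardized data matrix
(zero mean, unit Euclidean norm per ROI), the Pearson network is
$W = X^\top X$, the unconstrained minimiser of $\|W - X^\top X\|_F^2$.
The sparse-representation (SR) estimator solves, per target ROI $i$,

$$\min_{w}\; \big\|x_i - \textstyle\sum_{j \ne i} w_j x_j\big\|^2
  + \lambda \textstyle\sum_{j \ne i} |w_j|,$$

a regularised partial-correlation model with the self-weight excluded (a
zero diagonal by construction, not by penalty).  The solver is cyclic
coordinate descent with exact per-coordinate updates (columns have unit
norm), stopping when the largest coefficient change in a sweep drops below
$10^{-8}$, capped at $10^4$ sweeps.  Tests certify the solution against the
KKT conditions and against an independent solver (glmnet) on the same
objective.  Because the directed coefficient matrix is asymmetric, the
result is symmetrized as $(W + W^\top)/2$ — the least-committal symmetric
projection; a max-magnitude variant is available via the
`symmetrization` argument.

Windowing follows the convention $K = \lfloor (V - N)/s \rfloor + 1$
windows of width $N$ advanced by step $s$, with any trailing remainder
dropped; each window is standardized and correlated independently (each is
a standalone Pearson estimate).  No Fisher $z$-transform is applied, and no
within-window detrending — neither is part of the model implemented here.

## The matrix-normal MLE fixed point

Treating the windowed networks $W_1, \dots, W_K$ as samples from a
matrix-variate normal with mean $M = \frac{1}{K}\sum_k W_k$ and a single
shared row/column covariance $\Omega$, the maximum-likelihood estimate
satisfies

$$\Omega = \frac{1}{KP} \sum_{k=1}^K (W_k - M)\, \Omega^{-1} (W_k - M)^\top,$$

iterated from $\Omega = I$.  Three numerical choices matter:

* **Damping** (default $\eta = 0.5$): the raw substitution iteration can
  oscillate with period two — for $K=2$, $P=2$, $W_1 = 2I$, $W_2 = 0$ it
  bounces between $0.5I$ and $I$, while the true fixed point is
  $I/\sqrt{2}$.  The damped update
  $\Omega \leftarrow (1-\eta)\Omega + \eta\,\mathrm{RHS}(\Omega)$ has the
  same fixed points and converges on every case in the test suite.
* **Jitter**: before inversion, $\varepsilon \cdot \mathrm{tr}(\Omega)/P$
  is added to the diagonal, starting at $\varepsilon = 10^{-10}$ and
  escalating tenfold to at most $10^{-6}$; beyond that a singularity error
  is raised.  Rank-deficient scatter is *expected* when $K < P$.
* **Stopping**: relative Frobenius change below $10^{-6}$ (default), cap
  500 iterations; hitting the cap records a warning in the returned
  estimate rather than failing, and the final fixed-point residual
  $\|\Omega - \mathrm{RHS}(\Omega)\|_F / \|\Omega\|_F$ is always reported.

The estimator accepts any finite square matrices, not only symmetric ones:
the update symmetrizes its own output, and raw matrix-variate normal draws
(used for parameter-recovery tests, where the fixed point recovers the true
$\Sigma$ up to scale) are square but not symmetric.  The mean uses divisor
$K$, and the output is left on its natural scale — downstream penalties act
on the raw $\Omega_0$.

## Proximal refinement: S-HoFCN and M-HoFCN

The sparsity-refined network solves
$\min_\Omega \|\Omega - \Omega_0\|_F^2 + \mu \|\Omega\|_1$;
the modularity-refined network adds a trace-norm term,
$\min_\Omega \|\Omega - \Omega_0\|_F^2 + \mu_1\|\Omega\|_1 + \mu_2\|\Omega\|_*$,
because sparse-plus-low-rank structure induces block (modular)
organisation.  Both are solved by the three-step proximal scheme: a
gradient step $\Omega \leftarrow \Omega - \alpha \cdot 2(\Omega - \Omega_0)$,
entrywise soft-thresholding by $\mu_1$, and singular-value thresholding by
$\mu_2$.  At $\mu_2 = 0$ the modular problem reduces exactly to the sparse
one (asserted bit-for-bit in the tests).

Design choices where the scheme is under-specified:

* **Step size** $\alpha = 1/2$ by default — the reciprocal of the Lipschitz
  constant ($L = 2$) of the smooth term's gradient.  At this value the
  gradient step lands exactly on $\Omega_0$, so the algorithm collapses in
  one iteration to the sequential proximal maps
  $D_{\mu_2}(S_{\mu_1}(\Omega_0))$.  This is documented behaviour, and
  $\alpha$ is configurable; at other $\alpha$ the S-HoFCN fixed point is
  the entrywise shrinkage with effective threshold $\mu/(2\alpha)$, which
  the tests verify analytically.
* **Threshold scaling**: the literal scheme applies $\mu_1, \mu_2$
  unscaled by $\alpha$ (default).  Consequence at $\alpha = 1/2$: the
  computed minimiser corresponds to the objective with penalties doubled —
  a pure reparameterization of the search grid, harmless because the grid
  is tuned by cross-validation.  Setting `ista_scaling = TRUE` applies the
  textbook $\alpha$-scaled thresholds instead.
* The sequential composition of the two proximal operators is not the
  exact proximal map of the *summed* penalty; it is implemented as
  specified, not replaced by an inner splitting scheme.
* Convergence is measured on the post-SVT iterate (relative Frobenius
  change $< 10^{-6}$, cap 1000), and each iterate is re-symmetrized to
  absorb floating-point drift from the SVD.

## Classification harness

Features are the $P(P-1)/2$ strict upper-triangle edge weights (row-major).
Feature screening is a pooled-variance two-sample $t$-test (two-sided,
default $p < 0.05$; Welch available behind a flag); if nothing passes, the
single smallest-$p$ feature is kept so the classifier is never empty.  The
classifier is a soft-margin linear SVM at $C = 1$, solved by deterministic
dual coordinate descent on the hinge-loss dual (bias as an augmented,
weakly regularised feature); no SVM library is available in the target
environment, so the solver is built in C++ and certified in the tests by
the KKT conditions of its dual.

Evaluation is nested LOOCV: the outer loop holds out one subject; the
inner loop, restricted to the remaining $T-1$ subjects, re-runs feature
selection and training inside every inner fold for every candidate
hyperparameter and picks the value with the highest mean inner accuracy
(ties go to the earliest grid entry; the printed grid
$2^{-5}, \dots, 2^5$ is ascending, and for the threshold-based methods the
grid is the 11 sparsity levels $1\%, 10\%, \dots, 100\%$, where a level is
the fraction of largest-magnitude edges *kept*).  Window parameters
$(N, s)$ are deliberately *not* tuned inside the CV — they are swept
externally and reported per setting.  A standing "leakage probe" test
poisons the held-out subject's data and asserts that nothing on the
training side changes.

## The synthetic world

The generator produces the only data the package is tested on, so its
assumptions bound what a green test establishes:

* **BOLD surrogate**: stationary i.i.d. multivariate normal volumes with a
  block ("modular") correlation matrix — `within_corr` inside equal-size
  modules, `between_corr` elsewhere, unit diagonal, scaled by
  `noise_sd`$^2$ (defaults 0.6 / 0.1 / 1; the contrast is checked positive
  definite at construction).  An optional AR(1) filter adds temporal
  memory for sliding-window demonstrations.  There is no hemodynamic
  model, physiological noise, motion, or genuine nonstationarity; green
  end-to-end tests establish correctness of the *pipeline mechanics*, not
  clinical effect sizes.
* **Matrix-normal samples** for testing the MLE: $W_k = M + A Z_k A^\top$
  with $AA^\top = \Sigma$, the exact model under which the fixed point is
  consistent.
* **Cohorts**: patients and controls share the base covariance except for
  `effect_size` added to the latent correlation on a declared edge set
  (projected back to positive definite by eigenvalue clipping at
  $10^{-6}$); subject $k$ draws with sub-seed `seed + k`, and every
  generator restores the caller's RNG state.

The frozen end-to-end evaluation cohort is 10 patients + 10 controls,
$P = 16$ ROIs in two modules, $V = 120$ volumes, five between-module edges
shifted by $+0.5$ correlation, windows $N = 40$, $s = 5$, and an 11-point
line search $\mu_1 = \mu_2 \in \{2^{-5}, \dots, 2^5\}$ for M-HoFCN.  These
values were calibrated once against the generator (the full $11 \times 11$
grid reproduced the same headline accuracy at about six times the cost)
and then frozen with the seeds.

One calibrated finding is worth stating because it contradicts a naive
expectation: on a *balanced* null cohort (permuted labels), LOOCV accuracy
concentrates at **0**, not 0.5.  The held-out subject's class is always
the 9-vs-10 training minority, and with no signal the SVM tracks the
training majority — the well-documented below-chance behaviour of LOOCV.
The permuted-label control therefore asserts ACC $\le 0.2$ (all 20
calibration replicates gave exactly 0); an *optimistically biased*
pipeline — the failure mode the control exists to catch — would push the
null toward high accuracy instead.

## Known limitations

* SR group-norm extensions (group-sparse / weighted variants) and
  accelerated (FISTA) proximal schemes are out of scope.
* The matrix-normal model uses a single shared row/column covariance; no
  flip-flop estimation of separate row and column covariances.
* Tapered windows, overlap-corrected variance estimates, and any fMRI
  preprocessing (registration, filtering, nuisance regression,
  parcellation) are out of scope: inputs are already-extracted ROI series.
* With very few windows ($K \ll P$) the MLE iteration may legitimately hit
  its iteration cap; the estimate is returned with a warning and its
  residual, and callers should prefer geometries with $K \gtrsim P$.
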