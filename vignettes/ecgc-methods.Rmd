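---
title: "Elastic-net copula Granger causality: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-net copula Granger causality: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgc)
```

## The problem and the model

Given a multivariate time series — gene-expression time courses, fMRI region
signals, or any table with rows as time points and columns as variables —
we want the directed influence graph: which variables' pasts help predict
which variables' futures. The working model is a vector autoregression in a
transformed space. Writing $z_i(t)$ for the transformed series,

$$z_i(t) = \sum_{j=1}^{p} \beta_{j,i}^\top
  \left[z_j(t-1), \ldots, z_j(t-L)\right] + \varepsilon_i(t),$$

and variable $j$ Granger-causes variable $i$ exactly when the lag
coefficient block $\beta_{j,i}$ is not identically zero. Estimating each
target's equation and reading edges off the nonzero blocks turns network
inference into $p$ penalized regressions with $pL$ predictors each.

Two ingredients deal with the two standard obstacles:

**The Gaussian copula transform** handles marginals that are skewed,
heavy-tailed, or measured on a monotone-nonlinear scale (common for
microarray intensities and BOLD signals). Each column is mapped through its
empirical CDF $\hat F_i$ and the standard-normal quantile function,
$z = \hat\mu_i + \hat\sigma_i\,\Phi^{-1}(\hat F_i(x))$. Because
$\hat F_i(x_t)$ is a function of within-column ranks only, any strictly
increasing distortion of a column leaves the transformed data — and hence
the inferred network — unchanged. The empirical CDF reaches exactly 1 at the
column maximum, where $\Phi^{-1}$ diverges, so CDF values are Winsorized
into $[\delta_n, 1-\delta_n]$ first, with

$$\delta_n = \frac{1}{4\, n^{1/4} \sqrt{\pi \log n}}$$

for $n$ time points (about 0.021 at $n = 100$). This is the truncation level
from the nonparanormal estimation literature; it decreases slowly in $n$, so
extreme ranks are pulled in just enough to keep normal scores finite without
distorting the bulk. One side effect is worth knowing: once
$\delta_n > 1/n$ (from about $n = 96$ onward) the few most extreme order
statistics on each side share the clamped CDF value, so the transform is
strictly rank-preserving in the interior but maps those tail points to
ties. `copulaTransform()` accepts an override for users who
want a different bound. The rescaling by the column's sample mean and
standard deviation is cosmetic for edge selection — predictors are
re-standardized inside the fitting step — but keeps the transformed series
on the scale of the raw data.

**The elastic-net penalty** handles many, strongly correlated lagged
predictors. For each target the package minimizes

$$\frac{1}{2n}\lVert y - X\beta\rVert_2^2
 + \lambda\left(\alpha\lVert\beta\rVert_1
 + \frac{1-\alpha}{2}\lVert\beta\rVert_2^2\right),$$

the usual mixing family: $\alpha = 1$ is the LASSO (the baseline method),
smaller $\alpha$ adds a ridge component that stabilizes selection among
correlated lags. The $(\ell_1, \ell_2)$ weights $(\alpha, (1-\alpha)/2)$
follow the convention of the standard solvers for this family; the overall
magnitude $\lambda$ is what the path search tunes.

## Fitting and model selection

`fitPath()` standardizes predictor columns to mean zero and unit (population)
variance, centers the response, and solves the problem by cyclic coordinate
descent with the soft-threshold update
$\beta_j \leftarrow S(z_j, \lambda\alpha)/(1 + \lambda(1-\alpha))$. The
solver runs in covariance form (on $X^\top X/n$ and $X^\top y/n$), caches
residual correlations, and cycles over the active set between full passes;
convergence is declared when a full pass moves no coefficient by more than
`tol` (default $10^{-7}$, at most $10^5$ cycles, warning on failure). The
implementation is verified in the test suite against ordinary least squares
at $\lambda = 0$, the orthonormal-design closed form, an independent
accelerated proximal-gradient solver, and glmnet.

For each $\alpha$ in the grid (default $0.1, 0.2, \ldots, 1.0$) the solver
walks a log-spaced path of 50 $\lambda$ values from
$\lambda_{\max}(\alpha) = \max_j |x_j^\top y|/(n\alpha)$ — the smallest
$\lambda$ with an all-zero solution — down to $0.01\,\lambda_{\max}$, warm
starting each fit. Every $(\alpha, \lambda)$ fit is scored by the
Gaussian-likelihood AIC

$$\mathrm{AIC} = n \log(\mathrm{RSS}/n) + 2\,\mathrm{df},$$

with df the number of nonzero coefficients (the standard degrees-of-freedom
estimator for $\ell_1$-type fits), and the minimum-AIC fit is selected. Ties
break toward larger $\lambda$, then larger $\alpha$: sparser first.
Coefficients with magnitude at or below `zeroTol` ($10^{-8}$) are treated as
structural zeros; coordinate descent produces exact zeros at $\alpha > 0$,
so the threshold only guards numerics. "Statistically nonzero" is thus
implemented as *structurally nonzero after AIC selection*; no secondary
significance test is applied.

Two behavioral consequences of this AIC are worth knowing. First, it admits
a pure-noise predictor whenever the RSS drop beats $2$ — roughly a
$\chi^2_1 > 2$ event, probability about 0.16 — so a few false edges per
network are expected rather than exceptional; the benchmark FDR values
reflect this. Second, because ridge shrinkage biases coefficients and
thereby inflates RSS without reducing df, the minimum-AIC fit lands at
$\alpha = 1$ for most realizations of the benchmark systems: under this
selection rule the elastic-net arm frequently coincides with its LASSO
slice, and the two methods' benchmark rows can be identical. Users who want
the ridge component active can pass a restricted `alphaGrid`.

## Edge direction and self edges

In the regression with target $i$, a nonzero selected coefficient on any lag
of source $j$ declares the edge $j \to i$; `adjacency()` returns the matrix
with source rows and target columns. Diagonal entries (a variable's
dependence on its own past) are estimated like any other block but are
excluded from scoring by default: the benchmark claim concerns cross-edge
recovery, and whether diagonal terms count is the single largest source of
ambiguity when comparing against published summary tables.
`scoreNetwork(..., includeSelf = TRUE)` flips this.

## The simulated benchmark systems

`simulateDataset1()` (three variables, maximal lag 2) and
`simulateDataset2()` (five variables, maximal lag 4) iterate two classical
benchmark autoregressions with independent standard-normal innovations; the
equations and their ground-truth graphs (3 and 7 cross edges) are printed in
the help pages. Generation follows the benchmark protocol: each series
starts from N(0, 1) noise and the iteration output is used as-is, with no
burn-in discarded (a `burnin` argument exists for users who want
equilibrated draws of stationary systems).

The no-burn-in default matters for system 1: its companion matrix has
spectral radius 1.00228, so the system is *marginally explosive*. Magnitudes
grow about tenfold per thousand steps; a long pre-run would hand the
retained window over to the deterministic growing mode, make the lagged
columns of x2 and x3 nearly collinear, and visibly degrade recovery. Even
from a noise start the effect appears at long horizons — at $T = 1000$ the
lag-2 edge x3→x2 is regularly masked while both lag-1 edges remain easy —
and it is why large-sample moment checks (for example recovering the
generating coefficients by OLS at $T = 10^5$) are only meaningful for the
stationary system 2 (radius 0.877). `companionSpectralRadius()` exposes the
diagnostic.

`simulateRandomVAR()` generates random sparse stable systems (coefficients
shrunk until the spectral radius is at most 0.9, burn-in 1000) for
property-style tests: permutation equivariance, scale invariance, and
monotone-marginal invariance are checked on such systems and on the fixed
benchmarks.

Inference on system 1 uses $L = 2$ and on system 2 uses $L = 4$ — the
maximal generating lags. With $L < 4$ on system 2 the lag-4 edge x3→x2 is
unreachable by construction.

## The Monte-Carlo harness

`runBenchmark()` repeats, for each series length in the grid (default 15,
20, 35, 75, 150, 500, 1000): simulate with seed `baseSeed + r`, run each
method on the same realization, score cross edges, and average each metric
over replicates. F1 is averaged per replicate — the mean of per-replicate
F1 values, not the harmonic mean of the averaged precision and recall. FDR
is the complement of precision by construction whenever at least one edge is
predicted, and that identity is asserted per replicate in the tests. The
default is 500 replicates per cell, which stabilizes every reported mean to
about $\pm 0.02$ (Monte-Carlo standard error) while keeping a full
two-system sweep in the minutes range on one core; the published protocol
this harness mirrors used more than 5000 replicates, and `replicates`
scales up directly for users who want that.

A failed replicate (a fit error) is recorded, excluded from the averages and
counted in the output's `failures` column rather than silently dropped.

## Degenerate inputs and numerical corner cases

* Constant columns: the copula transform cannot rescale by a zero standard
  deviation; it emits a warning and returns unscaled normal scores. In the
  fitting step zero-variance predictor columns are dropped with a warning
  and reported as exact-zero coefficients.
* Ties: the empirical CDF uses the weak inequality (count of values
  $\le t$), so tied observations share a transformed value and the
  column maximum maps to $1$, which Winsorization then pulls to
  $1 - \delta_n$.
* $\mathrm{RSS} = 0$ (an exactly deterministic response): the AIC guards
  $\log 0$ with $\max(\mathrm{RSS}, 10^{-12})$.
* $\lambda_{\max} = 0$ (response orthogonal to every predictor): the path
  collapses to an all-zero fit.
* Short series: the lagged design requires $T \ge L + 2$; the simulators
  require $T \ge 15$, the shortest benchmark length.

## What the synthetic benchmarks do and do not show

The generators emulate linear Gaussian dynamics with known sparse structure
— exactly the setting in which Granger recovery can be scored objectively.
They do not emulate non-Gaussian innovations, hidden confounders, sampling
jitter or aggregation, non-monotone measurement distortions (the copula
absorbs only monotone ones), or contemporaneous coupling. Passing the
benchmark therefore demonstrates correct mechanics and calibrated behavior
of the selection rule, not that edges found in any particular real data set
are causal. For real applications the lag order L and the series length
remain the binding constraints: with $pL$ approaching $T$, AIC's liberality
grows and the FDR rises accordingly.
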