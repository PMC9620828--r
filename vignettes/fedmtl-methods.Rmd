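---
title: "Federated multi-task learning with fedmtl: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated multi-task learning with fedmtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedmtl)
```

## The problem

Multi-cohort molecular studies routinely face two constraints at once: the
cohorts cannot be pooled into one database (privacy, governance,
geography), and the biology they share is only partly common — a signature
may involve the same genes in every cohort while pointing in different
directions, or a data matrix may superpose a component common to all
cohorts with components unique to each. Conventional federated machine
learning handles the first constraint but assumes away the second: it fits
one model to all cohorts as if they were exchangeable. Multi-task learning
(MTL) addresses the second by fitting one model per cohort with a penalty
that couples them.

`fedmtl` combines both in an in-process simulation of a client–server
federation. Raw data live inside server nodes; the analysis client only
ever sees what `server_compute()` returns — scalar losses, gradients,
factor-update statistics, summary aggregates — with quantization,
disclosure control and communication metering applied at that boundary.
The simulation is deliberately transport-agnostic: every exchange goes
through one function, so a networked backend could replace it without
touching any algorithm.

## The model family

All supervised fits minimize one objective,

$$\min_{W,c}\;\sum_{t=1}^{T} L_t(w_t, c_t)\;+\;\lambda\, S(W)\;+\;C\,\aleph(W),$$

where $L_t$ is cohort $t$'s mean-form loss (squared error for continuous
outcomes, logistic negative log-likelihood for $\pm 1$ labels), $S$ is a
non-smooth sparsity-inducing penalty handled through its proximal
operator, and $\aleph$ is a smooth stabilizer. The four supervised
estimators are instances of this template:

* **`fit_l21`** — $S = \|W\|_{2,1}$ (sum of row norms): features are
  selected jointly across tasks but each task keeps its own coefficient
  values, including opposite signs. The estimator of choice for
  *heterogeneous* signatures.
* **`fit_trace`** — $S = \|W\|_*$ (sum of singular values): task
  coefficient vectors share a low-dimensional subspace.
* **`fit_net`** — $S = \|W\|_1$ with smooth coupling
  $C(\|WR\|_F^2 + \epsilon\|W\|_F^2)$ over a task graph $R$; the built-in
  `mean_graph()` penalizes each task's deviation from the across-task
  mean.
* **`fit_lasso`** — pooled coupling: a single coefficient vector over the
  union of all servers' samples, with per-server losses aggregated by
  sample-size weights $n_k/N$. This is the conventional federated-ML
  benchmark.

Per-task losses are normalized by $n_k$ so cohorts of different sizes
contribute comparably; intercepts are fitted but never penalized.

The unsupervised estimator, **`fit_inmf`**, factorizes each cohort's
non-negative matrix as $X_k \approx W_k (H + V_k)$ with a shared metagene
matrix $H$ and cohort-specific $W_k, V_k$, minimizing

$$\sum_k \|X_k - W_k(H+V_k)\|_F^2 + \lambda_{het}\sum_k \|W_k V_k\|_F^2$$

by alternating multiplicative updates. $W_k$ and $V_k$ never leave their
server; the $H$ update needs only the server-aggregated numerator
$A_k = W_k^\top X_k$ and denominator $B_k = W_k^\top W_k (H+V_k)$, one
access per server per round.

## Optimization

The solver is a monotone FISTA: gradient of the smooth part at the
momentum point (one synchronization round), proximal step, and a
backtracking line search that halves the step until the quadratic
upper-bound condition holds (each candidate evaluation costs one more
round). The monotone variant keeps the best iterate and restarts the
momentum sequence whenever the extrapolation overshoots; this makes the
recorded objective history non-increasing — an assertable invariant that
plain FISTA does not have — and avoids stalls near the optimum.

$\lambda_{\max}$, the smallest penalty weight that zeroes the model, is
computed from the first-order optimality condition at the intercept-only
fit: the max absolute entry (L1), max row norm (L2,1) or largest singular
value (trace) of the loss gradient there. Lambda paths are interpolated
geometrically from $\lambda_{\max}$ down to `min_ratio` $\cdot
\lambda_{\max}$ and fitted warm-started; because the first fit starts at
the zero matrix with intercepts at their closed-form optimum, the first
path entry is exactly zero, not merely small.

Key defaults (all overridable in `solver_options()`): `tol = 1e-5` on the
relative objective change, `max_iter = 1000`, initial step 1, shrink 1/2,
`min_ratio = 0.01`, `depth = 20`. The termination rules (`objective_rel`,
`param_rel`, `iter_only`) trade precision for communication; relaxing
`tol` or shortening `depth` are the intended speed knobs, alongside
payload quantization (below).

For iNMF, factors are initialized entrywise $U(0,1)$ scaled by
$\sqrt{\bar X / r}$, five random starts are fitted by default and the
best final objective is kept. `lambda_het` defaults to 0.003: the penalty
only has to break the allocation tie between $H$ and the $V_k$ (structure
present in every cohort is cheaper in $H$; structure unique to one cohort
cannot leave $V_k$ without a cross-cohort residual cost). Large values
are actively harmful — they push genuinely specific structure into rows
of $H$ that the other cohorts simply do not load. That same degenerate
direction motivates the shared-signature scoring rule in
`extract_signatures()`: rows of $H$ are weighted by each cohort's mean
loading on them (an aggregate the servers release) and a gene's shared
score is the minimum across cohorts, which filters rows used by only one
cohort. Multiplicative-update denominators are guarded by
$\epsilon = 10^{-12}$; rank selection uses the elbow (largest second
difference) of the objective-vs-rank curve.

## Privacy model

Three controls are simulated, all attached to `privacy_policy()`:

* **Quantization** (`digits`): every numeric payload crossing the
  boundary is rounded to a fixed number of decimal places,
  round-half-to-even on the decimal representation (base R's `round()` is
  not consistently decimal-half-even, so the package implements the
  rounding on the shortest round-trip decimal string). Fewer digits mean
  smaller payloads and a perturbed but usually close fit; with unlimited
  digits the federated fit equals a centralized one exactly.
* **Disclosure guard** (`nonzero_guard`): a fitted coefficient vector
  whose nonzero count exceeds the releasing server's sample count is
  refused — a saturated model can interpolate individual observations.
  Single-lambda fits error; path entries are withheld and
  cross-validation skips them. The simulation studies below disable the
  guard: it is a deployment safeguard, and at $n_k \ll p$ it would
  truncate the regularization path and change what is being compared.
* **Shared-only iNMF returns** (`inmf_shared_only`): only $H$ and scalar
  aggregates are client-visible; cohort-specific signatures are computed
  server-side and returned as gene names only. `server_export_factors()`
  writes $W_k, V_k$ to files *on the server side* as a stand-in for an
  authorized-retrieval mechanism; no key management is modeled.

Communication is metered two ways because the counting convention
matters: a *round* is one client-initiated broadcast, an *access* is one
request–response exchange with one server. A multi-task gradient
evaluation is one round but $K$ accesses; round counts are therefore flat
in $K$ (each server computes its own task's gradient locally) while
access counts grow linearly. `comm_summary()` reports both.

## The synthetic studies

`gen_case1` emulates the heterogeneous-signature supervised study: $T$
cohorts (default 3) with iid standard-normal features, a common support
of `s` features (default $0.1p$), coefficients $\pm$`magnitude` with
signs drawn iid Rademacher per cohort ("heterogeneous") or shared
("homogeneous"), and Gaussian noise (`noise_sd`, default 1) or logistic
sampling for binary outcomes. The study conditions used by the test suite
and the acceptance script are $T = 3$, $p = 200$, $n/p = 0.15$
($n = 30$ per server), $s = 20$, magnitude 1, noise sd 1 — a desk-scale
problem (the original design, like most expression studies, is an order
of magnitude larger; the subject/feature ratio, which drives the
phenomenon, is preserved).

`gen_case2` emulates the unsupervised comorbidity study: two cohorts
whose matrices superpose a shared signature ($H_{true}$, loading
$f \cdot m$ genes) and one cohort-specific signature each
($V_{k,true}$, loading $(1-f) \cdot m$ genes, disjoint sets), with
$m = 50$ outcome-associated genes per cohort, $p = 200$, $n_k = 60$, rank
4 per signature, loadings $U(0.5, 1.5)$ (every planted gene genuinely
loaded, three-fold effect-size spread), half-normal noise (sd 0.1). The
two signatures are expressed with *independent* sample-loading matrices
($X_k = W_k H + U_k V_k$), following the study's description of the
observed signal as a sum of a comorbidity component and a
disease-specific component: each component has its own expression
pattern across samples, so a cohort's local structure has up to $2r$
components. This is the feature that separates the methods: a local
rank-$r$ NMF must compress $2r$ components and, at low shared fractions,
spends its rank on the (larger) specific component, while the joint
factorization models the split explicitly.

What the generators do *not* emulate: count distributions (negative
binomial), batch effects, correlated designs, missing values. Passing
tests on this data show that the estimators recover the structure they
target under their own generative assumptions — not that they would do so
on real expression matrices.

## Design choices that were genuinely open

* **Loss scaling.** Mean-form ($1/n_k$) per-task losses, so cohort size
  does not silently weight the objective; the pooled lasso re-weights by
  $n_k/N$ so that splitting a dataset across servers changes nothing.
* **Standardization** is an explicit preprocessing step
  (`scale_dataset()`, per server, center/scale recorded) rather than a
  hidden fit option: silent per-server standardization would break the
  federated-equals-centralized identity for pooled fits.
* **Line-search accounting.** Each candidate step evaluation re-fetches
  per-server loss values (one round); the gradient at the momentum point
  is one further round. Rounds per iteration are therefore
  $2 + \text{retries}$, independent of $K$.
* **Baseline aggregation.** The per-cohort lasso ensemble ranks features
  by the mean absolute coefficient across cohorts (absolute, because
  heterogeneous signs are the object of study). The per-cohort NMF
  ensemble averages per-cohort gene scores into the bagged shared-set
  estimate; a min/intersection-style combination was rejected because it
  never degrades with heterogeneity, which would make the baseline a
  straw man in one direction and unbeatable in the other.
* **CV protocol.** Folds are drawn within each server (stratified for
  binary outcomes), the lambda grid is estimated once on the full
  federation, held-out metrics are computed server-side (one access per
  server per fold and lambda), and cohorts are averaged unweighted.

## Numerical behavior and edge cases

Ties in feature rankings break by index (deterministic). The logistic
loss is evaluated in the log1p form, stable for large margins.
`lambda_max` at the intercept-only optimum makes the first path fit exact
for L1/L2,1 (the same float comparison that defined the threshold zeroes
the gradient step); for the trace norm the SVD of the scaled gradient can
leave $10^{-16}$-scale residuals, so "zero at $\lambda_{\max}$" should be
checked at $\lambda$ slightly above it. Quantization is idempotent, and
the federated-vs-centralized deviation shrinks monotonically as digits
grow. iNMF updates preserve non-negativity exactly; zero denominators are
$\epsilon$-guarded; all-zero data matrices are handled.

## Known limitations

* The federation is in-process: there is no authentication, encryption or
  wire protocol, and timing results say nothing about network latency.
* The iNMF objective's multiplicative scheme finds local optima;
  cross-start selection by objective plus the cross-cohort weighting in
  signature extraction mitigate, but do not eliminate, the degenerate
  allocation described above.
* The supervised simulation reproduces the *direction* of the
  joint-vs-local selection-accuracy gap at low $n/p$; the magnitude of
  that gap depends strongly on the effect-size/noise balance, for which
  the package fixes one declared configuration (magnitude 1, noise sd 1).
* Only one penalty axis is searched ($\lambda$); the smooth weight $C$ is
  user-fixed per run.
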