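# fedmtl

Privacy-aware federated multi-task machine learning over a simulated
client–server data federation, for multi-cohort biomedical studies whose
data cannot be pooled and whose signals are only partly shared across
cohorts.

In a `fedmtl` federation every cohort's feature matrix and outcome vector
live inside a server node; the analysis client exchanges only model
parameters and aggregate statistics (losses, gradients, factor-update
numerators/denominators), with payload quantization, a disclosure guard
and communication metering applied at the server boundary. On top of that
transport the package implements:

* **Supervised multi-task estimators** minimizing
  `sum_t L_t(w_t, c_t) + lambda * S(W) + C * A(W)` with per-cohort
  mean-form least-squares or logistic losses `L_t`:
  - `fit_l21()` — row-sparse L2,1 penalty: joint feature selection
    across cohorts with cohort-specific coefficient values (signatures
    with the same genes but possibly opposite directions);
  - `fit_trace()` — trace-norm penalty: a shared low-rank subspace;
  - `fit_net()` — sparse fits coupled by a task-graph quadratic
    (`mean_graph()` pulls every cohort toward the across-task mean);
  - `fit_lasso()` — a federated lasso over the union of all samples, the
    conventional single-model benchmark.
* **Federated integrative NMF** (`fit_inmf()`): each non-negative cohort
  matrix is factorized as `X_k ~ W_k (H + V_k)`; the shared metagene
  matrix `H` is the only factor that ever reaches the client, while the
  cohort-specific `W_k`, `V_k` stay on their server and contribute only
  gene *names* to signature extraction.
* A monotone **FISTA** solver with backtracking, data-driven
  `lambda_max()` from the first-order optimality condition, log-scale
  `lambda_sequence()` grids, warm-started `solve_path()` fitting, and
  federated `cross_validate()` with within-server folds.
* **Synthetic generators** (`gen_case1()`, `gen_case2()`,
  `gen_scalability_suite()`) reproducing the statistical structure of the
  package's two simulation studies, with ground truth returned alongside
  the data, plus evaluation utilities (`selection_accuracy()`,
  `bagging_baseline()`, `signature_overlap()`,
  `comm_cost_experiment()`).

See `vignettes/fedmtl-methods.Rmd` for the models, their assumptions, all
tunable parameters and the design decisions.

## Worked example

Three cohorts share a 10-feature support with cohort-specific signs; a
cross-validated federated L2,1 fit recovers it jointly:

```r
library(fedmtl)

d <- gen_case1(n_tasks = 3, p = 100, n_per_task = 40, s = 10, seed = 42)
sess <- create_session(d$datasets, privacy_policy(nonzero_guard = FALSE))
sess
#> Federated session: 3 server(s)
#>   servers: task1 (n=40), task2 (n=40), task3 (n=40)
#>   features: 100
#>   policy: digits=unlimited, guard=FALSE, inmf shared-only=TRUE
#>   comm: rounds=0, total accesses=0

cv <- cross_validate(sess, "l21", loss = "ls", k_folds = 5, seed = 1)
cv
#> cv_result: best lambda 0.4139 (mse = 4.058)
cv$model
#> coef_model: 100 features x 3 task(s), 25 active feature(s), loss=ls

selection_accuracy(feature_scores(cv$model), d$truth$support)
#> [1] 1
comm_summary(sess)$rounds
#> [1] 607
```

The selected lambda keeps 25 active features whose top 10 (by row norm of
the coefficient matrix) are exactly the planted support — precision 1 at
k = 10 — after 607 synchronization rounds, none of which carried raw
data.

Disentangling a shared from two cohort-specific signatures with
federated iNMF (20% of each cohort's signal genes are shared — the most
heterogeneous setting):

```r
d2 <- gen_case2(shared_fraction = 0.2, seed = 7)
s2 <- create_session(d2$datasets, privacy_policy(nonzero_guard = FALSE))
m <- fit_inmf(s2, rank = 4, n_starts = 5, max_iter = 1500, tol = 1e-8,
              seed = 11)
m
#> inmf_model: rank 4, 200 genes, objective 205.536 (best of 5 start(s))

sig <- extract_signatures(m, s2, top_k = 10)
sig$shared
#>  [1] "g15"  "g22"  "g42"  "g67"  "g103" "g118" "g136" "g159" "g168" "g194"
identical(sig$shared, d2$truth$shared)
#> [1] TRUE
```

The ten top-scored genes of the client-visible `H` are exactly the ten
planted shared genes; the cohort-specific sets are available as gene
names via the same call while the underlying factors never left their
servers.

A command-line wrapper with `simulate`, `fit`, `cv`, `evaluate` and
`scalability` subcommands is installed at `inst/cli/fedmtl`
(`fedmtl_cli()` from R).

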