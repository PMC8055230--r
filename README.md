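# clonetrend

Clonal deconvolution of longitudinally sequenced tumours with explicit
modelling of sample timing.

A tumour is a mixture of *clones* — cancer-cell populations sharing a
unique set of somatic mutations. Bulk sequencing observes only, per
mutation *i* and sample *j*, alternative read counts r_ij out of R_ij
total. After correcting for sample purity ρ_j and local copy state
(total copy number D_ij, variant multiplicity d_ij), the expected
variant-allele fraction is linear in the cancer-cell fraction (CCF)
φ̃_ij:

    θ_ij = ζ_ij · φ̃_ij,   ζ_ij = d_ij ρ_j / (2(1 − ρ_j) + D_ij ρ_j)

`clonetrend` clusters mutations by CCF with a truncated Dirichlet-process
mixture (stick-breaking weights w_k, truncation K = 20, concentration
α ~ (1+α)⁻²) and — its distinctive feature — models each cluster's
logit-CCF trajectory ψ_k(t) over the sampling times as a Gaussian
process, so cluster prevalences are reconstructed as continuous
functions of time rather than isolated per-sample estimates:

    ψ_k(t) ~ GP(0, h² g_τ(t, t′)),     φ_jk = logit⁻¹(ψ_k(t_j))
    r_ij | z_i = k ~ BetaBin(R_ij, v_j θ; ·) or Bin(R_ij, θ)

Five prior families are available — `Flat` (uniform per-sample CCFs,
timing ignored), `GP0` (one shared GP), `GP1`/`GP2` (separable
multi-output GP with per-cluster amplitudes, and additionally an
LKJ-distributed between-cluster correlation matrix), `GP3`
(cluster-specific amplitudes and time scales) — each GP family with four
stationary kernels (`Exp`, `Mat32`, `Mat52`, `ExpQ`), giving a registry
of 17 model configurations. Fitting is by stochastic-gradient
variational inference (mean-field Gaussian on unconstrained transforms,
reparameterization gradients, Adam) maximizing the evidence lower bound
(ELBO); the maximized ELBO doubles as the model-comparison score.

The package also provides the purity/copy-number VAF machinery
(including the integer multiplicity estimation rule), soft/hard cluster
assignment, cluster pruning, posterior-predictive VAF densities,
clustering-agreement metrics (ARI/AMI/FMI) implemented from first
principles, a synthetic-data simulator with known clonal structure, and
a small command line interface (`inst/cli/clonetrend`).

## Worked example

Simulate a six-sample targeted-sequencing series with three mutation
clusters, fit the single-output GP model with a Matérn-3/2 kernel, and
compare it against the timing-blind baseline:

```r
library(clonetrend)

sim <- simulate_clones(n_mutations = 100, n_samples = 6, n_clusters = 3,
                       min_separation = 0.2, seed = 101)
fit <- clone_fit(sim$data, model = "GP0-Mat32", max_iters = 8000, seed = 1)
fit
#> <clone_fit> model GP0-Mat32
#>   mutations: 100  samples: 6  truncation K: 20
#>   final ELBO: -2557.64 (MC se 0.43), 4500 iterations, converged

glance(fit)
#> # A tibble: 1 × 8
#>   model     n_mutations n_samples n_clusters   elbo elbo_se iterations converged
#>   <chr>           <int>     <int>      <int>  <dbl>   <dbl>      <int> <lgl>
#> 1 GP0-Mat32         100         6          3 -2558.   0.427       4500 TRUE

tidy(fit)
#> # A tibble: 18 × 8
#>   cluster weight n_mutations sample_id  time   ccf ccf_lo ccf_hi
#>     <int>  <dbl>       <int> <chr>     <dbl> <dbl>  <dbl>  <dbl>
#> 1       1  0.591          61 s01         0   0.371  0.363  0.380
#> 2       1  0.591          61 s02         0.2 0.346  0.335  0.357
#> 3       1  0.591          61 s03         0.4 0.256  0.245  0.267
#> # … one row per kept cluster and sample
```

Three clusters are kept out of the twenty mixture slots; each row of
`tidy()` gives a cluster's posterior median weight, its assigned
mutation count and its CCF (with 95% credible interval) at each sampling
time. The hard clustering recovers the simulated truth exactly here:

```r
labels <- hard_assignment(membership_probabilities(fit))
adjusted_rand_index(labels, sim$truth$labels[names(labels)])
#> [1] 1

compare_models(list(fit, clone_fit(sim$data, "Flat",
                                   max_iters = 8000, seed = 1)))
#> # A tibble: 2 × 4
#>   model       elbo elbo_se  rank
#>   <chr>      <dbl>   <dbl> <int>
#> 1 GP0-Mat32 -2558.   0.427     1
#> 2 Flat      -2568.   0.400     2
```

The timing-aware model wins the ELBO comparison by ~10 nats: on data
with genuine temporal structure, discarding the collection times costs
model evidence. `autoplot(fit)` draws the reconstructed CCF trajectories
on a dense grid with credible bands; `plot_predictive(fit, "s01")`
overlays the posterior-predictive VAF density on a sample's observed VAF
histogram; `predict_trajectories()`, `cluster_report()` and
`write_fit_report()` expose the same results programmatically and on
disk.

Real data enter through `read_mutation_table()` — a long-format TSV/CSV
with columns `mutationID`, `sampleID`, `altCounts`, `totalCounts` (or
`refCounts`), `purity`, `time`, and optionally `cnTotal` and
`cnMultiplicity`; see `?read_mutation_table`.

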