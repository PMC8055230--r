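---
title: "Models and methods behind clonetrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonetrend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrend)
```

# The problem

Bulk sequencing of a tumour sample observes, at each somatic locus, the
number of reads carrying the alternative allele out of the total reads
covering the locus. The quantity of biological interest is the
cancer-cell fraction (CCF) of each mutation — the fraction of cancer
cells that carry it — and its evolution over the course of the disease.
Mutations acquired by the same clone share a CCF trajectory, so
clustering mutations by CCF recovers the clonal composition of the
tumour, and tracking each cluster across longitudinally collected
samples recovers the clonal dynamics. `clonetrend` performs both steps
jointly, explicitly using the *timing* of sample collection, which
standard cross-sectional deconvolution discards.

# From read counts to CCF

A sample is modelled as a mixture of three cell populations at each
locus: normal cells (diploid), a reference cancer population without the
mutation, and a variant population with it. With purity $\rho_j$, a
shared local total copy number $D_{ij}$ for both cancer populations (no
sub-clonal copy-number events — the package's standing assumption), and
variant multiplicity $d_{ij}$, the expected VAF is linear in CCF:

$$\theta_{ij} = \zeta_{ij}\,\tilde\phi_{ij}, \qquad
\zeta_{ij} = \frac{d_{ij}\,\rho_j}{2(1-\rho_j) + D_{ij}\,\rho_j}.$$

$\zeta_{ij}$ is the VAF the mutation would have if clonal. Purity and
copy number are inputs, produced upstream by tools such as ASCAT or
ABSOLUTE and treated as fixed. When the multiplicity is not supplied,
`resolve_multiplicity()` estimates an integer value from
$u_{ij} = \theta_{ij}\rho_j^{-1}(2(1-\rho_j)+D_{ij}\rho_j)$, rounding to
the closest integer when $u \ge 1$ and taking 1 otherwise. Three
implementation choices deserve note:

* half-way ties round away from zero (the rounding rule leaves ties
  undefined otherwise);
* the estimate is clamped at $D_{ij}$, since noisy VAFs can otherwise
  imply more variant copies than chromosomes;
* by default the observed VAF is pooled across samples with depth
  weights before estimation, so each mutation keeps one multiplicity
  over time — consistent with the no-sub-clonal-CNV assumption; set
  `per_sample = TRUE` to estimate each cell independently.

The rule is exact for clonal mutations ($u = d$) but biased for
sub-clonal mutations carrying more than one variant copy ($u = d\tilde\phi$
can fall below the true $d$), which mis-scales $\zeta$ and can split a
CCF cluster downstream. This is a limitation of the estimation rule, not
of the model; supplying phased or upstream-derived multiplicities avoids
it entirely (see the simulator notes below).

# Mixture and trajectory priors

Mutations are clustered with a truncated stick-breaking Dirichlet
process: $w_1 = u_1$, $w_k = u_k\prod_{l<k}(1-u_l)$ with
$u_k \sim \mathrm{Beta}(1,\alpha)$ and the truncation closed by
$u_K \equiv 1$ so the weights form an exact simplex. The truncation
default is $K = 20$, comfortably above the cluster counts supported by
typical longitudinal series; the concentration carries the heavy-tailed
prior $p(\alpha) = (1+\alpha)^{-2}$, equivalent to a uniform prior on
$1/(1+\alpha)$.

Each cluster has a latent per-sample CCF $\phi_{jk}$, modelled through
its logit $\psi_{jk}$. The prior families:

* **Flat** — $\phi_{jk} \sim U(0,1)$ independently (standard logistic on
  $\psi$); sample timing is ignored. Accepts a single sample.
* **GP0** — each column $\psi_{\cdot k}$ follows one shared
  Gaussian-process prior $\mathcal{N}(0, h^2 G_\tau)$ over the
  normalized sample times.
* **GP1/GP2** — a separable multi-output GP:
  $\mathrm{vec}(\Psi) \sim \mathcal{N}(0, \Sigma_K \otimes G_\tau)$ with
  $\Sigma_K = \mathrm{diag}(h_1^2,\dots,h_K^2)$ (GP1) or
  $\Sigma_K = DCD$ with a full correlation matrix $C$ under an
  LKJ($\eta = 2$) prior (GP2), concentrating mass near the identity.
* **GP3** — block-diagonal covariance with cluster-specific amplitudes
  *and* time scales $h_k^2 g_{\tau_k}$.

Sample times are affinely normalized to $[0,1]$
(`normalize_times()`), so the inverse time-scale $\tau$ is unitless and
comparable across studies. Four stationary kernels are supported, in
order of increasing smoothness: exponential, Matérn-3/2, Matérn-5/2 and
exponentiated quadratic, each with $g(0)=1$ and hyper-priors
$h^2 \sim \Gamma(1,1)$, $\tau \sim \Gamma(1,1)$. GP1 and GP2 share one
$\tau$ across clusters, as the separable factorization implies; GP3 is
the variant with cluster-specific time scales. The GP2 correlation
matrix is parameterized through canonical partial correlations of its
Cholesky factor ($z_{ij} = \tanh(y_{ij})$, column-dependent symmetric
Beta laws), which reproduces the LKJ distribution exactly and with a
known normalizing constant — important because ELBOs are compared
*across* families.

# Observation models

Read counts follow either a binomial or, by default, a beta-binomial
distribution, $r_{ij} \sim \mathrm{BBin}(R_{ij}, v_j\theta_{ij},
v_j(1-\theta_{ij}))$, whose sample-specific precision $v_j$ absorbs
sequencing over-dispersion; the prior $1/(1+v_j) \sim U(0,1)$ is
uninformative on the over-dispersion scale, and `shared_dispersion =
TRUE` pools a single precision when the data are thin. As
$v \to \infty$ the beta-binomial converges to the binomial; the
implementation switches to a series expansion of the log-gamma ratios at
very large shape parameters so that limit is numerically clean. An
optional symmetric sequencing-error adjustment
$\theta \mapsto \epsilon(1-\theta) + (1-\epsilon)\theta$ is available
(`error_rate`); its functional form is a simple stand-in for an explicit
error model and is off by default.

Cluster assignments are marginalized analytically,
$\log p(r_i) = \log\sum_k w_k \exp \sum_j \log p(r_{ij}\mid \theta_{ijk})$,
computed with log-sum-exp stabilization. Marginalization (rather than
sampling discrete labels) keeps the objective differentiable, which
gradient-based variational inference requires. Expected VAFs are clipped
to $[10^{-9}, 1-10^{-9}]$ before likelihood evaluation so boundary CCFs
cannot produce degenerate beta shapes.

# Variational inference

All parameters are mapped to an unconstrained space (logits for stick
fractions, the identity for $\psi$, logs for $\alpha$, $h^2$, $\tau$,
$v$, inverse-tanh partial correlations for $C$) and given a mean-field
Gaussian variational family. The evidence lower bound

$$\mathrm{ELBO} = \mathbb{E}_q[\log p(y, z)] + \mathcal{H}(q)$$

is maximized by stochastic gradient ascent with the reparameterization
trick, one Monte-Carlo sample per step, and Adam (learning rate 0.02).
The gradients of the joint log-density are derived analytically for
every family — including the Kronecker-structured multi-output
covariances and the backpropagation through the Cholesky-of-correlation
construction — and the test suite verifies each family against numerical
differentiation.

Engineering choices, all exposed as arguments:

* initialization: cluster trajectories start at k-means centres of the
  observed per-mutation CCF matrix (deterministic given the seed);
  stick means start near uniform weights; variational standard
  deviations start at $e^{-2}$.
* convergence: the run stops when consecutive 500-iteration means of
  the ELBO trace change by less than a relative $10^{-4}$; the cap is
  20000 iterations. On the simulated conditions below, convergence is
  typically declared within 2000–5000 iterations.
* the reported final ELBO is re-evaluated at the optimum with 500 fresh
  Monte-Carlo draws (the per-iteration trace is noisy); its Monte-Carlo
  standard error accompanies every model comparison so near-ties are
  visible.
* `restarts > 1` re-runs the optimizer from progressively more
  agglomerated k-means initializations (about $K/2^{r-1}$ distinct
  centres at restart $r$) and keeps the best final ELBO. Mean-field
  ascent cannot merge two components once they have confidently split a
  true cluster — a local optimum the ELBO itself diagnoses — and the
  agglomerated starts approach the same data from the merged side.
  The default is 1; multi-sample series (large $M$) benefit most.
* covariance matrices carry a relative diagonal jitter of $10^{-6}$
  before Cholesky factorization.
* posterior draws (default 1000) are taken from the fitted variational
  distribution; clusters are relabeled by decreasing posterior mean
  weight (label switching does not occur within a mean-field fit, so a
  single permutation suffices).

Everything is deterministic given `seed`: identical calls give
bit-identical ELBO traces, draws and report files.

# Model comparison, post-processing, metrics

The maximized ELBO lower-bounds the log evidence, so models are ranked
by it (`compare_models()`); its internal complexity penalty gives the
expected Occam behaviour — on data simulated *without* temporal
structure, the heavily parameterized GP2 does not beat GP0 beyond
Monte-Carlo error, and the free-parameter counts underlying that
intuition are available via `parameter_count()` ($n_p = L + ML$ for Flat
with $L$ occupied clusters, plus 2, $L{+}1$, $L{+}1{+}L(L{-}1)/2$, $2L$
for GP0–GP3).

Soft memberships are posterior medians of the per-draw Bayes-rule
probabilities; hard labels take the argmax with ties broken toward the
heavier cluster. Clusters are pruned at a posterior median weight of
0.02 (or kept if any mutation is hard-assigned to them); the threshold
is a reporting convention, not part of the model, and both
median-weight and assignment-fraction summaries are reported.
Trajectories are reconstructed by drawing each cluster's latent function
on a dense grid (default 101 points) from the GP conditional given its
values at the sample times — for separable families the conditional mean
is $g_* G^{-1}\Psi$ regardless of $\Sigma_K$, while the conditional
spread retains the between-cluster covariance — and summarized by the
median and 95% band. Flat-model "trajectories" are straight
interpolations between samples and are flagged as such. The
posterior-predictive VAF density extends the count pmf continuously in
$r$ so the plotted curve is smooth and integrates to one.

ARI, AMI (permutation-model expectation, max normalization) and FMI are
implemented from the contingency table directly; tests pin them to
explicit pair-enumeration and permutation-enumeration oracles, and to an
independent third-party ARI implementation. Degenerate
single-cluster-vs-single-cluster comparisons return 1 by convention.

# The simulator

`simulate_clones()` generates datasets with known truth for validation
and benchmarking: Dirichlet cluster weights (symmetric, concentration
2), trajectories drawn from the GP prior at the design times (or
i.i.d. uniform CCFs with `prior = "flat"`, the matching null for
timing-blind models), multinomial cluster assignment, per-locus copy
number from a profile over {1..4} (default mass 0.7 on diploid, in line
with the copy-number-quiet genomes of chronic lymphocytic leukaemia,
the archetypal longitudinal setting), multiplicity uniform on 1..D,
purity uniform on [0.6, 1], negative-binomial depths (default mean 500,
size 10 — a targeted-sequencing regime), and beta-binomial counts
(precision 500). `min_separation` rejection-samples trajectories until
every pair differs by a stated mean absolute CCF, making benchmark
difficulty reproducible. The defaults describe one fixed, realistic
study condition; they are arguments, not tuning knobs.

Two honesty notes. First, the simulator emits its true multiplicities in
the output table by default (`emit_multiplicity = TRUE`), mirroring the
model's assumption that local copy state is known input; with
`emit_multiplicity = FALSE` the integer estimation rule is exercised
instead, and its clonal-mutation bias (above) then caps achievable
clustering accuracy — a property of the rule that real analyses relying
on it inherit. Second, the generator draws from the model family itself
(plus the copy-number layer), so recovery results certify the inference
machinery, not robustness to model misspecification: real data add
mapping artefacts, correlated errors within reads, sub-clonal CNVs and
imperfect purity estimates that the simulator deliberately does not
emulate.

`benchmark_grid()` crosses sample counts, mutation counts and cluster
counts, fits any set of models per replicate, and returns a tidy table
of ARI/AMI/FMI and ELBO per fit, recording failures as flagged rows. The
packaged tests run scaled-down grids (e.g. three replicates of
$M{=}12$, $N{=}24$, $K{=}2$) so the full suite stays fast; the grid
itself scales to the hundreds of datasets used in simulation studies.

# Known limitations

* No sub-clonal copy-number modelling: $D$ and $d$ are whole numbers
  shared by the reference and variant cancer populations. Loci violating
  this (parallel CNV and SNV evolution) will be mis-converted.
* The multiplicity estimation rule is exact only for clonal mutations.
* Mean-field VI underestimates posterior correlations; credible bands
  on trajectories are typically slightly narrow.
* ELBO comparisons inherit Monte-Carlo noise; differences within ~2
  combined standard errors should be treated as ties.
* Phylogenetic structure between clusters is out of scope; cluster CCF
  trajectories can be passed to dedicated tree-building tools.
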