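---
title: "Kernel machine tests for network community structure: models, simulations, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel machine tests for network community structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netkmt)
```

## The problem

Mesoscale organization — the partition of a network's nodes into
communities — varies across people, with disease, and over the lifespan,
particularly in brain functional connectivity. Given one weighted,
undirected network per subject (e.g. non-negative correlation matrices over
brain parcels), the question this package answers is: **is between-subject
variation in community structure associated with an outcome, after
adjusting for covariates?**

The model is semiparametric:

$$G(E(y_i)) = x_i^\top \beta + h(z_i),$$

where $y_i$ is a binary or continuous outcome, $x_i$ a vector of clinical
covariates modeled parametrically, and $h(\cdot)$ an unknown smooth
function of the subject's community structure $z_i$, living in the
reproducing kernel Hilbert space of a kernel $K$. The null hypothesis
$H_0: h(\cdot) = 0$ is equivalent to a variance component being zero when
$h \sim N(0, \tau K(\rho))$ is viewed as a subject-level random effect, and
is tested with a score statistic — no basis expansion is ever chosen by the
user.

## From partitions to a kernel

Community structure is not a vector, so the kernel is built from pairwise
dissimilarities between subjects' partitions:

$$K_{ij} = \exp\{-d^2(z_i, z_j)/\rho\}.$$

Four dissimilarities are supported, mirroring the two families of cluster
evaluation metrics:

* **Extrinsic** (node-level comparison of two labelings, used
  reference-free by letting each partition play the ground-truth role):
  two-way harmonic **purity**, **NMI** (natural-log entropies, normalized
  by the average entropy), and **ARI** (chance-corrected pair counting).
  Distances are $d = 1 - s$. This is the simplest monotone conversion with
  $d = 0$ for identical partitions; since ARI can be negative, its distance
  can exceed 1, which the kernel accepts unchanged.
* **Intrinsic** (no node-level comparison): the $p$-norm difference between
  the *optimized objective values* of the detection runs — modularity for
  Louvain, Potts Hamiltonian for spinglass. For scalar objectives all
  $p$-norms coincide with the absolute difference; `p` matters only if
  vectors of objectives (e.g. across resolutions) are supplied.

Degenerate-metric conventions (documented because they do occur in
cohorts with very similar subjects): NMI of two all-in-one partitions is 1,
NMI is 0 when exactly one entropy vanishes, ARI is 1 when the
chance-correction denominator is exactly zero. Zero cells contribute
$0\log 0 = 0$ by continuity.

The extrinsic-metric kernels are proper (positive semi-definite) Gaussian
distance kernels. The intrinsic distance is not guaranteed to be
Euclidean-embeddable, so its kernel can be indefinite; `davies_test()`
eigen-checks the kernel at the smallest grid bandwidth and warns rather
than repairing it, since the score moments $\mu_Q$, $\sigma_Q$ remain
computable either way.

## The score test and the bandwidth nuisance

Under $H_0$ the kernel disappears from the model, so $\rho$ is an
inestimable nuisance parameter. Following the classical treatment of a
nuisance parameter present only under the alternative, the standardized
score

$$S(\rho) = \frac{Q(\rho) - \mu_Q}{\sigma_Q}, \qquad
  Q(\rho) = r^\top K(\rho)\, r,$$

is evaluated along a bandwidth grid and treated as a $\rho$-indexed
Gaussian process, giving the upper bound

$$p \le \Phi(-M) + W e^{-M^2/2}/\sqrt{8\pi},$$

with $M = \max_\rho S(\rho)$ and $W$ the total variation of $S$ along the
grid. Here $r$ is the null-model residual: $y - \hat\mu_0$ from the
logistic GLM for binary outcomes, and the OLS residual standardized by
$\hat\sigma$ for continuous ones. The moments use
$\mu_Q = \mathrm{tr}(P_0 K)$ and $\sigma_Q^2 = 2\,\mathrm{tr}(P_0 K P_0 K)$
with $P_0 = D_0 - D_0 X(X^\top D_0 X)^{-1} X^\top D_0$, $D_0 =
\mathrm{diag}[\hat\mu_0(1-\hat\mu_0)]$ in the logistic case and $D_0 = I$
after standardization in the linear case. Two numerical conventions are
worth stating explicitly:

* The weight matrix is the Bernoulli **variance** $\mu(1-\mu)$; that is
  what the score-test derivation requires, and the same convention is used
  inside the Newton iteration of `estimate_h()`.
* Standardizing the gaussian residuals by $\hat\sigma$ makes $S(\rho)$
  invariant to the scale of $y$ and keeps $E[Q] \approx \mathrm{tr}(P_0K)$
  internally consistent.

**Grid.** The bounds follow the standard squared-distance rule
$L = 0.1\min_{i\neq j} d_{ij}^2$, $U = 100\max_{i\neq j} d_{ij}^2$; when
some subjects have identical partitions ($d = 0$), $L$ falls back to the
smallest positive squared distance. The default grid has $m = 50$
**linearly** spaced points including both endpoints. This was a genuinely
open choice (log spacing is the natural default for a scale parameter),
settled empirically: for the intrinsic metric the bounds span many orders
of magnitude, and at tiny bandwidths the kernel degenerates toward an
identity-plus-spikes matrix whose quadratic form is far from Gaussian, so
a log grid — which devotes half its points to that regime — inflates the
null rejection rate of the intrinsic metric to roughly twice its
linear-grid value, while a linear grid passes through that regime with a
single point and keeps the intrinsic metric's Type I error at its nominal
level (the null studies in the acceptance suite check this).
Extrinsic-metric results are essentially indifferent to the spacing.
`rho_grid()` exposes both. $W$ is the sum of $|\Delta S|$ over consecutive grid
points; because the grid contains $L$ and $U$ themselves, the endpoint
terms of the bound are covered. Grid points with vanishing $\sigma_Q$ are
dropped with a warning; the p-value is clamped at 1 (the bound is not a
probability for small $M$, large $W$). The bound is conservative by
construction, which the Type I error studies below confirm.

`estimate_h()` is an estimation companion (ridge-type closed forms for the
linear model, blocked Newton–Raphson for the logistic one, relative-change
tolerance $10^{-8}$, 100-iteration cap) for examining $\hat h$ at fixed
$(\lambda, \rho)$; the test itself never estimates these.

## Community detection

* **Louvain** (`detect_louvain()`): weighted modularity maximization,
  delegated to igraph's implementation; the stored objective is this
  package's own direct evaluation of $Q$ on the returned partition, which
  the test suite checks against igraph's independent computation. Louvain
  is stochastic through its node scan order; all runs respect R's RNG
  seed.
* **Spinglass** (`detect_spinglass()`): simulated annealing on the
  Reichardt–Bornholdt Potts Hamiltonian
  $H(\sigma) = -\sum_{i<j}(A_{ij} - \gamma k_ik_j/2m)\,
  \delta(\sigma_i,\sigma_j)$ with the configuration-model null and
  resolution $\gamma = 1$ by default. Spin states range over
  `1..max_communities`; empty states are allowed, so the detected number
  of communities can be smaller than the cap. The schedule is geometric:
  $T_0 = 1$, cooling factor $0.99$, $N$ sweeps of $N$ single-node
  proposals per level, stopping at $T = 10^{-3}$ or as soon as a level
  accepts no move. The Hamiltonian is stored *signed* (lower = better), so
  intrinsic distances are differences of signed energies. On networks of
  up to 8 nodes the annealer provably reaches the exhaustive-enumeration
  ground state in the test suite.

`consensus_community_count()` reproduces the usual practice of scanning
`max_communities` over a candidate range across a cohort and taking the
modal number of non-empty communities.

## The simulator

Each subject's network is built from a planted community assignment: every
unordered dyad gets an independent Beta-distributed weight — from the
within-community distribution if the dyad is intra-community, otherwise
from the between-community distribution. The Beta support $[0,1]$ matches
non-negative correlation-like connectivity. Inter-subject variability has
two knobs:

* **Perturbation**: each node is independently reassigned with probability
  `perturb_prob`, uniformly among the *other* community labels, so a
  flagged node always moves. The number of moved nodes is therefore
  Binomial($N$, `perturb_prob`).
* **Master assignments**: within one generating population, subjects are
  perturbed copies of a single "master" assignment with uniform
  multinomial community sizes (redrawn until no community is empty). Under
  the alternative, cases and controls are *two distinct generating
  populations*: each group draws its own master. This is the study-design
  reading of a two-group process, and it is what gives the extrinsic
  metrics their discriminating signal — with one shared master the two
  groups' detected partitions are exchangeable and every extrinsic metric
  loses its power. `simulate_cohort(shared_master = TRUE)` remains
  available, and is what the null (one-population) scenario uses.

The simulator emulates: bounded correlation-like weights, planted block
structure, subject-level perturbation, and case/control imbalance. It does
**not** emulate: negative/signed edges, the temporal autocorrelation of
BOLD time series, site/scanner effects, spatially structured parcels, or
hierarchical communities. Passing the study below therefore says the test
behaves correctly when its distributional assumptions hold, not that it is
robust to every artifact of real connectivity pipelines.

## The replication study

The shipped presets reproduce the published simulation conditions: 100
networks of 50 nodes and 3 planted communities per replication, 45/55
case/control split, perturbation 0.1, between-community weights
Beta(1.5, 8) for everyone, within-community weights Beta(7, 8) for cases
and Beta(8, 8) for controls; the null scenario draws all 100 networks from
the control design and randomizes the labels. The logistic branch uses the
group label as outcome with an intercept-only null (no covariates, as in
the original study); the linear branch simulates a N(10, 5) continuous and
a Bernoulli(0.25) binary covariate with outcome
$y = 5 - 4\cdot\mathrm{case} + N(0, 2)$ under the alternative and
$y \sim N(100, 15)$ under the null, adjusting for both covariates.

Problem sizes are a deliberate package choice: the acceptance suite runs
300 replications for the Louvain scenarios and 100 for the spinglass
branch (the original study used 1000), with the spinglass annealer on a
reduced schedule ($T_{\min} = 10^{-2}$, 10 sweeps per level): on these
strongly separated simulated networks annealing freezes early, so the
reduced schedule loses little — the acceptance suite confirms the branch
retains its published power and Type I error band. Monte Carlo uncertainty at 300 replications is about $\pm 0.006$ (SE) for
a rate near 0.99 and $\pm 0.012$ near 0.05.

One empirical behavior of this implementation deserves a note: the power
of the intrinsic (objective-value) metric is sensitive to how much
run-to-run noise the detection algorithm leaves in the optimized
objective, because that noise inflates within-group distances. Published
figures for this metric therefore depend on implementation details
(stopping tolerances especially) more than the extrinsic metrics do.

## Numerical and degenerate-input choices

* Distance matrices are symmetrized (averaged with their transpose) and
  clipped at 0 against $10^{-16}$-scale float underflow before entering
  the kernel.
* `fit_null()` errors on rank-deficient designs and on non-converged
  logistic fits (perfect separation) rather than returning silently wrong
  moments.
* A constant kernel (all-ones, reached as $\rho \to \infty$) is
  annihilated by any design containing an intercept: $\sigma_Q = 0$ and
  the grid point is dropped as degenerate.
* All randomness flows through R's RNG: cohort simulation accepts a
  `seed`, study replications derive per-rep seeds from the study seed, and
  identical seeds give bit-identical results (including the C++ annealer,
  which draws from R's RNG).

## Known limitations

* The bandwidth grid bound, not an exact null distribution, determines the
  p-value; the test is conservative, visibly so for the ARI metric.
* The intrinsic-metric kernel may be indefinite (warned, not repaired).
* Estimation of $(\tau, \rho)$ by REML-type profiling is out of scope; the
  test treats $\rho$ by grid search only.
* Multilayer/hierarchical communities and signed networks are not
  supported.
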