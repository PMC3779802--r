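---
title: "Multilevel selection on swarming cooperation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel selection on swarming cooperation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmsel)
```

## The question

Secreted public goods — here, the rhamnolipid biosurfactants that let
*Pseudomonas aeruginosa* colonies swarm across a plate — benefit every cell
in the colony, producers and non-producers alike. Within any mixed colony a
non-producing defector therefore outgrows a costly producer, yet swarming
producers persist in nature. `swarmsel` quantifies the resolution offered by
multilevel selection: colonies richer in cooperators grow larger (they reach
more nutrients by expanding), so selection *between* colonies can oppose and
sometimes overturn selection *within* them. The package asks, for a given
within-colony competition model and a given amount of between-colony
variation, whether the global cooperator frequency rises or falls after one
round of colony growth.

## Within-colony competition model

Two strains, cooperators $C$ and defectors $D$, share a finite nutrient pool
$N$ in a closed colony:

$$\dot C = Y_C\, q\, \phi(N)\, C,\qquad
  \dot D = Y_D\, q\, \phi(N)\, D,\qquad
  \dot N = -q\, \phi(N)\,(C+D),$$

with $\phi(N) = N/(K_n+N)$ under Monod kinetics and $\phi(N) = \mathbf{1}[N>0]$
in the zeroth-order reduction used by default: both strains grow
exponentially at rates $Y_C q$ and $Y_D q$ until the pool is exhausted, then
stop. Costly cooperation means a lower cooperator yield, $Y_C < Y_D$.

The group benefit of swarming enters through the pool size. A colony
inoculated with cooperator proportion $p_i$ expands more the more
cooperators it has, so the nutrients it can reach grow from $N_{\min}$ (pure
defectors, no swarming) to $N_{\max}$ (pure cooperators):

$$N_0(p_i) = N_{\min} + (N_{\max}-N_{\min})\,S(p_i),$$

where $S$ is a logistic in $p_i$ with steepness `g_sat` and midpoint
`p_half`, affinely rescaled so $S(0)=0$ and $S(1)=1$ exactly. The exact
algebraic form of the saturation curve is a modelling choice; we use the
rescaled logistic because it pins both endpoints, its two parameters map
directly onto "how fast the benefit saturates" and "where", and `g_sat = 0`
recovers the exactly linear (no-diminishing-returns) limit. The default
midpoint `p_half = 0.25` places the onset of saturation below $p_i = 0.5$,
matching the observation that colony size gains level off beyond
half-cooperator mixtures. A Hill-type curve could be swapped in without
touching the rest of the machinery, since everything downstream consumes
only the response curves.

Each competition is summarized by the colony's initial proportion $p_i$, its
within-colony change $\Delta p_i$ (individual-level selection) and its
fitness $w_i$ = final over initial total cells (group-level selection).
Because every colony starts from the same inoculum — the model's standing
assumption — $w_i$ is proportional to final colony size.

**Solvers.** The zeroth-order model has an exact solution: the exhaustion
time $t^*$ solves
$(C_0/Y_C)(e^{Y_C q t^*}\!-\!1) + (D_0/Y_D)(e^{Y_D q t^*}\!-\!1) = N_0$,
a convex increasing equation solved by safeguarded Newton iteration started
from the fastest single-strain bound (monotone convergence, relative
tolerance $10^{-13}$). `run_competition()` uses this path by default; an
independent `deSolve` route (`lsodar`, relative tolerance $10^{-10}$, with
the exhaustion event detected as a root of $N$, not clipped afterwards) is
kept behind `solver = "ode"` and agrees to better than $10^{-6}$; Monod
kinetics with $K_n \to 0$ converge to the same limit. Nutrient bookkeeping
$(C_f-C_0)/Y_C + (D_f-D_0)/Y_D = N_\text{consumed}$ holds to $10^{-6}$ on
every path and is tested as an invariant.

**Growth-driven variant.** To contrast swarming (a carrying-capacity
benefit) with cooperation that merely accelerates growth, the growth-driven
model fixes $N_0$ and lets the uptake rate rise with cooperator proportion,
$q(p_i) = q_D + (q_C-q_D)\,p_i$, with the conventional endpoints
$q_D = 0.5$, $q_C = 1$. Linear interpolation is the simplest curve through
the two defined endpoints; only the endpoints are constrained by the
modelled biology. Once all colonies exhaust the fixed pool, final sizes are
set by yields alone and the group benefit vanishes — the r-strategy analogue
of the K-strategy benefit of expansion.

## Population structure and relatedness

Variation among colonies is modelled by a logit-normal law: the
cooperator-to-defector ratio is log-normal, $X = \log_{10}(C/D) \sim
\mathcal N(\mu, \sigma)$, and $p_i = (1+10^{-X})^{-1}$. One parameter,
$\sigma$, moves the density of $p_i$ from unimodal (well-mixed seeding) to
bimodal (strong segregation). Whole-group relatedness is

$$r = \frac{\mathrm{Var}(p_i)}{E(p_i)\,\bigl(1-E(p_i)\bigr)},$$

the between-colony variance relative to its maximum under full segregation.

Moments are computed by adaptive quadrature **on the X scale**
(`stats::integrate` over the normal density), which avoids the endpoint
singularity of the Jacobian $1/(\ln 10\, p(1-p))$ on the $p$ scale; the
quadrature tolerances ($10^{-10}$ relative) make the reported relatedness
accurate to far better than the two decimals quoted. The first-order
Delta-method approximation ($E \approx (1+10^{-\mu})^{-1}$,
$\mathrm{Var} \approx g'(\mu)^2\sigma^2$) is exposed only as a labelled
diagnostic: beyond $\sigma \approx 1$ it exceeds the logical bound
$E(1-E)$, so it is never used where relatedness is reported. At
$\mu = 0,\ \sigma = 4.2$ the exact computation gives $r = 0.8378$, i.e.
$0.84$ to two decimals.

An alternative, mechanistic source of the same variance is a dilution
bottleneck: $n \sim$ Poisson($\lambda$) founder cells per colony (empty
colonies excluded), each independently a cooperator with the global
probability. Then $\mathrm{Var}(p_i) = p(1-p)\,E(1/n \mid n\ge 1)$, so
$r = E(1/n \mid n \ge 1)$ independent of $p$. The series is summed to a
$10^{-12}$ relative tail and inverted by monotone root-finding;
$\lambda = 0.65$ founders per colony gives $r = 0.844$, and inverting
exactly at $r = 0.84$ gives $\lambda = 0.669$ — the pair (0.84, 0.65)
quoted in the literature is consistent at two-decimal printing precision,
and the package always reports its own computed values.

## The Price partition

For an ensemble of colonies with weights $\omega_i$ (probability masses or
relative inocula; equal by default),

$$\Delta p \;=\;
  \underbrace{\frac{\mathrm{Cov}(w_i, p_i)}{E(w_i)}}_{\text{group level}}
  \;+\;
  \underbrace{\frac{E(w_i\,\Delta p_i)}{E(w_i)}}_{\text{individual level}},$$

with all expectations $\omega$-weighted. `price_decompose()` also computes
the pooled final proportion directly, $\sum \omega_i w_i p_i' / \sum
\omega_i w_i$, and verifies the partition identity against it; the identity
is algebraically exact and holds to $10^{-12}$ in floating point on random
ensembles (a property test).

`global_response(p, sigma, ...)` assembles the pieces: $\mu$ is root-found
so the mixing distribution has *exact* mean $p$ (the Delta approximation is
not used here), an ensemble is formed, each colony's $(\Delta p_i, w_i)$ is
read off the competition model, and the Price partition is returned.

**Ensemble construction.** The reference ensemble is deterministic: 201
midpoint-rule nodes $x_k = \mu + \sigma\,\Phi^{-1}\!\bigl((k-\tfrac12)/K\bigr)$
with equal probability weights $1/K$ on the X scale. This makes scans exactly
reproducible without a seed; a seeded Monte-Carlo mode (default $10^4$
groups) exists as a cross-check and agrees within Monte-Carlo error. The
number of subpopulations behind the original analyses is not knowable, so
determinism, not fidelity to an unknown sample size, drove this choice.

**Interpolation surface.** Scans evaluate the competition model through
`response_surface()`: the response curves on a 401-point grid, interpolated
by a natural spline for $\Delta p_i(p)$ and a monotonicity-preserving
Hermite spline for $w_i(p)$ (monotone interpolation keeps the group-level
covariance from acquiring spurious wiggles). On these smooth curves the
interpolation error is orders of magnitude below every tolerance used.

`mls_scan()` tabulates $\Delta p(p, \sigma)$, reports interior equilibria
(sign changes of $\Delta p(p)$; $+\to-$ is a stable coexistence point), and
the fixation threshold $\sigma^*$ — the smallest $\sigma$ with $\Delta p > 0$
across the whole $p$ grid — refined by bisection to $10^{-2}$ and returned
as the upper end of the final bracket so its defining property holds exactly
on the evaluated grid. Grid resolution (99 interior $p$ points by default)
is part of the reported result.

`direct_resample()` is the model-free counterpart: pairs of observed
proportion levels (e.g. 17%/83%) are pooled with equal weight per level
into a two-point global population, whose relatedness has the closed form
$((p_h-p_l)/2)^2 / (\bar p(1-\bar p))$ — 0.4356 for the 17/83 pair, 0.9604
for 1/99, and exactly 1 for the 0/100 pair.

## Fitting the competition model

`fit_competition()` estimates parameters from replicated per-colony counts
by weighted least squares on the replicate means of $\Delta p_i$ and $w_i$
per proportion level. The two residual blocks are scaled by the standard
deviation of the observations in each block (so neither observable
dominates by units), and each level is weighted by its replicate count.
The optimizer is `nlminb` with box bounds on a log scale (positivity without
reparameterization tricks), started from 20 Latin-hypercube points in the
bounds plus one data-driven heuristic start; the best six candidates by
initial loss are refined locally and the best refit wins. Derivative-free
search was considered and rejected: the loss surface is smooth, and
numerical gradients with bounds are both faster and more reliable here.

**Identifiability.** With endpoint data on a fixed duration, only the
products $Y q$ are identified, so $q = 1$ is fixed by convention. A second
exact gauge freedom is specific to fully exhausted zeroth-order data:
rescaling both yields by $c$ and both pools by $1/c$ leaves every final
count unchanged (substitute $y = x^c$ in the exhaustion equation). The
yield *ratio* $Y_C/Y_D$ — the quantity of biological interest — is always
identified; fix one yield via `fixed` when absolute values matter. Bootstrap
uncertainty (`bootstrap_fit()`) uses case-resampling of replicates within
each level, refits from the point estimate, and reports min–max intervals
(the error-bar convention of the experimental literature, not percentile
CIs); the default is $B = 200$.

## Synthetic data

`generate_competitions()` emulates the plate experiment the analysis was
designed for: five mixing levels $\{0.01, 0.17, 0.5, 0.83, 0.99\}$, six
replicate colonies per level, an inoculum of $10^6$ cells split exactly
between the strains, and independent log-normal multiplicative noise of
mean 1 on each final count, rounded to whole cells. The default coefficient
of variation, 0.15, is typical of serial-dilution CFU counting. What the
generator deliberately does not emulate: spatial colony structure, plate-to-
plate batch effects, counting detection limits, and any dependence of the
noise on colony size — so passing recovery tests demonstrate correctness of
the estimation machinery under the stated error model, not robustness to
every failure mode of real plate data.

The reference truth sets in `example_params()` define the three regimes the
analysis distinguishes: `"costly"` ($Y_C/Y_D = 0.8$, strong saturation —
inverse-bell $\Delta p_i$, plateauing $w_i$), `"wildtype"` (marginal yield
advantage 1.05, linear benefit), `"neutral"` (equal yields, linear benefit)
and `"growth_driven"`. The magnitudes were chosen once to give colony
fitness in the 2–5× range and within-colony losses of a few percentage
points, the scale of the motivating plate experiments.

Under the costly truth the full analysis gives a finite fixation threshold
($\sigma^* \approx 2.4$ on the default grids), stable cooperator–defector
coexistence at intermediate $\sigma$, and a single sign change of
$\Delta p(\sigma)$ at $p = 0.5$; the wild-type truth is favored at every
$\sigma$; the growth-driven truth is favored only while colonies are still
growing. These are the qualitative signatures the acceptance tests assert —
the numeric thresholds depend on the truth parameters and are not external
targets.

## Numerical choices, degenerate inputs, limitations

* Proportions at the boundary: pure colonies are legal inputs everywhere
  ($\Delta p_i \equiv 0$ there); the mixing density is defined on the open
  interval and returns 0 at the endpoints by convention.
* $\sigma = 0$ degenerates gracefully: one colony at the global proportion,
  zero group term, relatedness 0.
* A vanishing pool ($N_0 \to 0$) gives $w_i \to 1$ exactly; colonies that do
  not exhaust within `duration` return their state at `duration` with the
  unconsumed remainder reported.
* A colony counts as "at carrying capacity" when
  $N_\text{final} < 10^{-6} N_0$; `compare_durations()` flags whole scans
  with `all_exhausted`.
* Problem sizes throughout (401-point surfaces, 201 quadrature nodes, 99-point
  $p$ grids, 100-repetition recovery studies, $B$ in the tens for test
  bootstraps) were chosen so the full analysis re-runs comfortably on a
  single CPU; all are arguments, not constants.
* One round only: the package evaluates $\Delta p$ for a single cycle of
  colony formation, growth and pooling. Iterated dynamics, fluctuating
  $\sigma$ across rounds, spatially explicit swarming, and stochastic
  birth–death noise within colonies are out of scope.
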