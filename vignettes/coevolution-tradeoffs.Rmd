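---
title: "Modelling dynamical growth-defense trade-offs in coevolving predator-prey populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dynamical growth-defense trade-offs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevotrade)
```

## The model

`coevotrade` implements an individual-based stochastic model of a prey
(bacteria-like) and a predator (ciliate-like) species that both evolve by
de novo mutation. There is no predefined set of types: the simulation
starts from one ancestral type per species, and new types arise, spread,
and go extinct under selection and drift. All dynamics are generated by a
small set of mass-action reactions simulated exactly with the
direct-method stochastic simulation algorithm (SSA).

A prey type $X_i$ carries a trait $g_i \in (0, 1]$ coupling growth to
defense: it reproduces at rate $b_x g_i$ (mutating with probability
$\mu_x$ per birth), dies intrinsically at rate $d_x$, and each individual
suffers competition death at rate $r_c (N_x - 1)$, where $N_x$ is total
prey abundance — competition within and between types is identical, so a
homogeneous prey population in isolation grows logistically with carrying
capacity $K(g) = (b_x g - d_x)/r_c$.

A predator type $Y_l$ carries a reproduction efficacy
$k_l \in (0, k_{\max}]$, the probability that consuming a prey also
produces a predator offspring. Predation on the pair $(i, l)$ occurs at
rate $f(g_i, k_l)\, x_i y_l$ with the power-law trade-off

$$f(g, k) = p\, g^{\,m k / k_{\max}},$$

increasing in $g$ (fast growers are poorly defended) and decreasing in
$k$ (investment in reproduction costs predation ability). Conditional on
a predation event the prey dies and, with probability $k_l$, a predator
is born (a mutant with probability $\mu_y$). Predators die at rate $d_y$.

The exponent $e = m k / k_{\max}$ determines the curvature of the
growth-defense trade-off experienced by the prey under a given predator:
$e > 1$ is concave (defense is *cheap*: a small growth cost buys a large
defense gain), $e < 1$ convex (*costly*), $e = 1$ linear. Because $e$
depends on the resident predator's $k$, the trade-off is **dynamical**:
as predators evolve smaller $k$ (better predation), the same prey
trade-off becomes more convex. `tradeoff_shape()` reports $e$ and its
classification; the boundary $|e - 1| < 10^{-9}$ is reported as linear
because exact $e = 1$ arises for rational parameter choices.

## Parameters and defaults

All rates are per unit simulation time; traits are dimensionless.

| parameter | default | meaning |
|---|---|---|
| `b_x` | 1.0 | prey background birth rate (type $i$ reproduces at $b_x g_i$) |
| `d_x` | 0.1 | prey intrinsic death rate |
| `r_c` | 5e-5 | pairwise competition rate; $K(1) = 18000$ |
| `mu_x` | 1e-4 | mutation probability per prey birth |
| `d_y` | 0.5 | predator death rate |
| `mu_y` | 1e-3 | mutation probability per predator reproduction |
| `p` | 0.005 | predation time-scale constant; $f(1, k) = p$ |
| `m` | 3 | initial trade-off shape (concave/cheap under the naive predator) |
| `k_max` | 0.3 | upper bound of the reproduction efficacy |

The default initial condition is 1000 prey at $g_1 = 1$ (fastest growth,
no defense) and 100 predators at $k_1 = k_{\max}$ (naive: best
reproduction, worst predation), run to a horizon of 2000 with a recording
grid of 1. What matters for evolutionary dynamics are the *effective*
mutation supplies $\mu_x N_x$ and $\mu_y N_y$; the per-event
probabilities above are calibrated to the population sizes that these
rates produce ($N_x^* \approx 333$, $N_y^* \approx 177$ at the
one-type fixed point), giving a mutation-limited regime in which a
handful of types segregate at a time.

Mutant traits are drawn from a **uniform** kernel by default (uniform on
$(0, 1]$ or $(0, k_{\max}]$, independent of the parent). A **normal**
kernel (parent-centred, resampled until inside the open trait range) is
available; its standard deviations are not pinned down by any closed-form
consideration, so we chose `sigma_g = 0.05` and `sigma_k = 0.015` — 5% of
each trait's range — as a conventional "small-effect mutation" scale.
Resampling (rather than reflecting or clipping) was chosen because it
preserves the stated open support without accumulating probability mass
at the boundaries; it is capped at 1000 attempts and errors beyond that,
which can only trigger for pathological `sigma` values.

## Simulation engine and numerical choices

The engine (`coevo_sim()`) is a compiled direct-method SSA. Design
choices that matter:

* **One channel per prey-predator pair with post-draw branching.** The
  three predation outcomes (consumption only / with reproduction / with
  mutant reproduction) have rates $(1-k)f$, $k(1-\mu_y)f$ and
  $k \mu_y f$, which sum to $f$; drawing the outcome after selecting the
  pair is mathematically identical to three separate channels and keeps
  the channel scan short. The branch probabilities summing to exactly 1
  is machine-checked in the tests.
* **Competition without self-competition.** The per-capita competition
  death rate is $r_c (N_x - 1)$ (each ordered pair of distinct
  individuals contributes $r_c$), which makes the mean-field carrying
  capacity exactly $(b_x g - d_x)/r_c$ up to $O(1/N)$ and gives a clean
  closed-form oracle. The alternative $r_c N_x$ scaling differs only at
  $O(1)$ abundances.
* **Cached pair rates.** $f(g_i, k_l)$ is evaluated once when a type is
  created and cached in a pair matrix; per event the engine only forms
  mass-action sums over extant types, so cost per event is linear in the
  (small) number of extant type pairs.
* **Sampling convention.** Abundances are recorded on the fixed grid by
  holding the state constant between events (right-continuous paths).
* **Absorption.** If the prey goes extinct, predation stops and
  predators decay by pure death — the run continues to the horizon,
  where the terminal status is read off the extant totals. The fully
  extinct state has zero total propensity and terminates the event loop
  immediately; the remaining grid points are filled with the empty state.
* **Reproducibility.** Each realisation uses R's RNG seeded from its
  configuration, so one seed plus one configuration is bit-identical,
  and ensembles use `base_seed + run index` so partial sweeps can be
  restarted and are invariant to execution order.
* **Trait bounds.** Draws are strictly inside the open-below ranges;
  a mutant equal to exactly 0 cannot occur.

An R-level single-event stepper (`ssa_step()`) implements the same
reaction scheme on top of the exported propensity functions. It is the
readable reference implementation and the vehicle for distributional
tests (e.g. exponentiality of waiting times at frozen propensities);
trajectories come from the compiled engine, and the two are checked
against the same closed-form oracles.

## Oracles: what validates the engine

Two mean-field results serve as independent oracles. The prey-only
carrying capacity $K(g)$ above, and the interior fixed point of the
one-prey one-predator system,
$$X^* = \frac{d_y}{k f(g,k)}, \qquad
  Y^* = \frac{b_x g - d_x - r_c X^*}{f(g,k)},$$
with non-coexistence flagged when $Y^* \le 0$. Both are cross-checked in
the tests against direct numerical integration of the ODEs (relative
error below $10^{-6}$), and the stochastic engine's time-averaged
abundances are required to land near them (within 15% for the cycling
two-species system, within 10% for prey alone). At the default rates the
baseline fixed point is $X^* = 333.3$, $Y^* = 176.7$.

## Ensemble analyses

`classify_outcome()` reads the extant totals at a horizon;
`richness()` counts types with abundance $\ge$ `min_count` at each
sample time and averages; `shannon()` is $-\sum q_i \ln q_i$.
Ensemble means of richness and diversity are **conditional on
coexistence** at the horizon, the natural conditioning when many
realisations lose a species. The default `min_count = 1` counts every
extant lineage; because transient single-copy mutants inflate raw
counts, a higher threshold is available, and reported results state
which was used.

The directional predictions of the model, each checked at 95% confidence
on paired 200-run ensembles at the standard parameterisation (horizon
2000):

* coexistence is more likely when the initial trade-off is concave
  ($m = 3$ versus $m = 0.5$, where runs frequently end in joint
  extinction after tall, narrow cycles);
* prey richness increases with $m$;
* at $m = 3$, prey richness is higher under prey-only evolution
  (`predator_evolves = FALSE`) than under coevolution — coevolving
  predators drag the trade-off towards costly and prune prey diversity;
* predator richness is lower at $m = 10$ than at $m = 3$: under a very
  cheap trade-off all prey afford strong defense, which constrains
  predators to high predation ability and low diversity.

A note on problem sizes: these ensembles are run at the standard
competition rate $r_c = 5\times10^{-5}$. We verified that "speeding up"
the system by raising $r_c$ (which shrinks populations) strengthens the
logistic damping of the stochastic cycles enough to suppress the
extinction pattern at $m < 1$ — the qualitative coexistence ordering is a
property of the weakly damped, large-fluctuation regime, so the check
must be run at the standard rates. Engine-validation tests, by contrast,
use $10\times$ or $100\times$ `r_c` freely, because the mean-field
recovery they measure is insensitive to the damping.

`phase_lag()` estimates the dominant cycle period from the periodogram
of the total-prey series and the predator's time shift by maximising the
cross-correlation, reporting lag/period in $[0, 1)$ — classical cycles
give 0.25, evolutionarily shifted cycles approach 0.5. A permutation
test (199 shuffles) gates the estimate: without a significant spectral
peak the lag is reported as undefined (`NA`) rather than as noise.

## Trade-off curve fitting

`tradeoff_fit()` / `fit_power_law()` fit $y = a z^c$ between prey growth
($z$) and mean predator growth on that prey ($y$, the standard proxy for
*lack of* prey defense) by nonlinear least squares **on the original
scale**, with starting values from a log-log linear regression. The
log-log fit is initialisation only: least squares on the log scale
weights multiplicative errors equally, which is a different estimator
and systematically differs on assays whose noise is closer to additive.
The free constant $a$ absorbs the overall growth scale, so the exponent
is invariant to rescaling the response (tested). $R^2$ is
$1 - SS_{res}/SS_{tot}$; classification uses strict inequalities at
$c = 1$ by default (`tol = 0`), configurable.

Whether growth rates should be normalised to the ancestral population
before fitting is ambiguous in general; the fitter takes raw inputs and
exposes `normalize = TRUE` as an option. Normalisation cannot change
$c$, only $a$, so the shape classification is unaffected.

`synthetic_assay()` generates the test bed: a 4-point design (one
ancestral plus three coevolved prey populations, growth rates spread
over $(0.2, 1]$) with 3 technical replicates and mean-one lognormal
noise of chosen coefficient of variation. It emulates the *structure* of
a real growth assay — few populations, few replicates, multiplicative
measurement error — but not its biology: real assays have unevenly
spaced growth rates, possibly non-lognormal error, and day/batch
effects. Passing the recovery tests (median $\hat c$ within 5% of truth
at 1% noise over 500 assays, machine-precision recovery at zero noise)
therefore demonstrates that the *fitting procedure* is accurate on
assay-sized designs, not that any particular experimental estimate is
correct. The regime-separation test generates stand-in assays in a
strongly concave regime ($c \approx 4.3$) and two convex regimes
($c \approx 0.23, 0.14$) and requires the cheap/costly classification to
flip accordingly.

## Known limitations

* No spatial structure; competition is symmetric within and between
  prey types by construction.
* The predator-side trade-off (reproduction efficacy versus predation
  ability) is an assumption of the model, not something the package can
  estimate from data.
* The direct method is exact but serial; runs with very large
  populations (small `r_c`) are event-bound. No tau-leaping or hybrid
  ODE acceleration is provided.
* `phase_lag()` assumes an approximately stationary window with a single
  dominant period; regime shifts within the window (e.g. a mid-run
  change of the resident prey type) blur the estimate, which is why the
  permutation gate errs on the side of "undefined".
* Richness counts depend on the `min_count` convention at low abundance;
  comparisons should always hold it fixed.
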