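---
title: "Mapping the parameter space of a two-cell biological switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the parameter space of a two-cell biological switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(switchmap)
```

## The model

During *Drosophila* oogenesis one of the two central cells of the 16-cell
germline cyst is selected as the oocyte. The selection is foreshadowed by
the accumulation of *orb* mRNA and Orb protein in that cell: Orb promotes
translation of its own transcript and, by binding *orb* mRNA to the
fusome, withdraws it from intercellular exchange. `switchmap` implements a
two-cell model of this positive feedback. Each cell `i` carries unbound
mRNA, fusome-bound mRNA and protein; binding and unbinding are fast, so a
rapid-equilibrium reduction collapses the six equations to four
(`reduce_rapid_equilibrium()`, `rhs_reduced()`), and rescaling time by the
maximal intercellular mRNA transport rate gives the dimensionless system
(`rhs_scaled()`)

$$\dot M_i = 1 - \mu M_i - \frac{M_i}{1+\kappa H_1(P_i)}
            + \frac{M_j}{1+\kappa H_1(P_j)},$$
$$\dot P_i = (1+\gamma H_2(P_i))\,
            \frac{1+\eta H_1(P_i)}{1+\kappa H_1(P_i)}\,M_i
            - \pi P_i + \epsilon\,(P_j-P_i),$$

where $H_1$ is the Hill switch for protein-induced mRNA binding
(threshold $\theta_1$, exponent $n$) and $H_2$ the switch for
autocatalytic translation (threshold $\theta_2$, exponent $\nu$). The
eight groups $(\mu, \pi, \epsilon, \gamma, \theta_1, \theta_2, \kappa,
\eta)$ are dimensionless; $\mu$ and $\pi$ compare degradation with mRNA
transport, $\epsilon$ compares protein with mRNA transport, $\gamma$
measures autocatalysis, and $\kappa = K/(1+K_0)$, $\eta = K/K_0$ descend
from the binding equilibrium constants. A steady state has equal total
mRNA in the two cells exactly when it has equal protein, so symmetry
breaking is read off the protein coordinates alone.

An *asymmetric* stable steady state ($P_1 \neq P_2$) models selection of
one cell; a parameter set whose stable states are *all* asymmetric
guarantees selection from every initial condition.

## Step one: exact decomposition in the sharp-switch limit

With $n, \nu \to \infty$ the Hill functions become Heaviside steps and
the positive $(P_1, P_2)$ quadrant splits into nine open domains on which
the dynamics are affine (`enumerate_domains()`, `affine_subsystem()`).
Each domain's matrix is block lower-triangular with eigenvalues
$\{-\pi, -\pi-2\epsilon\}$ and two strictly negative mRNA eigenvalues, so
it is Hurwitz for every positive parameter set and owns a unique fixed
point with the closed form implemented in `domain_fixed_point()`. Summing
the two mRNA equations shows $M_1 + M_2 = 2/\mu$ at every fixed point;
$M_1 = M_2 = 1/\mu$ holds only when both cells share the same transport
state — for mixed-transport domains the general form
$\mu M_1 = (\mu + 2T_2)/(\mu + T_1 + T_2)$ is required, and it is this
form that produces the long rational bounds in the region inequalities.

A domain is *attracting* exactly when its fixed point lies inside it
(`attractor_condition()`), and the set of simultaneously attracting
domains — the *configuration* — is what the model can do at a given
parameter set. Every condition compares one of nine rational functions
$q_k(\mu,\gamma,\eta,\kappa,\pi,\epsilon)$ (namely $\mu\pi P^*$ per
symmetric domain and per conjugate asymmetric pair,
`canonical_quantities()`) with the two rescaled thresholds
$\mu\pi\theta_\mathrm{low} < \mu\pi\theta_\mathrm{high}$, and the
thresholds appear nowhere else. The parameter-space arrangement therefore
coarsens exactly to *zone vectors*: assignments of each $q_k$ to
(below the low threshold | between | above the high threshold). A zone
vector is realizable precisely when the grouped ordering
$\max(\text{low group}) < \min(\text{mid group})$,
$\max(\text{mid group}) < \min(\text{high group})$ admits a positive
solution, because the thresholds are free coordinates. This is the exact
disjunctive-normal-form decomposition of the attractor conditions, with
feasibility reduced to ordered-grouping queries over six parameters.

### Admissibility

Because $\eta = K/K_0$ and $\kappa = K/(1+K_0)$ share the binding
constants, every physically realizable parameter set satisfies
$\eta > \kappa$, and conversely every pair $0 < \kappa < \eta$ is
realized. The decomposition runs over this admissible set. The constraint
is substantive: it forces
$w = (1+\gamma)(1+\eta)/(1+\kappa) > 1+\gamma > 1$, which makes "at least
one symmetric domain attracts" a theorem (if $\mu\pi\theta_2 < 1$ and the
mid symmetric state fails, then $1+\gamma \geq \mu\pi\theta_1$ fails or
$w > \mu\pi\theta_1$ holds). Dropping it admits configurations with *no*
symmetric attractor (e.g. the high/low pair alone, realizable at
$\kappa > \eta$), which the two-cell biology cannot produce.

### Feasibility oracle and numerical safeguards

Cell and wall feasibility are decided by a fixed-seed log-uniform witness
pool of $10^5$ points spanning $10^{[-3,3]}$ per base coordinate, with
every unwitnessed one-flip neighbour of a feasible cell retried by
budgeted Nelder–Mead maximization of the minimum relative slack
(declared feasible above $10^{-6}$, flagged inconclusive between
$10^{-8}$ and $10^{-6}$; the shipped catalog has zero flags). The catalog
is deterministic for fixed settings; the pool seed is part of the
algorithm configuration, not a statistical seed.

Two safeguards matter at extreme magnitudes. First, several orderings
among the $q_k$ are provable over the admissible set
($1 < A_1 < A_2 < 1+\gamma < w$ along the equal-transport chain, and the
within-pair and cross-pair orderings of the mixed-transport quantities);
pool rows whose floating-point $q$ vector violates one, or carries a
relative gap below $10^{-7}$, are discarded as cancellation artifacts.
Without this filter, points with $\eta-\kappa$ at relative $10^{-10}$
produce sign-flipped differences and phantom cells that corrupt the
region count; with it the catalog is stable across pool seeds and sizes
(20k–300k all yield the same 203 cells). Second, cells of equal
configuration are glued across codimension-1 walls only when the wall
itself is feasible (the flipped quantity strictly between the remaining
groups), so regions are connected components of the configuration's
feasible set with measure-zero boundaries ignored.

The catalog for $\theta_2 < \theta_1$ contains 203 cells, 40
configurations and 70 regions; `build_region_graph()` links regions
across walls where the configuration changes, giving a 70-node, 165-edge
graph with diameter 9 and 68.9% of unordered pairs within distance 4.
Both threshold orderings are supported; the opposite ordering is built
the same way (`decompose_regions("theta1_lt_theta2")`).

### The bistable-selection region

The region that couples the mid-level symmetric attractor (domain 4) with
the high/low asymmetric pair (domains 2 and 6) is the natural candidate
for robust selection; its representative
$(\theta_1,\theta_2,\mu,\gamma,\eta,\kappa,\pi,\epsilon) =
(1.4, 0.9, 0.8, 0.2, 2.3, 2.5, 1.2, 0.1)$ at $n=\nu=10$ relaxes to a
swap-conjugate pair of asymmetric states from every initial condition
tried. A compact five-inequality chain for this region
(`selection_chain_strings()`) is

$$L_A < \pi\mu\theta_2 < 1, \qquad
  1 < \tfrac{(1+\gamma)(1+\eta)}{1+\kappa} < \pi\mu\theta_1 < L_B,$$

with $L_A, L_B$ the $\mu\pi P^*$ components of the (0,2)-domain fixed
point. The chain is *necessary* for the configuration but not
sufficient: it leaves the (1,2)-pair quantity $C_1$ unconstrained, and
over the admissible set the chain region is exactly the disjoint union of
the $\{2,4,6\}$ region (where $C_1 < \mu\pi\theta_2$; the other branch is
infeasible, making the region singly defined) and the adjacent
$\{2,4,5,6,7\}$ region (where $\mu\pi\theta_2 < C_1 < \mu\pi\theta_1$,
adding the second asymmetric pair). `in_selection_chain()` implements the
chain verbatim, because the chain is the sampling definition
the density study reproduces; the catalog region carries the complete
description.

## Step two: finite-Hill exploration

`find_stable_steady_states()` enumerates the stable states of the smooth
system: 34 initial conditions (a $5\times5$ protein grid at
$\{0.2\theta_\mathrm{lo}, \theta_\mathrm{lo},
(\theta_\mathrm{lo}+\theta_\mathrm{hi})/2, \theta_\mathrm{hi},
2\theta_\mathrm{hi}\}^2$ with $M_i = 1/\mu$, plus the nine sharp-switch
fixed points as seeds), stiff integration with a compiled right-hand side
(`lsoda`, rtol $10^{-8}$, horizon $10^4$ rescaled time units, converged
when $\|f\|_\infty < 10^{-8}$), Newton polishing with the analytic
Jacobian to residual $10^{-10}$, deduplication at relative $10^{-4}$,
stability certification by Jacobian eigenvalue real parts, and closure
under the cell swap. Protein coordinates are clipped at zero before the
Hill terms, which are undefined for the tiny negative excursions adaptive
solvers produce. A state is asymmetric when
$|P_1-P_2| > 10^{-3}\max(P_1, P_2, \theta_2)$ — scale-aware and far below
the separation of genuine symmetry-broken branches. The classifier was
cross-checked against an independent implementation (dense random
multistart root finding with eigenvalue certification) with exact
agreement on every compared sample.

`density_study()` samples a box (default $[0.01, 3]$ per coordinate,
optionally restricted by a region predicate through rejection), runs the
enumeration per accepted set, and reports the proportion of
asymmetric-only sets with full seed provenance. Rare sets where no stable
state is certified within the budget leave the denominator and are
counted separately.

Computed at the reference scales (the acceptance script and test suite rerun
these): sampling 1000 sets from the five-inequality chain at $n=\nu=10$
classifies roughly 26–29% as asymmetric-only depending on seed
(e.g. 284/999 at seed 1), and 2000 box-wide samples yield a handful of
asymmetric-only sets (3 at the first seed tried; about $1.5\times10^{-3}$
overall). Within the chain the two constituent regions differ sharply:
the $\{2,4,6}$ part classifies ~13% asymmetric-only, the
$\{2,4,5,6,7\}$ part ~38%, so the region decomposition — not the chain —
is the informative sampling frame.

## The toy model

A single autocatalytic species $\dot X = b + H(X-\theta) - \gamma X$ has
two phase intervals with fixed points $b/\gamma$ and $(b+1)/\gamma$,
giving exactly three parameter regions: $D_1 = \{b > \gamma\theta\}$
(high state only), $D_2 = \{b < \gamma\theta < b+1\}$ (bistable),
$D_3 = \{b+1 < \gamma\theta\}$ (low only); the empty configuration is
contradictory. The region graph is the path $D_1 - D_2 - D_3$.
`toy_preservation_table()` samples each region in the $[0.01,3]^3$ box
and asks whether the finite-$n$ stable-state pattern (sign-change scan
with bisection, derivative-sign stability) matches the sharp-switch
prediction: $D_1$ and $D_3$ are preserved exactly at $n \in \{5,10,20\}$,
while the bistable window shrinks with decreasing $n$ — computed
proportions ~0.08, 0.22, 0.46 at $n = 5, 10, 20$ (1000 samples per cell).

## What the generator emulates, and limits

- The synthetic sampling emulates uniform exploration of the dimensionless
  box the analysis prescribes; it does not model measurement noise,
  parameter correlations, or the 16-cell cyst geometry (the two-cell
  reduction is the model's own assumption).
- The feasibility oracle is a budgeted numerical search, not a decision
  procedure: cells or walls whose maximal relative slack lies below
  $10^{-6}$ (for example exponentially thin slivers approaching the
  degenerate surface $\eta = \kappa$) are below its resolution. The
  partition, round-trip and adjacency test suites gate the shipped
  catalog.
- Steady-state enumeration certifies only what its 34 starts reach;
  the swap-closure, balance and deep-sharp-limit consistency properties
  (pattern preservation at $n=\nu=50$ on wide-slack parameter sets)
  bound, but cannot eliminate, the risk of missed attractors. Limit
  cycles are not searched for; non-convergent starts are counted and
  excluded.
- Trajectory plots and basin volumes are out of scope; classification
  asks only which stable states exist.

## Problem sizes

The shipped configuration uses a $10^5$-point witness pool for the
catalog (about half a minute), 1000-sample density studies (about a
minute each with the compiled right-hand side), 2000 box samples for the
rarity check, and 1000 samples per toy cell. These sizes keep every
statistic's Monte-Carlo error well inside the tolerances asserted in the
test suite.
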