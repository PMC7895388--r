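# switchmap

Parameter-space mapping for biological switching systems, instantiated on
a two-cell model of oocyte selection in the *Drosophila* germline cyst.

Only one of the two central cells of the fly's 16-cell germline cyst
becomes the oocyte. The selection is driven by Orb, a translational
regulator that promotes its own translation and, by binding its mRNA to
the fusome, withholds it from intercellular exchange — a positive
feedback that can break the symmetry between the two cells. `switchmap`
asks the systems-biology question behind this event: *across the entire
parameter space of the model, where does robust selection live?*

The package answers it in two steps:

1. **Exact sharp-switch decomposition.** Replacing the Hill regulatory
   terms with Heaviside steps makes the dimensionless model

   $$\dot M_i = 1 - \mu M_i - \frac{M_i}{1+\kappa H_1(P_i)}
              + \frac{M_j}{1+\kappa H_1(P_j)}, \qquad
     \dot P_i = (1+\gamma H_2(P_i))\,
              \frac{1+\eta H_1(P_i)}{1+\kappa H_1(P_i)} M_i
              - \pi P_i + \epsilon (P_j - P_i)$$

   piecewise affine on nine phase-space domains. Each domain attracts iff
   its closed-form fixed point lies inside it, which reduces to strict
   inequalities between rational functions of
   $(\mu,\gamma,\eta,\kappa,\pi,\epsilon)$ and the rescaled thresholds
   $\mu\pi\theta_{1,2}$. `decompose_regions()` enumerates all realizable
   attractor configurations and splits parameter space into connected
   regions of constant configuration; `build_region_graph()` computes
   which regions share codimension-1 boundaries.

2. **Region-guided finite-Hill exploration.** With finite exponents
   (default $n=\nu=10$), `find_stable_steady_states()` enumerates the
   stable equilibria from a 34-start initial-condition grid (compiled
   right-hand side, Newton polishing, Jacobian certification) and
   `density_study()` estimates how densely a region supports parameter
   sets whose stable states are *all* asymmetric — the sets that
   guarantee oocyte selection from any starting condition.

A one-dimensional autocatalytic toy model (`toy_params()`,
`toy_preservation_table()`) exercises the identical pipeline in a setting
small enough to verify by hand.

## Worked example

```r
library(switchmap)

catalog <- decompose_regions("theta2_lt_theta1")
catalog
#> <region_catalog> theta2_lt_theta1
#>   203 cells, 40 configurations, 70 regions (0 flagged tests)
#>   pool: 87886 kept of 100000 (seed 20210208, 10^[-3,3]); 60.9 s

stats <- distance_stats(build_region_graph(catalog))
c(stats$diameter, round(stats$frac_le4, 3))
#> [1] 9.000 0.689
```

Parameter space under $\theta_2 < \theta_1$ splits into **70 connected
regions realizing 40 distinct attractor configurations**; the adjacency
graph has **diameter 9**, and over **two thirds of region pairs lie
within distance 4** — qualitatively different dynamical phenotypes are
only a few boundary crossings apart.

```r
p <- dimless_params(mu = 0.8, pi = 1.2, epsilon = 0.1, gamma = 0.2,
                    theta1 = 1.4, theta2 = 0.9, kappa = 2.5, eta = 2.3,
                    n = 10, nu = 10)
find_stable_steady_states(p)
#> <steady_states> 2 stable state(s); class asymmetric_only
#>           M1      M2      P1      P2
#> [1,] 1.57885 0.92115 1.45380 0.88307
#> [2,] 0.92115 1.57885 0.88307 1.45380
```

At this parameter set the only stable states are a swap-conjugate
asymmetric pair: whichever cell starts ahead ends up as the oocyte, and
one of them always does. The set lies in the region whose sharp-switch
configuration couples the mid-level symmetric attractor with the high/low
asymmetric pair — the region `density_study()` shows is far denser in
such "guaranteed selection" parameter sets than the box at large:

```r
density_study(1000, region = in_selection_chain, seed = 1)
#> <density_estimate> region: 284/999 asymmetric-only (prop 0.2843)
#>   exponents n=10 nu=10, seed 1, box [0.01, 3]^8
```

against roughly 1–2 per thousand for unrestricted box sampling.

The toy model's three regions behave the same way under sharpening
(`toy_preservation_table(1000, c(5, 10, 20))`): the monostable regions
are preserved exactly at every exponent, while the bistable window
erodes as the switch softens (~0.08 / 0.22 / 0.46 of it remains at
$n = 5, 10, 20$).

## Package layout

- `R/hill.R`, `R/parameters.R`, `R/models.R` — switch family, parameter
  containers and transformations, model variants (full 6-D, reduced 4-D,
  rescaled, toy).
- `R/domains.R`, `R/decompose.R` — switching domains, affine subsystems,
  closed-form fixed points, attractor conditions, the region catalog.
- `R/graph.R` — region adjacency graph, distance statistics, exports.
- `R/explore.R` — finite-Hill steady-state enumeration, classification,
  density studies, the toy pipeline.
- `src/` — compiled right-hand side of the rescaled model.
- `vignettes/parameter-space-mapping.Rmd` — the methods vignette.
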