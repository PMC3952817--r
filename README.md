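# osfit

Quantitative calibration of mechanistic ODE models against **qualitative
(ordinal) biological data**, with multi-objective treatment of disparate
data categories.

Much of developmental biology's evidence is ordinal: a stained image shows
that pMad is *high* in the stem cell and *low* posteriorly, a mutant has
*spectrosomes* rather than *fusomes* — not concentrations. `osfit` makes such
data quantitatively usable for model fitting:

- **Optimal Scaling fitness.** For a model output `y` over the 1-D germarium
  geometry, each ordinal observation is replaced by *surrogate data* `s`
  constrained to rank-consistent intervals: rank `r`'s interval `[l_r, u_r]`
  must satisfy `u_r − l_r ≥ Δ_min`, `l_{r+1} − u_r ≥ g_min` (with
  `Δ_min = (S/2)·b/N`, `g_min = (S/4)·b/max(N−1,1)`, so minimum ranges and
  gaps never consume more than 75 % of the output scale `S`). Given
  intervals, the optimal surrogate is the clipped model output; the fitness
  is the relative error
  `E = sqrt( Σ_domains mean_i ((y_i − s_i)/(ν + ε))² )`,
  where `ν` is the total variation of `y` (penalizing flat outputs) and
  `ε = 1e-6·S`. The interval selection is a convex inner problem solved per
  model evaluation.
- **A germarium model family.** An 18-compartment line (cap cell + 17
  germline cells: GSC, CB, Cyst 3–9, Posterior 10–17) with Dpp secretion
  from the cap cell, finite-difference diffusion with no-flux ends, receptor
  binding, Mad phosphorylation, and Hill (n = 2) repression networks
  (`core_topology()`: pMad ⊣ Bam ⊣ Nos ⊣ Brat ⊣ pMad; `alt1_topology()`
  drops the feedback edge). Steady state is the 24 h solution from null
  initial conditions; the dynamic protocol shifts zone states posteriorly
  (cell division) and integrates 12 h more, with phenotype read as the
  trailing 6 h mean Brat.
- **Pareto multi-objective estimation.** Wild-Type, Mutant and Behavioral
  observations are separate objectives. A hybrid screen
  (Chebyshev–Gauss–Lobatto sparse grid ≤ 75 % of budget + Latin hypercube)
  feeds multi-start L-BFGS-B anchor searches and a modified Normalized
  Normal Constraint method that traces the front along constraint lines
  normal to the Utopian plane.
- **Downstream analysis.** Finite-difference relative sensitivities,
  exhaustive inhibitory network screening with a parsimony (minimal
  antichain) filter, and model-based experiment design over 210 genetic
  perturbation × measurement candidates (expected-prediction variance,
  Jaccard dissimilarity of prediction sets, within-model prediction
  variance, and sensitivity-based quantitative designs).
- **Synthetic ground truth.** `synthetic_study()` generates ordinal
  observations from a known two-regulator chain so the whole pipeline is
  testable against an achievable perfect fit.

## Worked example

```r
library(osfit)

fx <- packaged_fixture()      # 25 published germarium observations
fx[1:4, 1:6]
#>   index species   condition category dynamic n_categories
#> 1     1 Nos       WT        WildType FALSE              2
#> 2     2 pMad      WT        WildType FALSE              2
#> 3     3 Bam       WT        WildType FALSE              2
#> 4     4 Phenotype WT        WildType FALSE              2

m  <- germarium_model()       # Core network, reference parameters
ov <- evaluate_objectives(m, fx)
glance(ov)
#>   WildType Mutant Behavioral failed
#> 1        0  0.307      0.284 FALSE
```

The reference parameterization satisfies every Wild-Type observation
exactly (`WildType = 0`: an interval assignment exists in which all 17-cell
outputs are rank-consistent) while mutant and behavioral constraints are
violated — the trade-off between data categories that motivates the Pareto
treatment. `fit_representatives(fx, budget = ..., seed = ...)` then screens
parameter space and returns the Representative set (`tidy()` for the table,
`autoplot()` for the front projections); `screen_networks()` and
`design_experiments()` continue the workflow. A thin command-line wrapper
ships at `inst/cli/osfit`.

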