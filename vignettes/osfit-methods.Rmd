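---
title: "Fitting ODE models to ordinal data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting ODE models to ordinal data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`osfit` estimates parameters of mechanistic reaction–diffusion models from
qualitative biological observations. This vignette documents the model, the
Optimal Scaling fitness estimate, the optimization machinery, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The germarium model

The anterior *Drosophila* germarium is represented as a line of ODE
compartments: the somatic cap cell (CC) at the anterior end, then 17
germline cells partitioned as GSC (cell 1), cystoblast (cell 2), Cyst
(cells 3–9) and Posterior (cells 10–17). Per compartment the states are
extracellular Dpp, Dpp–receptor complex, and the intracellular regulators
of the chosen network topology.

* **Dpp transport.** `dD/dt = D∇²D + σ·1[CC] − k_on·D·R_free + k_off·C −
  δ_D·D`, with the Laplacian discretized by central finite differences and
  no-flux (ghost-node) ends. Secretion is restricted to the CC; receptors
  are absent from the CC.
* **Signaling.** Free receptors bind Dpp; the complex is internalized at
  first order. Mad phosphorylation is driven by the complex through a
  saturating Hill term `C²/(k_sig² + C²)` and removed at first order. The
  ligand–receptor layer admits many elaborations; the scheme here is the
  minimal one producing the modeled states (free ligand, bound complex,
  transducer) and is isolated in the model module so a more detailed
  published scheme can be swapped in without touching anything else.
* **Regulation.** Every regulatory edge contributes one Hill factor with
  coefficient 2: `K²/(K² + R²)` for repression, `R²/(K² + R²)` for
  activation. The Core network is the repression chain
  pMad ⊣ Bam ⊣ Nos ⊣ Brat plus Brat ⊣ pMad feedback; Alt1 omits only the
  feedback edge. dMyc is carried as an unconnected species in these
  networks so that conditions perturbing or measuring it remain
  simulatable.
* **Protocols.** "Steady state" is defined operationally as the state after
  24 h of integration from a null initial state (not a root solve), with
  `lsoda`, rtol `1e-6`, atol `1e-9`. The dynamic protocol approximates a
  division/displacement event by setting each zone's intracellular states
  to the mean of its anterior neighbor zone (GSC keeps its own mean),
  then integrates 12 h; the phenotype readout is the per-cell mean Brat
  over the trailing 6 h, mirroring the fusome/spectrosome correlation with
  differentiation. Integration failures are flagged and scored as infinite
  objectives rather than raised, so global screens survive bad corners.
* **Genetic conditions.** Null, heterozygous and doubled genomic content
  multiply a species' production by 0, 0.5 and 2; `Dpp` conditions act on
  secretion, `Rec` on receptor level, `Mad` on the phosphorylation rate.
  Overexpression adds a uniform ectopic production (`oe_rate`), a
  deliberately config-level constant: the true overexpression strength of
  Gal4-type constructs is too uncertain to fit by default. The combination
  null + overexpress on one species encodes a knockout rescued by ectopic
  expression.
* **Reference parameters.** Defaults give O(1) concentrations and
  hour-scale kinetics (production 1 h⁻¹, degradation 0.5 h⁻¹, regulator
  half-max at half the unrepressed level, and a Dpp decay length under one
  cell diameter so signaling is anterior-restricted). Screens draw from
  log-uniform ranges around these values; ranges are config-overridable so
  literature-derived ranges can be substituted where they exist.

## Optimal Scaling fitness

Ordinal data constrain order, not value. For each observation, per-rank
intervals `[l_r, u_r]` are chosen and the observation's cells are assigned
surrogate values inside their rank's interval. Given intervals, the optimal
surrogate is the model output clipped into the interval, which reduces the
problem to choosing `2·N` interval bounds.

* **Error.** Squared relative residuals `((y_i − s_i)/(ν + ε))²` with
  `ν` the total variation of the output across the full 17-cell geometry
  and `ε` a small constant. `ν` makes flat outputs expensive: a model
  cannot cheaply satisfy graded data by flattening. The final error is the
  square root of the sum over observation domains (the observed regions) of
  each domain's mean cell error, so a 7-cell region and a 1-cell region
  weigh equally. Whether `ε` should be absolute or scale-relative is not
  determined by the formulation; we use `ε = 1e-6·S` so the whole estimate
  is exactly scale invariant (verified by a property test).
* **Category aggregation.** Each category's objective is
  `sqrt(Σ_obs error_obs²)` — the per-observation root is taken first, and
  categories aggregate observation-wise. The alternative reading (one
  root over the pooled sum) differs only monotonically per observation; the
  convention is fixed here and used consistently.
* **Minimum ranges and gaps.** Detectable ordinal differences imply a
  finite resolution, but the assays' sensitivities are unknown. The
  heuristic `Δ_min = (S/2)·b/N`, `g_min = (S/4)·b/max(N−1, 1)` with budget
  `b = 0.75` keeps intervals from collapsing while guaranteeing that `N`
  ranges plus `N−1` gaps consume at most `0.75·b·S ≤ 75 %` of the scale for
  every `N` — the bound the acceptance script reports.
* **Solver.** With surrogates eliminated, the inner problem is *convex* in
  the bounds (clipping residuals are maxima of affine functions, squared),
  solved in slack coordinates (lowest bound, extra widths, extra gaps) by
  L-BFGS-B from deterministic starts (a greedy minimal-span construction,
  rank-wise quantiles, a compressed placement, and the best point of a
  small vectorized lattice when the dimension permits). When a
  rank-consistent assignment exists, the greedy construction returns the
  exact zero-error solution directly; ties between optimal interval sets
  are broken toward the smallest total span, then lexicographically
  smallest bounds. Bounds are capped at `max(y)` plus the total mandatory
  span plus `Δ_min`: a tighter cap at `max(y) + Δ_min` is *not* neutral,
  because the width and gap constraints can push the top interval's bounds
  past `max(y)` at error-balancing optima — a fact discovered when a
  tighter cap made the solver and the brute-force oracle disagree.
* **Oracle.** `solve_scaling_oracle()` is an independent nested-grid
  search over the raw bounds with pattern-search contraction (the radius
  halves only when no improving move is found). The acceptance suite
  checks solver/oracle agreement to 1e-3 relative on 100 random small
  instances and that zero-error cases coincide exactly with a direct
  feasibility check.

## Search and the Pareto front

All parameter search runs in log10 space. The global screen allocates at
most 75 % of its budget to a nested Chebyshev–Gauss–Lobatto sparse grid
(level chosen automatically from budget and dimension; skipped entirely
when even the coarsest level exceeds the cap) and the rest to a seeded
Latin hypercube. Anchor points minimize one category objective each by
multi-start L-BFGS-B (numerical gradients, strict bounds) from the best
screened samples; one screen serves all anchors.

The front is traced with a modified Normalized Normal Constraint method.
In the objective space normalized by the anchors, an even barycentric
lattice on the Utopian plane defines constraint lines along the common
inward normal. Each line's search minimizes progress along the normal with
the on-line condition enforced as a quadratic penalty (weight `1e4`) —
equality constraints on nonconvex objectives are fragile, a penalty is
robust and keeps residuals at the `1e-6`–`1e-3` level in normalized units
on the analytic test problem. Searches are seeded by a quadratic response
surface fitted to the sparse-grid samples, at the plane point and at
fractions {0.25, 0.5, 0.75} of the constraint vector — several inward
offsets guard against gradient searches settling in local minima along a
constraint line. Desk-scale defaults
are a 2,000-point screen, 8 starts, 7 lattice points per edge for two
objectives and 5 for three; a cluster-scale preset (500 k samples, 64
starts) is reachable through the same configuration objects. Solutions plus anchors are filtered for Pareto optimality
(weak-dominance filter, duplicates dropped keeping the first) and
deduplicated in parameter space at 1e-6 log-units. When all anchors
coincide (e.g. a noiseless synthetic study where one parameter set
satisfies everything), the front is that single point and the constraint
searches are skipped.

## Network screening and experiment design

The naive inhibitory screen enumerates all subsets of the 12 possible
repression edges among the four regulators. Each topology is scored by its
best Wild-Type error over an exhaustive strong/weak lattice — every edge's
`K` at 0.1× or 10× the regulator's unrepressed level. "Weak" is nearly but
not exactly an absent edge (a 10× half-max still represses ~1 %), so the
monotonicity of best error under edge addition holds only up to that
approximation; the test suite asserts it with a small allowance. The
acceptance threshold (default `E_WT ≤ 0.05`) and the strong/weak levels
are config values chosen once and documented here. Accepted topologies
pass a parsimony filter keeping the minimal antichain under edge-set
inclusion; for four regulators the full enumeration is 2¹² = 4,096
topologies.

Experiment design enumerates single and pairwise perturbations
({null, heterozygous, doubled} on {Dpp, Rec, Mad, Bam, Nos, Brat, dMyc};
21 + 189 = 210 conditions) crossed with measured species. Qualitative
predictions discretize each simulated output to the binary region labeling
with minimal Optimal Scaling error (ties toward fewer high regions);
expected predictions are per-region medians over Representatives with ties
to low. Discrimination is scored by the variance over models of expected
predictions and by summed pairwise Jaccard dissimilarity of prediction
sets (`1 − (M_jk + M_kj)/(R_j + R_k)`, counts over Representatives, so
duplicated Representatives re-weight the index as the count-based
definition implies); refinement by within-model prediction variance.
Variances are population variances, since Representative counts differ per
model. Quantitative designs aggregate relative sensitivities (forward
differences, default step 1 %) by Representative means or variances, with
cells aggregated by region means summed.

## The synthetic-data generator

`synthetic_study()` provides ground truth: a two-regulator chain
(pMad ⊣ Bam ⊣ Nos) in the standard geometry, observed under Wild Type
(steady + dynamic) and a Bam knockout, with four free parameters (two
regulatory half-maxima, two production rates) and log10 bounds ±1.5 decades
around the truth. Region ranks come from quantile thresholds of the
Wild-Type output; regions whose cells straddle the rank structure are
masked, as a curator reports only regions with a clear level — masking is
applied *before* optional rank-flip noise so noise is never repaired away.
The construction guarantees that the true parameters score exactly
(0, 0, 0), giving the pipeline an absolute floor: the acceptance suite
demands a Representative with all category objectives below 0.01 at desk
budget. What passing does **not** show: real curated data have no
guaranteed zero-error parameter set, inter-laboratory scale differences are
modeled only through per-observation scaling, and the generator's
threshold-based ranks are cleaner than human interpretations of images.

## Known limitations

One-dimensional geometry; no cyst connectivity or cell-contact mechanisms;
steady state by finite-horizon integration (slow modes slower than ~24 h
are truncated by design); local (not global) sensitivity; the desk-scale
defaults trade front density for runtime — problem sizes used by the test
suite are a 2,000-sample screen with 8 starts on the four-parameter
synthetic study, and analytic or few-cell instances elsewhere.
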