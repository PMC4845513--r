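---
title: "How biomass composition and model structure shape flux-balance predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How biomass composition and model structure shape flux-balance predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoflux)
```

## The modeling problem

Genome-scale stoichiometric models predict metabolic fluxes by linear
programming: flux balance analysis (FBA) maximizes the flux through a biomass
pseudo-reaction subject to steady-state mass balance and flux bounds,

$$\max_v \; v_\mathrm{growth} \quad \text{s.t.} \quad S v = 0, \quad
v_\mathrm{min} \le v \le v_\mathrm{max},$$

where $S$ is the stoichiometric matrix and the biomass reaction consumes each
precursor metabolite $X_i$ with coefficient $c_i$ (mmol per gram dry weight)
plus a growth-associated maintenance (GAM) cost in ATP. Two modeling inputs
are notoriously uncertain, especially for plant models where biomass data is
often borrowed across tissues or species: the biomass composition (the
$c_i$), and the network structure itself. This package provides the machinery
to quantify how much either one moves the predictions: a model-by-composition
scenario matrix with flux dispersion statistics, flux variability analysis
(FVA) with an overlap classification, single-component ±30% perturbation
scans, maintenance-configuration scans, and correlations between growth-rate
changes and coefficient size.

Everything is testable without external downloads through a synthetic-network
generator whose optima are known in closed form.

## The constraint-based engine

### Plain FBA and FVA

`solve_fba()` maximizes the objective flux. Infeasibility (for instance a
maintenance drain that the nutrient supply cannot cover) is reported as a
status, not an error, because scenario scans must continue past infeasible
cells. When the optimum is degenerate — parallel pathways are the canonical
cause — the individual fluxes of the returned solution are arbitrary vertex
coordinates; only the objective value is meaningful, and the package's tests
never compare individual fluxes of a plain FBA solution.

`flux_variability()` reports, per reaction, the minimum and maximum flux
attainable while the objective is held at its optimum. The optimum is imposed
as an equality (within $10^{-9}$) rather than a $\ge$ cut, so the ranges
describe exactly the optimal face. An `optimum_fraction < 1` relaxes this to
a one-sided cut.

### Geometric FBA

`geometric_fba()` removes the degeneracy by returning the flux distribution
central to the optimal face. The iteration is: (i) compute FVA ranges over
the current face; (ii) take range midpoints $m$ and solve an L1 projection
$\min \sum_r |v_r - m_r|$ over the face; (iii) contract each reaction's range
to its reach within the *set of L1-optimal solutions* (an added budget
constraint $\sum_r |v_r - m_r| \le D^\*$), and repeat until every range is
narrower than `tol`.

The budget step matters: when three or more routes are interchangeable the L1
projection itself has ties, and a simplex solver would return an arbitrary
symmetry-breaking vertex. Constraining the follow-up range computation to the
L1-optimal set collapses every range at once when the midpoint is feasible
($D^\*=0$) and halves open ranges symmetrically otherwise, so the result is
invariant to reaction ordering and splits $n$ interchangeable pathways as
exactly $1/n$ each (verified for $n = 2,3,4$). Defaults: `tol = 1e-6`,
`max_iter = 50`; non-convergence is an error carrying the open reaction
count, never a silently uncentered result.

### Numerical conventions

* Non-finite bounds are clamped to ±1000 flux units when reactions are added,
  so every LP is bounded. This is a unit convention, not physics; analyses
  whose fluxes approach the cap (for example an extreme GAM on a tiny
  network) measure the cap, and the toy-scale tests therefore use toy-scale
  maintenance values.
* The LP backend solves $\min/\max\; c^\top v$ subject to equalities,
  inequalities, and variable bounds. Before the simplex runs, variables fixed
  by equal bounds are eliminated, equality rows pinned to a single remaining
  variable are propagated (which also removes most degeneracy), all-zero rows
  are checked for consistency and dropped, and linearly dependent balance
  rows — conserved moiety pairs such as a two-carrier loop — are removed by a
  rank computation on the transposed system.
* Feasibility tolerance is $10^{-7}$ on $|Sv|$; steady state of every
  returned optimum is asserted at $10^{-6}$ in the tests.

## Biomass compositions

A `biomass_composition` is a tibble of components with coefficients
(mmol/gDW), macromolecule classes, molecular weights, and carbon counts; GAM
is an attribute, *not* a component, so swapping compositions between models
never changes the maintenance cost. The key operations:

* `normalize_by_weight()` rescales all coefficients by one factor so that one
  flux unit of biomass consumes exactly 1 g of precursors
  ($\sum_i c_i \mathrm{MW}_i / 1000 = 1$). This reconciles compositions
  published in different unit conventions before they are compared. The
  operation is idempotent and scale-invariant.
* `intersect_components()` restricts comparisons to components *producible*
  in every model (positive maximal export flux under the scenario's nutrient
  constraints), reporting per model which components were excluded — models
  legitimately differ in which precursors they can synthesize.
* `perturb_component()` multiplies a single coefficient, deliberately
  *without* renormalizing: the scientific question is how growth responds to
  more or less of one precursor per biomass unit, with the rest unchanged.
  One flux unit of biomass then no longer weighs exactly 1 g; `bof_mass()`
  reports the effective mass so downstream yield conversions stay honest.

## The scenario matrix and its statistics

`run_matrix()` crosses every model with every composition under a common
constraint set (one bounded carbon uptake, open N/S/P exchanges, fixed NGAM,
shared GAM), naming scenarios `<model>-<BOF>` and flagging each model's own
composition as its reference scenario. Each cell is solved by geometric FBA
so fluxes are comparable across cells.

Dispersion is summarized as the per-reaction standard deviation of central
fluxes across the scenarios of a group — sharing a composition across models
(the structure axis) or sharing a model across compositions (the composition
axis) — followed by the median over reactions. The sample SD ($n-1$
denominator) is the default because groups are small (three scenarios); with
$n = 3$ the sample/population distinction is material, so it is surfaced as
an option rather than hidden.

FVA ranges are classified per reaction as `non_overlapping` only when the
intervals are pairwise disjoint across *all* compared scenarios, with
touching endpoints counted as overlapping. The criterion is conservative by
design — one overlapping pair means the prediction difference is not robust —
and the per-pair detail is attached for inspection.

## Sensitivity analyses

`component_sensitivity()` varies each coefficient independently by 0.7× and
1.3× (the conventional ±30% band for biomass uncertainty) against one
reference optimum. Demand monotonicity — raising any coefficient can never
raise growth, since the feasible set per biomass unit shrinks — is asserted
property-style across seeded random networks.

`maintenance_scan()` solves the four maintenance configurations (none, GAM
only, NGAM only, both) and reports percent differences against the full
configuration. When no configuration changes growth the model is flagged
maintenance-insensitive: the signature of an energy-generating futile cycle,
which the synthetic generator can graft onto any toy network for testing.

`growth_coefficient_correlation()` computes the Pearson correlation between
the magnitude of growth changes (up and down records pooled) and each
component's fractional coefficient in carbon-atom or weight terms. Pooling
magnitudes is the primary output because up/down perturbations move growth in
opposite directions by construction; the signed correlation is emitted
alongside for transparency. Zero variance on either axis yields an explicit
"undefined" flag — never a silent 0. When molecular weights are proportional
to carbon counts the two bases coincide exactly, a limit the tests pin down.

## What the synthetic networks do and do not emulate

`make_toy()` builds the smallest network with the structure the analysis
targets: a bounded substrate uptake, $n$ parallel catabolic routes converting
substrate to an ATP-like energy currency (parallelism makes the optimum
degenerate on purpose), a fixed maintenance drain, and a two-component
biomass reaction. Its optimum is known in closed form,

$$v^* = \frac{y\,u - m}{y\,c_G + c_E},$$

with yield $y$, uptake $u$, maintenance $m$ — e.g. $(3 \cdot 10 - 2)/(3
\cdot 0.5 + 1) = 11.2$ for the default toy — so every pipeline stage can be
checked against hand arithmetic, and `solve_fba()` is additionally checked
against a brute-force vertex-enumeration oracle on 100 seeded random toys.

The toys deliberately do not emulate: compartmentalization, cofactor
stoichiometry (the energy currency is lumped, so GAM hydrolysis products are
optional), element balance (formulas are omitted by default; the audit in
`validate_model()` is opt-in), or the 500–3500-reaction scale of published
genome-scale models. Passing tests therefore demonstrate the correctness of
the algorithms and statistics, not the biological conclusions one would draw
from real models — those require the published SBML models and their
curation patches, which this package consumes via `read_sbml()` and
`apply_model_patch()` but does not ship.

Random toys and compositions are seeded per draw (`random_toy_spec(seed)`,
`make_random_composition(n, seed = )`); no function touches the global RNG
state.

## Problem sizes

The shipped test suite and the acceptance script run entirely on networks of
5–15 reactions: 100-network oracle and analytic sweeps, a 3×3 scenario
matrix over structurally distinct toys, 25–200-component compositions for the
normalization properties, and a five-precursor network whose synthesis costs
scale with carbon content for the correlation analysis. These sizes keep
every quantity exactly checkable while exercising the same code paths a
genome-scale model would.

## Known limitations

* The LP layer targets small dense problems; genome-scale models (thousands
  of reactions) would need a sparse large-scale solver behind the same
  `solve_lp()` contract.
* No thermodynamic (loopless) constraints: futile cycles are *detected* via
  maintenance insensitivity, not removed.
* Gene–protein–reaction rules, annotations, and model curation beyond
  declarative bound/direction patches are out of scope.
* SBML support covers the constraint-based skeleton (species, reactions,
  bounds in fbc or kinetic-law encodings, one active objective); kinetics and
  units are ignored on read and not written.
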