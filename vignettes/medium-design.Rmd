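---
title: "Multiobjective Bayesian design of growth media over genome-scale metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiobjective Bayesian design of growth media over genome-scale metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmedia)
```

## The problem and the model

Culture-medium composition determines how fast a production strain grows,
how much product it makes, and what the medium costs — three goals that
usually conflict. `fluxmedia` treats medium design as a bi-level
optimization. The inner level is flux balance analysis (FBA) over a
genome-scale metabolic model (GEM): with stoichiometric matrix $S$
($m$ metabolites $\times$ $n$ reactions) and flux vector $v$,

$$v^\* = \arg\max_v \; c'v
\quad \text{s.t.} \quad S v = 0,\;
v_i^{\min} \le v_i \le v_i^{\max} \ (i \in I_{\mathrm{int}}),\;
0 \le v_i \le v_i^{\max} \ (i \in I_{\mathrm{ext}}),$$

where $I_{\mathrm{int}}$ and $I_{\mathrm{ext}}$ index internal and
nutrient-import (exchange) reactions, and the weight vector $c$ mixes the
biomass reaction with an optional production flux (e.g. 99:1 or 95:5
ratios via `make_combined_objective()`). A nutrient absent from the medium
has $v_i^{\max} = 0$.

The outer level tunes the upper bounds of a chosen subset
$I_{\mathrm{ext}}^{\mathrm{opt}} \subseteq I_{\mathrm{ext}}$ of imports —
the medium composition — to jointly maximize

$$f_{\mathrm{prod}}(v^\*), \quad f_{\mathrm{growth}}(v^\*), \quad
-f_{\mathrm{cost}}(v_{\max}), \qquad
f_{\mathrm{cost}} = z' v_{\max},$$

where $z$ prices each supplied bound. Cost deliberately depends only on
what is *supplied*, never on what the cell actually consumes. Because each
outer evaluation needs an LP solve and the design space has 10–13
dimensions in realistic campaigns, the outer search uses multiobjective
Bayesian optimization rather than gradients: independent Gaussian-process
(GP) surrogates per objective, collapsed by a random-weight augmented
Chebyshev scalarization

$$s(y; w) = \min_j (w_j y_j) + \rho \sum_j w_j y_j,$$

and a log-expected-improvement acquisition maximized over the unit box
(`run_mobo()`). Non-dominated samples form the Pareto front from which a
designer picks a preferred trade-off.

## Sign and unit conventions

* **Exchange orientation.** Model files follow the community convention of
  uptake as *negative* flux through a metabolite-consuming boundary
  reaction. Internally every import is re-oriented uptake-positive so the
  medium is encoded purely by upper bounds $0 \le v_i \le v_i^{\max}$ and
  the optimizer's box is non-negative; `write_gem()` translates back, so
  files round-trip exactly.
* **Concentration to flux.** Laboratory media are specified in mM; GEM
  bounds are mmol/gDW/h. `concentration_to_flux()` multiplies by a supply
  factor, default 0.5 l/gDW, calibrated so that 20 mM glucose maps to an
  uptake bound of 10 mmol/gDW/h — the bound that reproduces realistic
  wild-type *E. coli* growth given doubling times of 42 ± 12 min
  (`doubling_time_to_growth()`: 0.77–1.39 per hour). Read literally as
  "0.5 l of medium per gDW over a 24-h supply period" the dimensions give
  a per-day amount rather than an hourly rate; the package implements the
  numeric mapping (bound = concentration × 0.5) that the calibration
  actually uses and leaves the supply-period interpretation to this
  paragraph.
* **Sinks** (forced product drains, e.g. a lipopeptide sink with lower
  bound $10^{-4}$ mmol/gDW/h) are boundary reactions but are never medium
  decision variables, so the optimizer cannot relax a production floor by
  buying it in the medium.

## Normalization and orientation of objectives

GPs are fit on `[0, 1]`-scaled inputs ($v_{\max}$ divided by the search
box) and oriented objectives: production and cost are min–max scaled over
the *full accumulated dataset* (constants recomputed every iteration, not
frozen at initialization), cost is inverted as $1 - \text{scaled}$ so all
objectives are maximized, and growth passes through untouched when its
observed range already lies in `[0, 1]` (it is min–max scaled, with a
warning, otherwise). Min–max scaling is monotone, so weak dominance — and
hence the Pareto front — is unchanged by the transformation. Two
conventions deserve a note:

* A **constant objective column** maps to 0.5, the center of the unit
  interval, so a degenerate dimension neither attracts nor repels the
  Chebyshev scalarization.
* An **infeasible medium** scores growth = production = 0 while cost is
  still charged. The optimizer therefore sees infeasibility as a strong
  penalty and learns to avoid the region, but the raw solver status is
  retained in the dataset; low-growth samples are removed only by the
  plot-level `filter_low_growth()` view (default threshold 0.001 per
  hour), never from the data.

## The optimizer, step by step

1. **Initialization:** `n_init` media uniform on the box (default 50),
   projected onto any equality constraints; all randomness flows from one
   master seed through named substreams (initialization, per-candidate
   scalarization weights, acquisition screens), so adding a feature never
   silently shifts another stream and runs are byte-reproducible.
2. **Surrogates:** one GP per objective — Matérn-5/2 kernel with
   per-dimension lengthscales, constant mean, Gaussian noise —
   hyperparameters refit from scratch each iteration by L-BFGS-B on the log
   marginal likelihood (warm-starting is available as `refit_gp = FALSE`
   but is not the default). Cholesky factorizations escalate jitter before
   failing.
3. **Acquisition:** for each of the `batch_size` candidates an independent
   weight vector is drawn uniformly from the probability simplex, the GP
   posteriors are collapsed through the scalarization linearized at the
   posterior mean (delta method: the variance combines per-objective
   variances through the active minimum term plus the $\rho$ augmentation),
   and log-expected improvement is maximized by a random screen of
   `raw_samples` points followed by L-BFGS-B refinement from the best
   `acquisition_restarts`. Earlier candidates in a batch condition later
   ones through fantasy observations at the posterior mean (sequential
   greedy rather than joint optimization: cheaper and order-deterministic).
4. **Evaluation and accumulation:** candidates are de-normalized, applied
   with `apply_medium()`, solved by FBA or parsimonious FBA, and appended;
   the dataset size is exactly `n_init + n_iter * batch_size`.
5. **Restarts:** `restart_from_pareto()` seeds a new run with *every*
   front member of the previous run (no truncation rule is imposed when
   the front exceeds `n_init`), padded with fresh random media — useful
   when a single run under-covers the front, as happens for products whose
   precursors draw on many densely connected pathways.

Defaults worth knowing: $\rho = 0.05$ (the augmentation coefficient is not
pinned down by any external reference; 0.05 keeps the scalarization
Pareto-compliant while still rewarding aggregate improvement),
`raw_samples = 64`, `acquisition_restarts = 4`. Weight vectors are drawn
per candidate, not per batch.

## Constraints

Linear constraints among decision variables (fixed formulation couplings,
solubility caps expressible linearly) participate directly: equalities by
projection onto the affine subspace alternated with box clipping,
inequalities by rejection at initialization and post-projection screening
at proposal time; proposals satisfy them to $10^{-6}$ in unit-box
coordinates. Nonlinear constraints can be supplied as predicates on the
evaluator side but do not steer the acquisition optimizer.

## The inner solvers

FBA LPs are solved by a dense two-phase primal simplex written for this
package (no LP backend is available in the target environment; the one
candidate, `boot::simplex`, fails with an internal error on valid
degenerate inputs). The solver uses Bland's-rule tie-breaking to preclude
cycling, reports `infeasible`/`unbounded` statuses explicitly (naming a
ray member when unbounded), and is validated against brute-force vertex
enumeration of the flux polytope to $10^{-9}$ relative error in the test
suite. Feasibility/optimality tolerances default to $10^{-9}$.

Plain FBA returns whichever optimal vertex the pivoting reaches; FBA
optima are generically non-unique. `solve_pfba()` provides the
parsimonious representative: stage one solves FBA, stage two fixes
$c'v \ge (1-\texttt{tol}) \cdot \text{optimum}$ — an inequality rather
than an equality, so round-off cannot render stage two infeasible — and
minimizes total absolute flux via reversible-reaction splitting. Note the
consequence: stage two will spend its whole tolerance if doing so saves
flux, so pFBA objectives sit at the floor, not at the FBA optimum.

## What the synthetic models do and do not emulate

`make_toy_gem()` builds mass-balanced networks in which biomass flux is
exactly $\min_i(u_i / a_i)$ over uptakes $u_i$ with demands $a_i$,
optionally with a product branch competing for one precursor (flux
conservation then gives the exact growth/production trade-off on the
shared nutrient). Every generated model carries a closed-form optimum
evaluated independently of the LP, and `brute_force_pareto()` supplies
grid-enumeration reference fronts (inclusive endpoints, so the all-zero
and all-max corners are always present). These fixtures reproduce the
*structure* of the design problem — competing linear objectives over a
box, degenerate optima, infeasible corners — at desk scale. They do not
emulate the pathway redundancy, cofactor coupling, or maintenance costs of
a real reconstruction, so a green test establishes the optimizer and
solvers are correct, not that any particular organism-scale prediction is
accurate. Genome-scale checks (growth of *E. coli* near 0.85/h at a
glucose uptake bound of 10) require downloading the published model and
live in `scripts/case_study_bigg.R`.

In the surfactin case-study skeleton the published component list names
twelve species while stating thirteen decision variables; the package
resolves the discrepancy by carrying iron in both oxidation states
(ferric and ferrous exchanges are distinct reactions in these
reconstructions), which restores the stated count and is flagged in the
emitted configuration. Shipped prices are unit placeholders, not vendor
quotes, and are marked as such.

## Sensitivity analysis

`perturb_pareto()` samples compositions from an isotropic normal centered
on each front member in box-normalized coordinates (sigma as a fraction of
the box, default grid 0.01/0.05/0.1), clips to the box, evaluates, and
classifies each perturbation by dominance against the existing front:
*inward* if dominated, *outside-envelope* if non-dominated. A geometric
envelope test would be an alternative reading of "outside the solution
envelope"; dominance was chosen because it needs no front interpolation
and agrees with the Pareto machinery used everywhere else. On concave
reference fronts the inward fraction grows with sigma — most perturbations
of an optimal medium are suboptimal — while outside-envelope points flag
locally under-resolved stretches of the front worth refining with a
restart.

## Known limitations

* The simplex is dense and intended for desk-scale fixtures and mid-size
  models; genome-scale LPs solve but take seconds, so long genome-scale
  campaigns should budget accordingly.
* Expected improvement uses a delta-method Gaussian approximation of the
  scalarized posterior rather than Monte-Carlo sampling of the joint GP.
* Hypervolume is exact only in two objectives (Monte Carlo beyond) and is
  a test diagnostic, not a method output.
* No pH/buffering chemistry, solubility databases, or bulk-pricing curves:
  these enter only through user-supplied constraints or price tables.
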