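# fluxmedia

Computational design of growth media for microbial production strains.
`fluxmedia` wraps flux balance analysis (FBA) of a genome-scale metabolic
model (GEM) inside a multiobjective Bayesian optimization loop and searches
the space of nutrient-import bounds for Pareto-optimal trade-offs between
growth rate, production flux, and medium cost. It is aimed at metabolic
engineers and bioprocess developers who have a curated GEM of their host
and want candidate medium formulations — which components matter, which can
be cut, and what each trade-off costs — before committing to wet-lab
screening.

## The method

The inner problem is standard FBA. With stoichiometric matrix **S** and
flux vector **v**,

    v* = argmax_v c'v   s.t.  S v = 0,
         v_i_min <= v_i <= v_i_max   (internal reactions, I_int)
         0 <= v_i <= v_i_max         (nutrient imports, I_ext)

where **c** weights the biomass reaction and optionally a production flux
(ratios like 99:1 or 95:5 via `make_combined_objective()`). The outer
problem tunes the import upper bounds of the chosen decision variables
`I_ext_opt ⊆ I_ext` — the medium — to maximize the objective vector

    ( f_prod(v*),  f_growth(v*),  −f_cost(v_max) ),   f_cost = z' v_max

with **z** a per-component price vector; cost depends only on what is
supplied, never on the flux solution. The outer search is Bayesian:
independent Gaussian-process surrogates per objective on the unit box
(Matérn-5/2, per-dimension lengthscales), random-weight augmented Chebyshev
scalarization `min_j(w_j y_j) + ρ Σ_j w_j y_j`, and batched
log-expected-improvement acquisition with sequential fantasy conditioning.
Production and cost are min–max normalized over the accumulated dataset
(cost inverted so everything is maximized); infeasible media are penalized
with zero growth/production while still being charged their cost.
A parsimonious FBA solver (`solve_pfba()`), linear constraints among
components, Pareto-seeded restarts, composition PCA, per-component front
distributions, and perturbation-based sensitivity analysis round out the
pipeline. The methods vignette (`vignettes/medium-design.Rmd`) documents
conventions, defaults, and limitations.

Models are read from SBML Level 3 (fbc flux bounds) or BiGG-style JSON
(`read_gem()`); exchange reactions are re-oriented uptake-positive
internally and translated back on write, so files round-trip exactly.

## Worked example

A two-nutrient synthetic model with known optima: biomass consumes one
unit of nutrient 1 and two of nutrient 2, so growth = min(u1, u2/2) and
cost = u1 + 0.5·u2 per unit supplied.

```r
library(fluxmedia)

toy <- make_toy_gem(toy_gem_spec(2, demands = c(1, 2), prices = c(1, 0.5),
                                 box_upper = c(10, 10)))
cfg <- optimization_config(n_init = 20, n_iter = 10, batch_size = 5, seed = 1)
ds  <- run_mobo(toy$model, toy$medium, toy$prices,
                objectives = c("growth", "cost"), config = cfg)
ds
#> sample_dataset: 70 samples, 2 decision variables, objectives: growth/cost
#>   iterations 0..10; feasible: 70/70

front <- pareto_front(ds)
front
#> pareto_front: 25 members over objectives growth/cost

best <- best_ratio_trace(ds, "growth", "cost")
max(best$best_so_far)
#> [1] 0.499

component_distributions(front, toy$medium)
#>   component min   q25 median   q75  max   iqr tight
#> 1     EX_N1   0 0.156  0.291 0.414 0.51 0.258 FALSE
#> 2     EX_N2   0 0.401  0.601 0.827 1.00 0.426 FALSE
```

The 70 evaluated media (20 random + 10 iterations × batch 5) yield a
25-member front. The best growth-per-cost ratio, 0.499, matches the
analytic optimum: efficient media satisfy u1 = u2/2, giving growth/cost
= u1/(2·u1) = 0.5. The component summary shows both nutrients spanning
wide box-normalized ranges across the front — the front trades total
supply against cost rather than pinning either component.

Case-study configuration skeletons for the published campaigns
(M9-grown *E. coli*, antibody-fragment production with amino acid
supplementation, surfactin production in *B. subtilis*) are emitted by
`make_case_study_config()`; their prices are placeholders to be replaced
with vendor quotes. `scripts/case_study_bigg.R` (network required)
downloads iML1515 and checks the genome-scale growth calibration.

## Command line

`inst/cli/fluxmedia.R` wires YAML run configurations to the pipeline:

```sh
Rscript inst/cli/fluxmedia.R run --config run.yaml --seed 7 --out runs/demo
Rscript inst/cli/fluxmedia.R report runs/demo
Rscript inst/cli/fluxmedia.R sensitivity runs/demo --sigma 0.01,0.05,0.1 --n 100
Rscript inst/cli/fluxmedia.R toy --case synthetic --out .
```

Each run writes `samples.csv`, `front.csv`, and a `manifest.json` (config,
seed, model checksum) sufficient to re-launch an identical run; fixed
seeds reproduce artifacts byte-for-byte.

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline end to end from scratch: the
unit-conversion calibration (doubling time → growth rate, concentration →
flux bound), a seeded optimization of the synthetic growth/cost model
compared against a brute-force grid front, and the perturbation
sensitivity analysis around the resulting Pareto front.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
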