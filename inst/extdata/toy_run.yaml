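# Minimal self-contained run configuration: a 2-nutrient synthetic model
# with known growth/cost trade-offs, optimized for growth vs. medium cost.
model:
  toy:
    n_nutrients: 2
    demands: [1.0, 2.0]
    prices: [1.0, 0.5]
    box_upper: [10.0, 10.0]
objectives: [growth, cost]
run:
  n_init: 8
  n_iter: 3
  batch_size: 3
  seed: 1
  rho: 0.05
  solver: fba
out: fluxmedia_toy_run
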