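# reactbo

Batch Bayesian optimization of continuous reaction conditions — substrate
and enzyme concentrations, pH, cosolvent fraction, cofactor loading —
against a figure of merit (FoM) such as the total turnover number (TON).
Built for bench scientists running iterative screening campaigns where every
data point is an experiment: the package proposes the next handful of
conditions, you run them, record the results in a CSV ledger, and iterate.

## The method

A Gaussian-process surrogate (Matérn-5/2 kernel, per-variable lengthscales,
multi-restart marginal-likelihood fitting) models the FoM over a feasible
candidate grid, respecting linear constraints such as
`28.6·[NH₄⁺] + 2·[DMSO] + 2.1·[enzyme] < 200`. Candidates are scored by
expected improvement

> EI(x) = (μ(x) − f⁺ − ξ)·Φ(Z) + σ(x)·ϕ(Z),  Z = (μ(x) − f⁺ − ξ)/σ(x),
> ξ = 0.01,

where f⁺ is the best measured FoM so far. Batches of 5 are assembled with
the Kriging-believer heuristic, with two exploration-biased variants:

* **BOA-1** — before each pick, every grid candidate within a standardized
  Euclidean distance of 1.0 from any measured point or batch-mate is
  excluded, spreading the batch across the hyperspace;
* **BOA-2** — EI evaluated with σ² in place of σ, on a response rescaled so
  its maximum is 10, emphasizing unexplored high-uncertainty regions early
  and decaying to plain EI as data accumulate.

A second FoM (e.g. chemoselectivity) can constrain the search via a
probability-of-feasibility factor `EI(x)·Φ((μ′(x) − threshold)/σ′(x))`.
A face-centred central-composite-design + quadratic-surface baseline (29
runs for 5 factors, 47 for 6) represents the classical single-iteration RSM
alternative, and a mechanistic synthetic enzyme simulator (substrate
saturation/inhibition, pH optimum, cosolvent inactivation, enzyme-loading
dilution, TON–selectivity trade-off) provides ground-truth surfaces for
closed-loop benchmarking.

## Worked example

A closed-loop campaign on the shipped `pal5` synthetic surface (an
ammonia-lyase-like system with a reagent-solubility constraint):

```r
library(reactbo)

preset <- enzyme_preset("pal5")
print(preset$space)
#> Design space: 5 variable(s), 1 constraint(s)
#>   cinnamate    [10, 100] mM  (7 levels)
#>   NH4          [1, 6] M  (7 levels)
#>   PAL          [1, 20] uM  (7 levels)
#>   pH           [7, 10]   (7 levels)
#>   DMSO         [5, 30] %  (7 levels)
#>   s.t. 28.6*NH4 + 2*DMSO + 2.1*PAL < 200

cfg <- campaign_config(strategy = "boa1", n_iterations = 3, seed = 42)
camp <- run_closed_loop(preset$space, preset_oracle(preset), cfg)
summary(camp)
#> Campaign summary (strategy 'boa1', FoM 'TON')
#>  iteration n_measured best_so_far
#>          0          5    195.1428
#>          1          5    475.9548
#>          2          5    475.9548
#>          3          5   1172.3770
#> Best measured condition:
#>  cinnamate NH4 PAL  pH DMSO      TON iteration   source
#>        100   6   1 8.5    5 1172.377         3 measured
```

Starting from 5 random conditions, three 5-experiment iterations locate the
surface's true grid optimum — maximal substrate and ammonia, minimal enzyme
loading and cosolvent, pH at the enzyme's optimum (the measured 1172
exceeds the noise-free optimum 1137 by simulated experimental noise). For a
real campaign, replace the oracle with the lab: `init_campaign()` writes the
ledger CSV, `select_batch()` (or the `suggest` CLI verb in
`inst/cli/reactbo.R`) appends proposals, `record_measurements()` marks them
measured.

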