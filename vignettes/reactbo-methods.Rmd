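---
title: "Batch Bayesian optimization of reaction conditions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch Bayesian optimization of reaction conditions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactbo)
```

## The problem

Optimizing an enzymatic (or any) reaction means finding, in a hyperspace of
continuous conditions — substrate and enzyme concentration, pH, cosolvent
fraction, cofactor loading — the point that maximizes a figure of merit (FoM)
such as the total turnover number (TON, moles of product per mole of enzyme).
Each evaluation is a wet-lab experiment, so the budget is tens of runs, not
thousands. `reactbo` implements an iterative batch Bayesian-optimization
workflow for this setting: a Gaussian-process (GP) surrogate is fitted to the
experiments so far, an acquisition function scores every untested grid point,
a batch of the most promising conditions is proposed, measured, appended to
the ledger, and the cycle repeats until the budget or a target FoM is
reached. A single-iteration response-surface-methodology (RSM) baseline —
central composite design plus a quadratic fit — is included for comparison.

## Surrogate model

The response is modelled as a constant-mean GP with a Matérn-5/2 kernel and
per-variable (ARD) lengthscales. Inputs are mapped affinely to the unit cube
for kernel numerics; outputs pass through one of two invertible transforms:

* `zscore` (default): centre and scale to unit variance — used by the
  conventional and BOA-1 strategies;
* `max10`: $y' = 10\,y/\max(y_\text{measured})$ — required by the
  variance-squared strategy, which only makes sense when the response
  magnitude is pinned (see below). Believer pseudo-observations never update
  the max.

Hyperparameters (lengthscales $\ell_j$, signal variance $\sigma_f^2$, noise
variance $\sigma_n^2$) maximize the log marginal likelihood by L-BFGS-B with
analytic gradients from 8 seeded restarts (first start deterministic:
$\ell_j = 0.5$ on the unit cube, $\sigma_f^2 = \mathrm{var}(y)$); ties keep
the first optimum found, so fits are reproducible. A noise floor of $10^{-6}$
(transformed units) is always added: enzymatic replicates are noisy, and the
floor keeps the Cholesky factorization well conditioned and tolerates
replicated conditions. Duplicate conditions with conflicting responses and a
zero floor are refused with an instructive error rather than silently
regularized. The kernel choice follows common practice in reaction
optimization; the package makes no claim that it matches any particular
historical script.

## Acquisition functions

With posterior mean $\mu(x)$, standard deviation $\sigma(x)$, incumbent
$f^+$ (the best **measured** value — believer records may raise the GP mean
but never the incumbent) and jitter $\xi = 0.01$:

$$\mathrm{EI}(x) = (\mu - f^+ - \xi)\,\Phi(Z) + \sigma\,\phi(Z),\qquad
Z = \frac{\mu - f^+ - \xi}{\sigma},$$

with the degenerate branch $\max(\mu - f^+ - \xi, 0)$ at $\sigma = 0$ (the
$\sigma \to 0^+$ limit; the piecewise definition is a deliberate numerical
choice, verified by a limit test at $\sigma = 10^{-12}$).

Two batch-aware variants address EI's tendency to over-exploit:

* **BOA-1** keeps EI but, before each pick, eliminates every grid candidate
  whose minimum Euclidean distance — on z-scored coordinates — to any
  measured point or to any believer already chosen this batch is $\le 1.0$.
  "Within the threshold" is read inclusively: a candidate at exactly 1.0 is
  eliminated, strictly greater is kept. Including same-batch believers in the
  reference set is a deliberate reading — it is what prevents a batch from
  piling into one region, which is the rule's purpose. If the filter empties
  the grid the radius is halved once, then dropped, each fallback logged:
  refusing to propose anything would be worse than proposing close neighbours.
* **BOA-2** replaces $\sigma$ by $\sigma^2$ inside EI, on the `max10` output
  scale. Early in a campaign most of the grid has $\sigma > 1$ (on a 0–10
  response), so squaring amplifies exploration; as data accumulate and
  $\sigma$ drops below 1 the variant decays towards plain EI and
  exploitation takes over. The rescaling is what keeps $\sigma^2$
  commensurate — squaring a TON-scale uncertainty would be meaningless.

For two-FoM problems (e.g. maximize TON subject to chemoselectivity above a
target), the score is multiplied by the probability of feasibility from an
independent GP on the second FoM:
$\mathrm{AF}(x) = \mathrm{EI}(x)\,\Phi\!\big((\mu'(x) - T)/\sigma'(x)\big)$.
The threshold $T$ is interpreted on the native second-FoM scale and the
second GP is z-scored internally; because the factor is invariant under
affine transforms of the second response, this is exactly equivalent to
fitting on the native scale while numerically better conditioned. At
$\sigma' = 0$ the factor is the indicator limit (0.5 at equality). Each FoM
gets its own independent fit; no multi-task sharing is attempted.

## Batch selection

Batches of $q$ (default 5) conditions are assembled by the Kriging-believer
heuristic: after each pick, the GP's predictive mean at that point is
appended as a pseudo-observation (`source = "believer"`) and the model is
refitted (hyperparameter refitting per insertion is the default; a
`refit_believers = FALSE` flag freezes them for speed and only reconditions
the posterior). Believer rows exist only inside `select_batch()`; the
returned proposal and any ledger written to disk contain none. Exact
duplicates of already-chosen points are additionally removed from the
candidate pool so batch points are always pairwise distinct even for the
conventional strategy.

## Design space, grid and standardization

Candidates are a finite Cartesian grid (endpoints included) filtered by the
linear feasibility constraints, with strict `<` honoured strictly — a
boundary point of a strict constraint is infeasible. The acquisition argmax
over a fixed, lexicographically ordered grid is exactly reproducible, which
is why a grid is used instead of continuous acquisition maximization; ties
break to the lowest index and are flagged. The default resolution is 7
levels per variable. That default is a documented judgement call — fine
enough that grid quantization is small against experimental noise, coarse
enough that a 5–6-variable grid stays in the $10^4$–$10^5$ range; nothing in
the workflow depends on it and it is configurable per variable.

Standardization for the BOA-1 distance rule is a z-score per variable over
the **feasible** candidate set, using the population standard deviation.
This makes the 1.0 threshold scale-free: one unit is one standard deviation
of the searchable range of that variable. pH is treated as a plain linear
axis like any other variable (no hydrogen-ion transform).

## The synthetic enzyme simulator

Because wet-lab TONs are not computationally reproducible, the package ships
a ground-truth simulator whose factors are the simplest mechanistically
sensible forms reproducing the qualitative behaviours enzymologists expect:

$$\mathrm{TON}(x) = \mathrm{TTN}_{\max}\cdot
\frac{S}{S + K_m + S^2/K_i}\cdot
e^{-\left(\frac{\mathrm{pH} - \mathrm{pH}_{opt}}{w}\right)^2}\cdot
e^{-k_d\,[\mathrm{DMSO}]}\cdot
\frac{E_{1/2}}{E_{1/2} + E}\cdot(\text{optional cofactor/cosubstrate factors})$$

— substrate saturation with inhibition (interior optimum at
$S^* = \sqrt{K_m K_i}$), a Gaussian pH optimum, exponential cosolvent
inactivation, TON decreasing with enzyme loading, an optional Gaussian
cofactor optimum (TPP inhibitory in excess) and a saturating cosubstrate
term. Measurements multiply the true TON by a lognormal factor with unit
mean and a 5% coefficient of variation — a typical inter-replicate spread
for HPLC-quantified biotransformations. Chemoselectivity, where modelled, is
a logistic map of an affine function of the conditions scaled to 0–100%,
parameterized so that it is anti-correlated with TON (the recurring
trade-off), with additive truncated Gaussian noise. The conversion between
an isomer ratio and chemoselectivity is
$100\,(\text{major}-\text{minor})/(\text{major}+\text{minor})$, so 85:15
corresponds to 70%.

Three presets live in versioned YAML fixtures (`inst/extdata/presets/`), so
tests can pin exact optima: `bfd5` (5 variables incl. cofactor), `pal5`
(5 variables plus the solubility constraint
$28.6[\mathrm{NH_4^+}] + 2[\mathrm{DMSO}] + 2.1[\mathrm{enzyme}] < 200$) and
`bal6` (6 variables with the TON/selectivity trade-off). Each file records
the unique argmax of its default grid under the noise-free surface. These
are synthetic fixtures: smooth, separable up to mild coupling, stationary
and low-noise. Real enzymatic landscapes can hold interactions (pH–DMSO–
solubility coupling), heteroscedastic noise and day effects that these
surfaces do not emulate, so passing benchmarks here demonstrates correct
algorithmic behaviour, not guaranteed wet-lab performance.

## The RSM baseline

The comparator is a face-centred central composite design: a full two-level
factorial core up to 4 factors and a resolution-V+ half fraction from 5, two
axial points per factor on the faces, and 3 centre replicates — 29 runs for
5 factors, 47 for 6, matching the classic design sizes. (Which exact design
a commercial DoE package would generate is not knowable; the face-centred
half-fraction choice is flagged as an inference from those run counts.) The
full quadratic model ($1 + 2k + k(k-1)/2$ coefficients) is fitted by least
squares; rank deficiency reports the aliased terms by name. The predicted
optimum is the argmax over the feasible candidate grid — no stationary-point
extrapolation outside the bounds, and constraints are respected because
infeasible candidates were never generated. The baseline is deliberately
single-iteration: design, fit, predict, one confirmation run.

## Campaign mechanics and determinism

A campaign is `n_initial` uniform random feasible grid points (5 by
default, drawn without replacement; a space-filling initial design was
considered and rejected as the default to keep the workflow's entry point
assumption-free), then `n_iterations` cycles of 5 proposals each. Every
random draw — initial design, GP restarts, simulator noise — descends from
the campaign seed, and seeded sections restore the caller's RNG state, so a
configuration replays a byte-identical history. The running best is
monotone; an optional `stop_target` ends the loop early; total measured rows
always equal `n_initial` plus the sum of returned batch sizes. In
human-in-the-loop mode the tool only ever appends proposals and fills in
measured values; user rows are never deleted.

## Numerical choices, in one place

* EI at $\sigma = 0$: closed-form limit branch; scores clipped at 0 against
  floating-point negatives.
* GP noise floor $10^{-6}$; interpolation tests use $10^{-8}$.
* Optimizer: L-BFGS-B, 200 iterations max, bounds
  $\log \ell \in [\log 10^{-3}, \log 10^{3}]$ on the unit cube; 8 restarts;
  first-found tie-break.
* BOA-1 boundary: distance exactly equal to the threshold is excluded.
* Grid argmax tie-break: lowest index, tie flag set.
* Constrained factor at $\sigma' = 0$: indicator with 0.5 at equality.
* Degenerate constant-response fits: the z-score scale falls back to 1, the
  fit returns the constant.

## Benchmark sizes and what they show

The shipped benchmark compares boa1, boa2 and uniform random sampling on
`bfd5` at a budget of 5 initial + 5×5 proposed experiments over 20 seeded
campaigns — the same shape as a realistic screening effort. Both batch
strategies roughly double the median final best TON of random sampling.
Reaching within 90% of the global grid optimum is a much harder ask on this
surface — only 5 of 16807 grid points qualify — and at this budget the
exploration-biased variants land there in a minority of seeds, while plain
EI, free to exploit a smooth unimodal landscape, reaches the basin in most
seeds; on rugged real surfaces that preference can invert, which is exactly
the trade-off the variants exist to manage. The geometry property of BOA-1
(every proposal
strictly farther than 1.0 standardized units from all measured points and
batch-mates) is exercised over 50 seeded 4-variable campaigns sized so the
exclusion radius never exhausts the grid. Known limitation, visible in the
traces: BOA-1's exclusion blocks fine-tuning near the incumbent late in a
campaign, and BOA-2 spends its early budget at the boundaries — each variant
trades early coverage against late refinement, which is why they complement
each other.
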