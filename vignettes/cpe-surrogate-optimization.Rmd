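---
title: "Surrogate-based optimization of cloud point extraction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-based optimization of cloud point extraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and validation design
behind `cpeopt`, in the spirit of a methods section: what is computed, under
which assumptions, and what the package's own tests do and do not establish.

## The problem

Cloud point extraction (CPE) separates bioactive compounds into a
surfactant-rich phase. Eleven process factors govern recovery of the three
responses tracked throughout — total phenolic content (TPC, mg gallic-acid
equivalents/100 g dry weight), total carotenoids (TC, mg β-carotene/100 g
dw) and antioxidant activity (AA, µmol Trolox equivalents/100 g dw):

| factor | meaning | kind | screening levels |
|---|---|---|---|
| X1 | surfactant type | categorical | Tween 80 / Triton X-100 |
| X2 | surfactant concentration (%, w/v) | continuous | 2 – 10 |
| X3 | solid:liquid ratio (mass fraction) | continuous | 0.01 – 0.1 |
| X4 | pH | continuous | 1.5 – 7.5 |
| X5 | equilibration temperature (°C) | continuous | 35 – 75 |
| X6 | equilibration time (min) | continuous | 20 – 60 |
| X7 | salt type | categorical | NaCl / KCl |
| X8 | salt concentration (%, w/v) | continuous | 16 – 18 (OVAT grid 6 – 18) |
| X9 | centrifugation speed (g) | continuous | 2473 – 9892 |
| X10 | centrifugation time (min) | continuous | 10 – 20 |
| X11 | CPE steps | categorical | Step 1 / Step 2 |

Some settings produce no phase separation at all; such runs record zero for
every response. The solid:liquid ratio is treated as the continuous solids
mass fraction (1:50 = 0.02) rather than a categorical label, which is how
interpolated optima between printed levels become expressible.

## Encoding and normalization

Categorical factors are expanded to **full one-hot blocks** (not reference
coding): each level gets a slot, exactly one slot is 1 per run. Full one-hot
is what makes the 11-factor space encode to 14 model inputs
(8 continuous + 2 + 2 + 2), so the reference surrogate is an MLP 14–*h*–3.
The redundancy this introduces (slots of a block sum to 1, collinear with
any intercept) is handled downstream, not in the encoding — see the
sensitivity section.

Inputs and responses are normalized **per column to [0, 1] by min–max** on
the training table. Min–max keeps an identity-activation network directly
interpretable as an affine map of scaled factors, and the column ranges are
the natural scale on which influence percentages are comparable across
units. A constant column scales to 0 and inverts back to its value.

## The surrogate

A single hidden layer maps encoded, scaled inputs to scaled responses:

$$\hat y = f_2\!\big(b_2 + V^\top f_1(b_1 + W^\top x)\big)$$

with activations $f_1, f_2$ chosen from `identity`, `logistic`, `tanh`,
`exponential`. Training minimizes $\tfrac12\sum\|\hat y - y\|^2$ on the
normalized scale with BFGS (`stats::optim`) and analytic gradients, from a
random initialization per restart. Key numerical choices:

- **Initialization.** Uniform(−0.5, 0.5) scaled by 1/√fan-in for the weight
  matrices, and output biases aimed at $f_2^{-1}(\bar y)$ so every restart
  starts predicting near the response means. This is the standard cure for
  dead saturated units: with unscaled flat initialization, exponential-output
  networks routinely start (and die) in a zero-gradient regime where all
  predictions collapse to zero; with fan-in scaling and mean-matched biases,
  roughly 15 of 16 restarts converge on typical campaign tables.
- **Exponential activation** uses a linear tail beyond 30 (continuous value
  and derivative), so line searches back out of saturation instead of
  hitting an overflow cliff.
- **Convergence**: `reltol = 1e-12`, at most 500 iterations by default
  (2000 in the recovery study). A failed optimizer run is retried once on a
  derived sub-seed before counting as a failed restart.
- **Search** (`cpe_mlp_search`) trains `restarts` networks for every
  (hidden size, activation pair) combination and selects the highest mean
  training r² across responses; ties break to fewer hidden neurons, then
  lower loss, then lower restart index. Sub-seeds are a deterministic
  function of the master seed and the candidate coordinates, so enlarging
  the restart budget only appends candidates — the selected r² is monotone
  in the budget.

Two structural facts worth keeping in mind. First, with identity activations
in both layers and $h \ge 3$ the network family is exactly the affine family
(the product $WV$ has at most rank 3 anyway for three outputs), so the best
achievable loss equals ordinary least squares' loss — the package's tests
verify this against a QR-based oracle. Second, a 14–7–3 network has
$14\cdot7 + 7 + 7\cdot3 + 3 = 129$ parameters; fitted to a 12-run screening
table it *interpolates* (training r² = 1.000 per response). The model
summary warns that this is a fit statistic, not generalization.

## Yoon connection-weight sensitivity

The relative influence of encoded input $i$ on response $j$ is

$$RI_{ij} = 100 \cdot \frac{\sum_k W_{ik} V_{kj}}
{\sum_{i'} \big|\sum_k W_{i'k} V_{kj}\big|},$$

computed from the weights as trained (normalized scale; biases excluded),
so $\sum_i |RI_{ij}| = 100$ per response by construction.

One subtlety is forced by full one-hot coding: adding a constant to all slot
products of a block is absorbed by the bias, so slot products are identified
only **up to a per-block additive constant**, and the constant a
gradient-trained network leaves behind is whatever the random initialization
put there. Aggregating raw slots would therefore inject initialization noise
into categorical factors' influence. The implementation centers each block's
products (the canonical estimable contrast) before normalizing; factor-level
influence is then the signed RI for continuous factors and the magnitude of
the level contrast for categorical ones (whose centered signed sum is zero
by construction).

In the identity-activation limit $\sum_k W_{ik}V_{kj}$ is the equivalent
affine coefficient, and RI equals the normalized least-squares coefficients;
this is cross-checked in the tests against an independent `lm.fit` oracle at
tolerance 1e-6 on well-determined continuous data.

**Limitation (measured, not hypothetical).** RI is built from weight
products, so it weights *local steepness*, not integrated effect. In the
recovery study below, the solid:liquid ratio's grid compresses the
1:100–1:50 span into 11% of the normalized axis; any good fit needs large
weights there, and the ratio tops the RI ranking (~31% per response) even
though its end-to-end effect is modest. The simulator's dominant factor by
any integrated measure (multiplier log-range, log total variation,
response-scale range) is the equilibration temperature, which RI ranks
around fourth. Conversely a linear (identity) sensitivity model measures
response-scale average slopes, under which several factors are within ~15%
of each other and the top slot flips with the data seed. Top-1 factor
identification from connection weights is therefore not reliable on this
problem class, and the recovery report says so honestly; rankings should be
read in groups, not by single positions.

## Designs

`pb_design()` builds the standard cyclic 12-run Plackett–Burman design for
exactly 11 two-level factors (generator row cycled 11 times plus an
all-minus row): every column is balanced 6/6 and all 55 column pairs are
orthogonal under ±1 coding — verified exhaustively in the tests. The mapping
of levels to +/− is configurable; `table2_pairing()` reproduces the pairing
used in the bundled screening table. The bundled table itself is loaded via
`cpe_fixture()`, never regenerated, since the printed row assignment is one
of many valid designs.

`ovat_grid()` produces one-factor-at-a-time sweeps: one run per grid value,
all other factors at a fixed context (`ovat_center()` holds each factor at
its OVAT-stage best).

## Multi-objective optimization

`cpe_optimize()` maximizes the three predicted responses simultaneously with
an NSGA-II-style evolutionary algorithm over the mixed space: binary
tournament selection on (non-domination rank, crowding distance), BLX-0.5
blend crossover and Gaussian mutation (σ = 5% of range, clipped to bounds)
on continuous genes, uniform crossover and random resets on categorical
genes, elitist environmental selection; defaults 36 generations, population
100. Operator rates are package choices and configurable.

Two numerical details: (1) with three objectives the population is typically
front-saturated well before the final generation, and members can survive
that a nearby point would strictly dominate; a final **dominance polish**
(25 rounds of small Gaussian perturbations, a member replaced only when its
perturbation dominates it) removes such stragglers, and the tests verify the
front against brute-force dominance and, on a small space, against
exhaustive grid enumeration. (2) The **compromise** solution maximizes the
equal-weights sum of objectives min–max normalized *over the front*; a
degenerate (constant) objective contributes zero, and ties resolve to the
first member in front order.

## The response-surface simulator

`cpe_sim_config()` defines a multiplicative ground truth
$y_j = \text{gate}(x)\, \beta_j \prod_i f_{ij}(x_i)$ with piecewise-linear
multiplier profiles, per-level categorical multipliers, phase-separation
gates that zero all responses, and multiplicative log-normal replicate noise
(`y · exp(ε)`, `ε ~ N(0, cv)`, triplicates averaged by default).

The default configuration emulates the qualitative single-factor findings of
CPE screening: saturating surfactant-concentration effect; solid:liquid
ratio peaked at 1:50; pH effect peaked acid-side for phenolics and
antioxidant activity but increasing for carotenoids (the one deliberate
trade-off); temperature peaked at 45 °C; mildly decreasing equilibration
time; decreasing centrifugation speed and time; a second extraction step
that halves carotenoid recovery. Gates: no separation for Span 85 or
Ceteareth-12, for CaCl₂, below 15% salt, or at ≥ 75 °C with ≥ 18% salt — the
last reproduces all-zero rows in Plackett–Burman tables under the bundled
level pairing. Baselines (350 / 16.5 / 980) match the magnitudes of real
recoveries; the noise CV of 0.03 matches the scale of printed triplicate
standard deviations. Peak prominences are set well above that noise so the
synthetic optimum is *identifiable at the designs' resolution* — a
validation surface whose features drown in its own noise cannot validate
anything.

What the simulator does **not** emulate: assay-specific interference,
drift between batches, correlated errors across responses, and any micelle
thermodynamics; effects are multiplicatively separable by construction. Test
passes on the simulator therefore establish pipeline correctness
(identifiable truth in, truth out), not performance on arbitrary real
systems.

Because the truth is separable except for the pH trade-off,
`sim_true_optimum()` computes the exact Pareto front semi-analytically:
shared-argmax factors are fixed, trade-off factors are scanned on fine
grids, and the same `pareto_filter()`/`compromise_point()` machinery
extracts the compromise. `sim_true_effects()` quantifies each factor's
graded effect as the log-range of its multiplier over a region, with gates
deliberately excluded (they are a discrete failure mode, not a graded
effect).

## The recovery experiment

`recovery_experiment()` is the package's end-to-end validation: simulate a
screening-and-optimization campaign on the default ground truth and check
what the pipeline recovers. Its design extends the classic
screening-then-model sequence with three ingredients that experimentation
showed to be *necessary*, not optional, for interior optima:

1. **Campaign** — the 12-run Plackett–Burman design plus OVAT sweeps around
   the center plus 64 uniform space-filling anchor runs over the separating
   region (~230 measured runs after dropping failed separations, triplicate
   noise). A two-level design alone carries no curvature information, and
   axis sweeps alone leave an interpolating surrogate unconstrained off the
   axes — an optimizer then reliably exploits off-axis artifacts rather
   than the signal.
2. **Surrogate family** — exponential hidden and output activations: the
   network is then $\exp(b + \sum_k v_k e^{w_k^\top x})$, a multiplicatively
   separable form matching the simulated surface class, with far smaller
   off-axis artifacts than saturating units at comparable fit quality
   (hidden size 3, 16 restarts, 2000 iterations).
3. **Measured verification and refinement** — each of two optimizer rounds
   proposes a Pareto front whose members are *measured* (simulated in
   triplicate) and fed back into the training table before refitting; the
   final optimum is then polished by a measured coordinate refinement (two
   OVAT-style local passes, spans 25% and 8% of range), with the compromise
   always selected on measured, not predicted, values. Selecting on
   measurements is what debunks any surrogate artifact the optimizer found;
   it mirrors the verification step any careful study performs.

The report compares the final compromise against the exact truth:
categorical genes must match exactly and continuous genes fall within 10% of
the searched range (at the default seed the observed maximum offset is below
1% of range; across development seeds typically 2–9%). The sensitivity
check — is the top-|RI| factor the truth's largest graded effect? — fails
for the reasons analysed above, and is reported as a finding about
connection-weight sensitivity rather than patched over.

Sensitivity is computed from the screening-stage fit (before verification
data accrue), mirroring the fit → sensitivity → optimize order of a real
campaign.

## Problem sizes and runtimes

Defaults are sized for interactive use on one CPU: the screening-table fit
is instant; a full `cpe_optimize()` run (36 × 100, polish 25) takes a few
seconds; `recovery_experiment()` with its ~230-run campaign, two
optimize–verify rounds and refinement takes well under a minute; the entire
test suite a few minutes. The restart default of 200 in `run_pipeline`-scale
searches is deliberately far below the hundred-thousand-network searches
commercial screening software advertises: with selection on training r² and
an interpolating reference family, additional restarts change the selected
model negligibly.

## Known limitations

- Model selection uses training r² only; with saturated designs this
  selects interpolants, and all generalization claims must come from
  verification measurements, as in the recovery loop.
- Connection-weight sensitivity over-weights locally steep features and
  under-determines near-tied effects (see above); no Garson or
  permutation-importance alternatives are provided in this version.
- The optimizer handles box and level constraints only.
- The simulator's separable, multiplicative truth is a deliberate
  simplification; pipelines validated on it may still underperform on
  strongly interacting real surfaces.
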