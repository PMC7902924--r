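---
title: "Modeling mitigation-investment decisions in a landslide microworld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mitigation-investment decisions in a landslide microworld}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilsRL)
```

## The decision environment

`ilsRL` simulates repeated mitigation-investment decisions against
landslide risk. Each round a player receives an income (292 EC by
default), invests a fraction of it in mitigation, and a landslide may
occur. The landslide probability blends two sources:

- an *investment* term, `P(I) = 1 - M * cum_invest / cum_budget`, falling
  linearly from 1 (nothing ever invested) to `1 - M` (every EC of income
  to date invested). `M` is the return-to-mitigation parameter: even full
  investment leaves residual risk `1 - M`.
- an *environmental* term `P(E)`, standing in for rainfall and spatial
  susceptibility.

The total probability is the convex combination
`P(T) = We * P(I) + (1 - We) * P(E)` with `We = 0.7` in all shipped
conditions. An occurred landslide independently triggers property damage
(property wealth halves), injury (income falls by 10%) and fatality
(income falls by 20%), with per-condition probabilities: 3/10/1% (low
damage feedback), 30/90/9% (high), 16.5/50/5% (medium). After each round
the player observes a reward `W(t) = income - invest` and a loss
`L(t) = PD(t) + income drop`, the property-damage amount plus the
within-round income reduction.

Two environment parameters are not pinned by the study conditions and
carry package defaults exposed in the condition YAML fixtures:

- `p_env = 0.3`: the environmental probability is treated as a single
  configured scalar (optionally a per-round series). Its decomposition
  into rainfall and spatial terms is not modeled; any split would be
  invented.
- `mitigation_return_M = 0.9`: a free parameter of the environment; 0.9
  makes investment consequential (residual risk 0.1) without eliminating
  risk.

Two further conventions: the per-round budget equals the current
(possibly damage-reduced) income, so the cumulative budget is the sum of
incomes to date; and within a round the order is observe income, invest,
compute probabilities, sample the landslide, apply damages, emit
feedback — so a round's loss reflects damages landing after that round's
investment. Injury and fatality in the same round compound
multiplicatively (the order is immaterial for the product). Currency is
kept as real-valued EC throughout; no rounding is applied.

## The decision models

Models choose among ten options, option `k` covering the half-open
investment-ratio bin `[(k-1)/10, k/10)`; the realized ratio is uniform
within the chosen bin. Bins are half-open so the partition of `[0,1]` is
total. All models start with every option expectancy at 50 units, making
the first choice uniform.

Because raw EC magnitudes span five orders of magnitude (income ~3e2,
property damage ~1e7), rewards and losses are divided by `scale_divisor`
(default: the initial income, 292) before entering any utility function.
Without some normalization the softmax saturates to an argmax and every
model degenerates; scaling by initial income makes a fully uninvested,
undamaged round worth exactly 1 utility-input unit.

| model | utility of feedback | learning rule | sensitivity |
|-------|---------------------|---------------|-------------|
| EV    | `(1-w)W - wL`       | delta rule on chosen option, recency `a` | `(t/10)^c`, `c` in `[-5,5]` |
| EV-PU | prospect utility of net `x = W - L` | delta rule, recency `A` | `(t/10)^c` |
| PVL   | prospect utility of net `x` | decay rule, recency `A` | `3^c - 1`, `c` in `[0,5]` |
| PVL-2 | `win^a - lambda * loss^a` (separable) | decay rule | `3^c - 1` |
| RANDOM | none | none | argmax of 10 iid uniforms |

The prospect utility is `x^alpha` for gains and `-lambda * |x|^alpha`
for losses. The EV valence is implemented as `(1-w)W - wL`: `w` weights
losses *against* rewards, so the loss magnitude must enter negatively
for `w > 0.5` to describe loss aversion. The delta rule updates only the
option chosen on the round that produced the feedback; the decay rule
first shrinks all expectancies by `A`, then credits the chosen option
with the utility. Choice uses a softmax over `theta * EV_k`, computed
with max-subtraction so large expectancies cannot overflow. Sensitivity
for the EV family uses the round index of the decision being made.

Per-participant randomness is one seeded stream with a fixed draw order
(choice draw(s), bin draw, environment draws; exactly four environment
uniforms when a landslide occurs, one otherwise), so every trajectory is
bit-reproducible from `(model, params, config, seed)`. The flat
simulator `simulate_participant()` is tested to be bit-identical to the
compositional `agent_act()` + `step_round()` path.

## Synthetic cohorts

The human cohorts behind the original analyses are not publicly
deposited, so the package generates synthetic stand-ins.

*Model ground truth* cohorts run agents of a known model through the
microworld; they are used for parameter recovery and self-consistency
checks.

*Stylized human* cohorts draw per-participant trajectories around a
target mean curve with independent Gaussian noise (sd 0.15), clipped to
`[0,1]`. The default targets encode only what is known about the human
cohorts: overall mean investment ratio 0.38 (low condition, near-flat
curve), 0.67 (high condition, rising curve), and a midpoint constant
0.52 for medium. The high-condition target is a logistic rise from 0.30
toward 0.85 with slope scale 3 rounds, its midpoint solved at run time
so the 30-round mean equals 0.67 exactly. Cohort sizes default to the
study sizes: 20 (low), 23 (high), 30 (medium).

These cohorts reproduce the *aggregate* contrasts the analysis needs (a
high mean above a low mean, a rising high-condition curve). They do not
model individual differences, autocorrelated noise, or any within-round
coupling between a participant's events and their next decision, so
passing tests on stylized cohorts demonstrates that the pipeline is
correct and well-posed — not that real participants behave like the
generator.

## Calibration

Each model's parameters are fitted to a cohort's mean investment-ratio
trajectory by minimising `SSD1 + (1 - R^2)`, where SSD1 is the mean over
rounds of the squared difference between the simulated and target mean
curves and R^2 is the squared Pearson correlation between the curves.
R^2 of a constant curve is undefined; the degenerate rule returns 1 when
the curves are essentially identical (SSD1 < 1e-12) and 0 otherwise,
keeping the objective continuous.

The optimizer is a real-coded genetic algorithm with population 20,
crossover rate 0.80 and mutation rate 0.01, stopping when the average
relative change of the best objective over 50 stall generations falls
below 1e-8 or at the generation cap. Operator details are package
choices: tournament selection of size 2, per-gene arithmetic crossover,
Gaussian mutation with sd 10% of each parameter's range reflected at the
bounds, and one elite per generation (making the best objective
non-increasing). The generation cap is 500 in the `full` profile and 30
in the `smoke` profile used by the tests and the acceptance script;
smoke-profile runs keep a five-model, two-condition calibration within
minutes on one core at 23 simulated participants and 5 objective
replicates per evaluation.

The objective involves simulation, so it is made a deterministic
function of the parameters by common random numbers: a fixed bank of
per-replicate, per-participant seeds derived from the calibration seed
is shared by every candidate, and the simulated mean curve is averaged
over `n_objective_replicates` (default 5) replicates. This removes
evaluation noise from the search itself; residual noise remains in how
well any finite simulation approximates the model's expected curve.

## Parameter recovery and its limits

With a single 23-participant cohort as the target, the mean curve
carries sampling noise of roughly `0.29 / sqrt(23) ≈ 0.06` per round.
That noise floor dominates the objective: the correlation between a
smooth simulated mean curve and a noisy single-cohort curve is small no
matter the parameters, and the fitted objective routinely lands *below*
the objective at the generating parameters. Point recovery of
individual parameters in this regime is not meaningful, and the package
does not claim it.

The recovery checks therefore separate two questions. Optimizer
soundness is tested on the literal single-cohort design: the calibrated
objective must come within 0.02 of (or beat) the objective at the
generating parameters, and must beat the no-learning baseline. Ordering
recovery — whether a loss-aversion ground truth of `lambda = 4.797`
yields a larger recovered `lambda` than a ground truth of 2.204 — is
tested against each model's *expected* mean curve, estimated by
averaging the 23-agent cohort curve over 10 seed replicates, the
standard recovery-study design when the estimand is the model's mean
behavior.

Even in that favorable design, `lambda` ordering is not recovered, and
the package documents this as a structural identifiability limit rather
than an optimizer defect. In this environment a round's loss does not
depend on that round's bin choice: injury, fatality and property-damage
sizes are fixed consequences of the sampled event, and investment
affects only *future* landslide probability. The `lambda` penalty
therefore lands on whichever bin happened to be chosen and, over
rounds, shifts all expectancies nearly uniformly — a shift the softmax
cancels. Measured directly, the expected 23-agent mean curves under
`lambda = 4.797` versus `2.204` (other high-condition parameters held)
differ by about 0.001 in level, far below Monte-Carlo resolution at any
feasible budget, so the fitted `lambda` is essentially unconstrained by
the objective. The corresponding test is kept in the suite as a
deliberately failing record of this limit.

## Generalization

Generalization freezes the parameters calibrated in the low and high
conditions and simulates each model in the medium condition with no
refitting, tabulating SSD1, R^2, `AIC1 = 30 ln(SSD1) + 2p` and
`AIC2 = ln(SSD2) + 2p` (SSD2 compares grand means over participants and
rounds; `p` is the free-parameter count — 3 for EV, 4 for the prospect
family, 0 for the random baseline). The random model appears under both
parameter provenances with identical values, since it has no parameters
to freeze. AIC1's round multiplier generalizes to the actual round
count `T`, which is the constant 30 for all shipped conditions.

## Reproducibility conventions

Every sampling function either takes explicit uniforms (for scripted
traces) or documents its draw count; cohort generators derive
per-participant seeds from the cohort seed; `objective()` restores the
ambient RNG state so calibration code can interleave with other
randomness; and the workflow runner (`run_manifest()`,
`run_calibration_experiment()`, `run_generalization()`, `report()`)
derives all stage seeds from one master seed, so a manifest pins every
number in the output directory (timestamps aside).

## Known limitations

- Stylized cohorts are aggregate emulations; no claim about individual
  human trajectories.
- The GA is a global heuristic; with a 4-dimensional box and simulation
  noise it finds good objective values but parameter point estimates are
  only as identified as the objective allows (see above).
- The environment's `p_env` and `M` are fixed defaults, not estimated;
  conclusions conditional on them.
- No hierarchical or per-individual fitting; the unit of fit is the
  cohort mean curve.
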