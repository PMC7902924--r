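# ilsRL

Reinforcement-learning models of repeated mitigation-investment decisions
in a simulated landslide environment.

People living in landslide-prone regions repeatedly decide how much of
their income to invest in mitigation. `ilsRL` provides a desk-scale
implementation of the full modeling loop used to study such decisions:

- a **landslide microworld**: each round an agent invests a fraction of a
  292 EC income; the landslide probability is
  `P(T) = We·P(I) + (1−We)·P(E)` with `P(I) = 1 − M·(cumulative
  investment / cumulative budget)`; an occurred landslide can
  independently halve property wealth (property damage), cut income by
  10% (injury) or 20% (fatality). Feedback per round is the reward
  `W(t) = income − invest` and loss `L(t) = PD(t) + income drop`.
- **five decision models** over ten investment-ratio bins: expectancy-
  valence (EV, valence `(1−w)W − wL`, delta-rule learning, sensitivity
  `(t/10)^c`), prospect-valence learning (PVL, prospect utility
  `x^α` / `−λ|x|^α` of the net outcome, decay-reinforcement learning,
  sensitivity `3^c − 1`), EV-PU (prospect utility with EV learning and
  sensitivity), PVL-2 (separable utility `win^α − λ·loss^α` with PVL
  learning), and a no-learning RANDOM baseline.
- **genetic-algorithm calibration** of each model to a cohort's mean
  investment-ratio curve, minimising `SSD1 + (1 − R²)` (population 20,
  crossover 0.80, mutation 0.01, stall window 50, tolerance 1e−8).
- **model comparison** via OLS-style criteria `AIC1 = 30·ln(SSD1) + 2p`
  and `AIC2 = ln(SSD2) + 2p`, plus generalization of frozen parameters to
  a held-out medium-damage condition.
- a **synthetic-cohort generator** (the original human cohorts are not
  publicly deposited): model-generated cohorts with known ground truth,
  and stylized human-like cohorts matching the documented aggregate
  contrasts (overall mean investment ratio 0.38 low / 0.67 high, with a
  rising high-condition curve).

## Worked example

```r
library(ilsRL)

# a PVL-2 agent with high-condition calibrated parameters
cfg <- load_condition("high")
par <- load_calibrated_params()$high[["PVL-2"]]
ratios <- simulate_participant("PVL-2", par, cfg, seed = 42)
round(mean(ratios), 3)
#> [1] 0.576

# calibrate PVL-2 to a stylized high-damage cohort (smoke budget)
coh <- generate_stylized_human_cohort(cohort_spec("high", seed = 7))
ga  <- ga_config(max_generations = 30, n_sim_participants = 23, seed = 7)
fit <- genetic_calibrate("PVL-2", cfg, mean_trajectory(coh), ga)
fit
#> <ils_fit> PVL-2 / high  objective 0.359082
#>   params: alpha = 0.3345, lambda = 2.8585, A = 0.8838, c = 3.5312
#>   ssd1 0.08229  R^2 0.7232  AIC1 -66.93  AIC2 4.46  (30 generations)
```

The objective is `SSD1 + (1 − R²)`: the fitted PVL-2 agent reproduces
most of the rising trend of the stylized high-damage cohort
(R² ≈ 0.72) while sitting somewhat below its level (SSD1 ≈ 0.08). The
full workflow — stylized low/high cohorts, all five models
calibrated per condition, frozen parameters generalized to the medium
condition, tables and a report written to an output directory — is:

```r
man <- run_manifest("runs/demo", seed = 1, profile = "smoke")
res <- run_calibration_experiment(man)
gen <- run_generalization(man, res$fits)
report(man)
```

`run_calibration_experiment()` writes one comparison table per condition
(SSD1, R², AIC1, AIC2 per model, sorted by AIC1) and six-block mean
curves; `run_generalization()` writes a 5-model × 2-provenance table for
the medium condition.

## Package layout

- `R/ils-env.R` — microworld: probabilities, event sampling, damages,
  round stepping
- `R/rl-agents.R` — utilities, learning rules, softmax choice, model
  dispatch
- `R/simulate.R` — seeded trajectory simulation
- `R/synthetic-cohort.R` — cohort specs, generators, CSV round-trip
- `R/calibration.R` — objective and genetic algorithm
- `R/evaluation.R` — SSD1, R², AIC1/AIC2, block means, comparison tables
- `R/pipeline.R` — manifest-driven workflow and reporting
- `inst/extdata/` — condition YAMLs and calibrated-parameter fixture
- `vignettes/ilsRL-methods.Rmd` — model equations, design choices,
  limitations
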