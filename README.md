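# ctdose

Probabilistic forecasting of perioperative inflammatory-marker trajectories
and safety-constrained propofol–ketamine dosing recommendations for elderly
burn patients, from irregularly sampled event streams.

Elderly (≥65 y) burn patients mount a biphasic cytokine response — IL-6,
TNF-α and CRP peak 8–12 h after anesthetic induction — under reduced
hemodynamic reserve. Propofol suppresses cytokine production non-monotonically
(a U-shaped dose–response with its minimum near 50–60 mcg/kg/min, as
hypotension-driven hypoperfusion amplifies release at high rates); low-dose
ketamine suppresses monotonically with Emax kinetics (half-max ≈6 mcg/kg/min,
saturation ≈10–12), preferentially on TNF-α. `ctdose` implements an
integrated pipeline for this setting:

* **Event-triplet representation** — each observation is `(value, time,
  modality)`; no imputation. A transformer encoder with continuous-time
  sinusoidal positions and masked-value self-supervised pre-training
  summarizes the episode history into a context vector `z_obs`.
* **Latent continuous-time ODE forecaster** — `dz/dt = f_θ(z, u(t))`,
  `z(t₀) = φ(z_obs)`, with `u(t)` the linearly interpolated infusion rates;
  Gaussian heads emit per-cytokine forecasts `ŷ_c(t₀+h)` for
  `h ∈ {2,4,6,8,12,16,20,24}` h, trained on NLL + λ·CRPS.
* **Two-stage calibration** — per-cytokine temperature scaling, then
  inductive conformal correction: 90% intervals with distribution-free
  marginal coverage ≥ 90% on exchangeable data.
* **CPQL dosing agent** — conservative Q-learning over the continuous action
  `(Δr_p ∈ [−15, 15], r_k ∈ [0, 20])` mcg/kg/min with reward
  `R = 2·1[MAP∈65–90] − 0.01·AUC_IL6(t,t+6h) − 0.005·r_p −
  0.02·max(r_k−10, 0)`, a hard projection onto dose ceilings (100/20) and
  per-5-min rate limits (20/5), and an abstain gate that withholds
  recommendations when a composite confidence score falls below 2.5/5.
* **Off-policy evaluation** — IS / WIS / doubly-robust / fitted-Q estimators
  normalized to behavior cloning = 1.000, plus counterfactual rollouts in
  the ground-truth simulator and a Pareto sweep over the reward weight.
* **Interpretation** — dose–response partial dependence, the joint dose
  surface, and integrated-gradients attributions (completeness-checked).

The clinical source cohorts require credentialed access, so the package
ships a mechanistic synthetic cohort generator (coupled cytokine/MAP ODEs
with the dose–response structure above, a confounded clinician behavior
policy with logged propensities, ~48% informative lab missingness) that
serves as training data, test fixture and ground-truth environment. All
neural components run on a small reverse-mode autodiff engine included in
the package; `deSolve` supplies the adaptive Dormand–Prince solver.

## Worked example

```r
library(ctdose)

# 1. a synthetic cohort of 100 episodes
es  <- simulate_cohort(sim_config(n = 100, seed = 1))
std <- fit_standardizer(es)

# 2. pre-train the encoder, fit and calibrate the forecaster (smoke scale)
enc <- pretrain_masked_modality(es, std,
         encoder_config(layers = 2, heads = 2, d = 16,
                        pretrain_epochs = 3, max_events = 100), seed = 2)
mod <- train_forecaster(es, enc,
         forecaster_config(latent_width = 8, epochs = 80,
                           origins_h = c(2, 6)), seed = 3)
mod <- calibrate_forecaster(mod, es)
forecast_metrics(forecast_pairs(mod, es, "test"), by = "cytokine")
#> # A tibble: 4 × 6
#>   cytokine     n   mae  rmse coverage90  crps
#>   <chr>    <int> <dbl> <dbl>      <dbl> <dbl>
#> 1 crp        165  6.85  8.83      0.933 0.282
#> 2 il10       165 14.4  21.7       0.982 0.459
#> 3 il6        165 58.6  91.2       0.964 0.426
#> 4 tnfa       165 19.2  27.3       0.945 0.318
# coverage 0.93-0.98 against the 0.90 nominal target: the cluster-aware
# conformal stage over-covers, as its finite-sample guarantee implies; MAE is
# on the raw pg/mL (mg/L for CRP) scale at smoke training budgets.

# 3. offline transitions, conservative agent, recommendations
tx    <- build_transitions(es, mod)
agent <- cql_train(tx, cql_config(steps = 400, n_q = 3, batch = 256,
                                  lr = 1e-3, n_step = 8), seed = 4)
S  <- do.call(rbind, tx$state)
fc <- forecast_episodes(mod, es, origins_h = 2)
fc <- fc[fc$cytokine == "il6" & fc$horizon_h == 12, ]
ramps <- fit_confidence_ramps((fc$hi90 - fc$lo90) / pmax(fc$mean, 1),
                              runif(500, 0, 6),
                              q_ensemble(agent, S[1:500, ])$variance)
rec <- recommend(es, agent, mod, ramps)
c(violations = sum(rec$violation), abstain = mean(rec$abstained))
#> violations     abstain
#>          0      0.3066
# every emitted recommendation satisfies the ceilings and rate limits
# (violations = 0); ~31% of decision steps defer to the clinician at this
# crude ramp calibration (the pipeline fits ramps on the training cohort).

# 4. off-policy evaluation, normalized to behavior cloning = 1.000
ope_evaluate(tx, list(CPQL = agent_policy(agent),
                      rule_based = rule_based_policy()))

# 5. dose-response interpretation
pd <- partial_dependence(mod, es, "propofol")
autoplot(pd)
```

`run_pipeline(pipeline_config(n = 60, seed = 1))` chains every stage
(simulate → pretrain → train → calibrate → evaluate → transitions → agent →
rollout → OPE → explain) and writes tidy CSV artifacts plus a run manifest;
`inst/cli/ctdose` is a thin command-line front end over the same functions.

## Scope notes

The simulator is a stand-in for credentialed clinical cohorts: it reproduces
the statistical structure of the problem (irregular informative sampling,
confounded treatment assignment, U-shaped/Emax dose–response, hemodynamic
coupling), not real-data effect sizes. The methods vignette
(`vignettes/methods.Rmd`) documents the models, every tunable parameter, the
numerical choices, and known limitations — including which properties are
and are not recoverable at the desk-scale training budgets used here.
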