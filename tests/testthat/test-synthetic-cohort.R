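# Generator-level contracts: seed determinism, cohort composition, the
# mechanistic dose-response structure, the confounded behavior policy, and
# counterfactual consistency.

test_that("simulation is fully determined by the seed", {
  cfg <- sim_config(n = 10, seed = 31, vitals_every_min = 60)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$static, b$static)
  expect_identical(a$truth$dense$il6, b$truth$dense$il6)
})

test_that("zero-drug IL-6 peaks 8-12 h post induction on the dense grid", {
  st <- list(il6 = 46, crp = 14, tnfa = 18, il10 = 12.4,
             base_il6 = 46, base_crp = 14, base_tnfa = 18, base_il10 = 12.4,
             amp_il6 = 38, amp_tnfa = 20)
  dt <- 5 / 60
  path <- numeric(288)
  for (k in seq_len(288)) {
    st <- cytokine_dynamics(st, (k - 1) * dt, rp = 0, rk = 0, perf = 1, dt_h = dt)
    path[k] <- st$il6
  }
  t_peak <- which.max(path) * dt
  expect_gte(t_peak, 8)
  expect_lte(t_peak, 12)
})

test_that("drug effect factors obey their asymptotics and the U-shape", {
  gt <- gt_params()
  # Emax asymptote: rk -> infinity gives 1 - emax
  expect_equal(f_ketamine(1e9, gt$emax_tnfa, gt), 1 - gt$emax_tnfa, tolerance = 1e-6)
  # suppression maximal at m_p
  grid <- seq(5, 100, by = 5)
  expect_equal(grid[which.min(f_propofol(grid, gt))], gt$m_p)
  # TNF-alpha weighted more strongly by ketamine than IL-6
  expect_lt(f_ketamine(8, gt$emax_tnfa, gt), f_ketamine(8, gt$emax_il6, gt))
  expect_error(f_propofol(-1), "negative dose")
  expect_error(cytokine_dynamics(list(), 0, rp = -5, rk = 0, perf = 1, dt_h = 1),
               "negative dose")
})

test_that("12-h IL-6 is lower at the optimum than at low dose (simulator as oracle)", {
  at_mp <- oracle_trajectory(rp = 55, rk = 0)$il6
  at_15 <- oracle_trajectory(rp = 15, rk = 0)$il6
  at_95 <- oracle_trajectory(rp = 95, rk = 0)$il6
  expect_lt(at_mp, at_15)
  expect_lt(at_mp, at_95)   # hypoperfusion-driven upturn at high dose
  # ketamine suppression is monotone on the noise-free oracle
  ks <- vapply(c(0, 3, 6, 9, 12), function(rk) oracle_trajectory(55, rk)$il6, numeric(1))
  expect_true(all(diff(ks) < 0))
})

test_that("MAP dynamics mean-revert with dose-proportional depression", {
  gt <- gt_params()
  m <- 70
  for (i in 1:200) m <- map_dynamics(m, 83, rp = 0, rv = 0, dt_h = 5 / 60, gt)
  expect_equal(m, 83, tolerance = 0.1)
  m_hi <- 83
  for (i in 1:200) m_hi <- map_dynamics(m_hi, 83, rp = 100, rv = 0, dt_h = 5 / 60, gt)
  expect_lt(m_hi, 83 - 20)
  # vasopressor raises the equilibrium monotonically
  eq <- vapply(c(0, 0.05, 0.1), function(rv) {
    m <- 83
    for (i in 1:200) m <- map_dynamics(m, 83, rp = 60, rv = rv, dt_h = 5 / 60, gt)
    m
  }, numeric(1))
  expect_true(all(diff(eq) > 0))
})

test_that("behavior policy titrates down under hypotension and confounds ketamine", {
  st <- tibble::tibble(depth = 70, map = c(60, 80), rp_prev = 50, rk_prev = 0,
                       arm = 0L, rk_target = 8, depth_target = 52)
  act <- behavior_policy_sim(st, sim_config(), eps_rp = c(0, 0), eps_rk = c(0, 0))
  expect_lte(act$d_rp[1], -6)      # hypotension-triggered reduction
  expect_gt(act$d_rp[2], 0)        # deepening toward the target otherwise
  expect_true(all(is.finite(act$log_prop)))

  # selection on baseline CRP: ketamine arm less inflamed (one-sided)
  es <- fixture_cohort()
  pats <- es$truth$patients
  expect_lt(mean(pats$base_crp[pats$arm == 1]), mean(pats$base_crp[pats$arm == 0]))
  # arm assignment probability decreasing in baseline CRP
  expect_lt(cor(pats$base_crp, pats$p_ket), 0)
})

test_that("cohort composition tracks the target strata and plausibility bands", {
  es <- simulate_cohort(sim_config(n = 614, seed = 614, vitals_every_min = 120))
  s <- es$static$tbsa
  props <- c(mean(s < 20), mean(s >= 20 & s < 40), mean(s >= 40))
  expect_true(all(abs(props - c(0.645, 0.241, 0.114)) <= 0.05))
  expect_true(all(es$static$age >= 65))
  expect_equal(es$static$baux, es$static$age + es$static$tbsa)

  # relative spike prevalence under the default behavior policy
  spikes <- true_spike_labels(fixture_cohort(), criterion = "relative")
  expect_gte(mean(spikes$spike), 0.15)
  expect_lte(mean(spikes$spike), 0.40)
})

test_that("lab sampling is seeded, intensity-controlled and informative", {
  expect_length(sample_lab_times(30, intensity = 0, seed = 1), 0)
  a <- sample_lab_times(30, 0.5, seed = 4)
  b <- sample_lab_times(30, 0.5, seed = 4)
  expect_identical(a, b)
  # informative sampling draws more when IL-6 runs high
  hi <- function(t) rep(250, length(t))
  lo <- function(t) rep(5, length(t))
  n_hi <- mean(vapply(1:100, function(s) length(
    sample_lab_times(30, 0.4, informative = TRUE, seed = s, il6_at = hi)), numeric(1)))
  n_lo <- mean(vapply(1:100, function(s) length(
    sample_lab_times(30, 0.4, informative = TRUE, seed = s, il6_at = lo)), numeric(1)))
  expect_gt(n_hi, n_lo)
  expect_error(sample_lab_times(-1, 0.5), "duration")
})

test_that("re-simulation with identical doses reproduces the factual trajectory", {
  es <- fixture_small_cohort()
  run <- resimulate(es)   # behavior policy, same noise
  expect_equal(run$dense$il6, es$truth$dense$il6, tolerance = 1e-12)
  expect_equal(run$dense$map, es$truth$dense$map, tolerance = 1e-12)
})
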