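test_that("the reward matches the printed coefficients by hand arithmetic", {
  # MAP 75, AUC 100, rp 50, rk 12: 2.0 - 1.0 - 0.25 - 0.04
  expect_equal(compute_reward(75, 100, 50, 12), 0.71)
  expect_equal(compute_reward(60, 0, 0, 0), 0)          # all terms vanish
  expect_equal(compute_reward(70, 0, 0, 10), 2.0)       # hinge inactive below rk_ref
  # upper bound: R <= alpha for admissible inputs
  set.seed(1)
  r <- compute_reward(runif(500, 40, 110), runif(500, 0, 3000),
                      runif(500, 0, 100), runif(500, 0, 20))
  expect_true(all(r <= 2.0 + 1e-12))
})

test_that("hard projection clips to the box and rate limits, idempotently", {
  # ceiling clip: proposed absolute 110 -> 100
  p <- project_action(d_rp = 15, rk = 0, rp_prev = 95, rk_prev = 0)
  expect_equal(p$rp, 100)
  # rate-limit clip: previous 50, proposed +25 -> +20 -> 70
  p <- project_action(d_rp = 25, rk = 0, rp_prev = 50, rk_prev = 0)
  expect_equal(p$rp, 70)
  # ketamine box clip both ways
  expect_equal(project_action(0, 25, 50, 18)$rk, 20)
  expect_equal(project_action(0, -3, 50, 2)$rk, 0)
  # property: 10^4 random proposals land in the box within the step limits,
  # and projection is idempotent
  set.seed(2)
  n <- 10000
  d <- runif(n, -60, 60); rk <- runif(n, -10, 40)
  rp0 <- runif(n, 0, 100); rk0 <- runif(n, 0, 20)
  pr <- project_action(d, rk, rp0, rk0)
  expect_false(any(violates_constraints(pr$rp, pr$rk, rp0, rk0)))
  pr2 <- project_action(pr$d_rp, pr$rk, rp0, rk0)
  expect_equal(pr2$rp, pr$rp, tolerance = 1e-12)
  expect_equal(pr2$rk, pr$rk, tolerance = 1e-12)
  # without projection, adversarial proposals do violate the constraints
  expect_true(any(violates_constraints(rp0 + d, rk, rp0, rk0)))
})

test_that("transitions carry reward consistent with their own fields", {
  tx <- fixture_transitions()
  es <- fixture_small_cohort()
  expect_true(all(c("reward", "log_prop", "terminal") %in% names(tx)))
  expect_true(all(is.finite(tx$reward)))
  expect_true(all(tx$reward <= 2.0 + 1e-9))
  # one terminal flag per episode, at its last decision step
  term <- tapply(tx$terminal, tx$episode_id, function(x) which(x))
  expect_true(all(vapply(split(tx$terminal, tx$episode_id),
                         function(x) sum(x) == 1 && x[length(x)], logical(1))))
})

test_that("CQL training is seeded and pessimistic about out-of-distribution actions", {
  # crisp action-dependent rewards make the conservative gap visible
  tx <- linear_behavior_transitions(n_ep = 300, steps = 1, seed = 5)
  agent <- cql_train(tx, cql_config(steps = 400L, n_q = 2L, cql_weight = 2,
                                    bc_alpha = 2.5, bc_weight = 0,
                                    batch = 256L, n_step = 1L),
                     seed = 31)
  S <- do.call(rbind, tx$state)
  A_data <- pmin(pmax(ctdose:::action_to_unit(tx$d_rp, tx$rk), -1), 1)
  set.seed(3)
  A_rand <- matrix(runif(nrow(S) * 2, -1, 1), ncol = 2)
  q_data <- mean(q_ensemble(agent, S, A_data)$q)
  q_rand <- mean(q_ensemble(agent, S, A_rand)$q)
  expect_lt(q_rand, q_data)   # conservative gap

  a2 <- cql_train(fixture_transitions(), cql_config(steps = 50L, n_q = 2L), seed = 99)
  a3 <- cql_train(fixture_transitions(), cql_config(steps = 50L, n_q = 2L), seed = 99)
  expect_identical(a2$loss_history, a3$loss_history)
  expect_error(cql_train(fixture_transitions()[0, ]), "empty")
})

test_that("a larger conservative penalty pulls actions toward the data", {
  # reward increasing in the action beyond the data support, so an
  # unpenalized critic invites out-of-distribution drift; anchoring off in
  # both arms to isolate the critic penalty
  tx <- linear_behavior_transitions(n_ep = 300, steps = 1, seed = 6,
                                    reward_fn = function(a) a[1])
  lo <- cql_train(tx, cql_config(steps = 600L, n_q = 2L, cql_weight = 0,
                                 bc_alpha = 2.5, bc_weight = 0, batch = 256L,
                                 n_step = 1L), seed = 21)
  hi <- cql_train(tx, cql_config(steps = 600L, n_q = 2L, cql_weight = 10,
                                 bc_alpha = 2.5, bc_weight = 0, batch = 256L,
                                 n_step = 1L), seed = 21)
  S <- do.call(rbind, tx$state)
  A_data <- ctdose:::action_to_unit(tx$d_rp, tx$rk)
  dist_to_data <- function(agent) {
    A <- ctdose:::actor_eval(agent$theta, S)
    mean(vapply(seq_len(nrow(A)), function(i) {
      min(sqrt(rowSums(sweep(A_data, 2, A[i, ])^2)))
    }, numeric(1)))
  }
  expect_lt(dist_to_data(hi), dist_to_data(lo))
})

test_that("confidence scoring ramps, gates and names the failing component", {
  ramps <- fit_confidence_ramps(pi_widths = runif(100, 0.2, 2),
                                densities = runif(100, 0, 10),
                                q_vars = runif(100, 0, 0.5))
  best <- confidence_score(0.01, 0, 0.0001, ramps)
  expect_equal(best$score, 5, tolerance = 1e-6)
  expect_false(best$abstain)
  # stale labs drive the density component to the floor and the reason names it
  stale <- confidence_score(0.5, 14, 0.0001, ramps)
  expect_true(stale$abstain)
  expect_match(stale$reason, "lab result")
  # mid-range inputs land between the threshold and 5 -> recommend
  mid <- confidence_score(0.6, 2, 0.05, ramps)
  expect_gt(mid$score, 2.5); expect_lt(mid$score, 5)
  expect_false(mid$abstain)
  # abstain monotonicity: widening the PI never raises the score
  widths <- seq(0.1, 3, by = 0.2)
  scores <- vapply(widths, function(w) confidence_score(w, 2, 0.05, ramps)$score,
                   numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("recommendations honor every safety constraint and degrade to abstain", {
  es <- fixture_small_cohort()
  ids <- es$static$episode_id[1:8]
  rec <- recommend(es, fixture_agent(), fixture_model(), fixture_ramps(),
                   episode_ids = ids)
  expect_equal(sum(rec$violation), 0L)
  expect_true(all(abs(rec$delta_propofol) <= 20 + 1e-9))
  expect_true(all(rec$ketamine_rate >= 0 & rec$ketamine_rate <= 20))
  # degraded data (75% of labs masked) abstains at least as often
  rec_masked <- recommend(mask_labs(es, 0.75, seed = 8), fixture_agent(),
                          fixture_model(), fixture_ramps(), episode_ids = ids)
  expect_gte(mean(rec_masked$abstained), mean(rec$abstained))
})
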