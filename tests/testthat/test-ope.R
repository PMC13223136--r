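test_that("behavior cloning recovers a linear behavior rule", {
  tx <- linear_behavior_transitions(n_ep = 400, steps = 1, seed = 5)
  bc <- fit_behavior_cloning(tx)
  # true mean functions: d_rp = 2 s1 - s2, rk = 1 + s3
  expect_equal(as.numeric(bc$coef$d_rp), c(0, 2, -1, 0, 0), tolerance = 0.25)
  expect_equal(as.numeric(bc$coef$rk), c(1, 0, 0, 1, 0), tolerance = 0.25)
})

test_that("identity policy gives unit weights so IS and WIS equal the mean return", {
  tx <- linear_behavior_transitions(n_ep = 60, steps = 3, seed = 6)
  # the exact behavior policy as target: densities match the logged propensities
  behavior_as_target <- list(
    action = function(S) tibble::tibble(d_rp = 2 * S[, 1] - S[, 2], rk = 1 + S[, 3]),
    log_density = function(S, d_rp, rk) {
      stats::dnorm(d_rp, 2 * S[, 1] - S[, 2], 1, log = TRUE) +
        stats::dnorm(rk, 1 + S[, 3], 0.5, log = TRUE)
    })
  r <- ope_is_wis(tx, behavior_as_target, discount = 0.99)
  emp <- mean(tapply(seq_len(nrow(tx)), tx$episode_id, function(i) {
    sum(tx$reward[i] * 0.99^(seq_along(i) - 1))
  }))
  expect_equal(r$value[r$estimator == "IS"], emp, tolerance = 1e-10)
  expect_equal(r$value[r$estimator == "WIS"], emp, tolerance = 1e-10)
})

test_that("IS matches the enumerable two-action bandit expectation", {
  # one state, two actions (a = -1 or +1), behavior uniform, reward 1[a = +1]
  set.seed(8)
  n <- 4000
  a <- sample(c(-1, 1), n, replace = TRUE)
  tx <- tibble::tibble(
    episode_id = sprintf("b%04d", seq_len(n)), t_h = 0,
    d_rp = a, rk = 0, reward = as.numeric(a > 0),
    log_prop = log(0.5), terminal = TRUE,
    state = I(replicate(n, c(0, 0), simplify = FALSE)),
    next_state = I(replicate(n, c(0, 0), simplify = FALSE)))
  class(tx) <- c("ctdose_transitions", class(tx))
  # target: always pick +1; density as a point mass smeared over the two atoms
  target <- list(
    action = function(S) tibble::tibble(d_rp = 1, rk = 0),
    log_density = function(S, d_rp, rk) ifelse(d_rp > 0, log(1), log(1e-12)))
  r <- ope_is_wis(tx, target, discount = 1)
  # brute-force oracle: E_target[reward] = 1
  expect_equal(r$value[r$estimator == "IS"], 1, tolerance = 0.05)
  # WIS self-normalization is exact here
  expect_equal(r$value[r$estimator == "WIS"], 1, tolerance = 1e-9)
})

test_that("DR collapses to per-decision IS with a zero value model", {
  tx <- linear_behavior_transitions(n_ep = 50, steps = 1, seed = 9)
  pol <- deterministic_policy(function(S) tibble::tibble(d_rp = 0.5, rk = 1))
  dr0 <- ope_dr(tx, pol, fqe = NULL, discount = 1)
  w <- ctdose:::step_weights(tx, pol)
  expect_equal(dr0$value, mean(w * tx$reward), tolerance = 1e-12)
})

test_that("FQE solves a tabular chain exactly and respects the geometric bound", {
  # 3-state deterministic chain s1 -> s2 -> s3 (terminal), rewards 1, 2, 3
  onehot <- function(i) as.numeric(seq_len(3) == i)
  mk <- function(rep_i) {
    rows <- list()
    for (r in seq_len(rep_i)) {
      for (s in 1:3) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          episode_id = sprintf("c%02d", r), t_h = s,
          d_rp = 0, rk = 0, reward = s, log_prop = log(1),
          terminal = s == 3,
          state = I(list(onehot(s))),
          next_state = I(list(onehot(min(s + 1, 3)))))
      }
    }
    out <- dplyr::bind_rows(rows)
    class(out) <- c("ctdose_transitions", class(out))
    out
  }
  tx <- mk(4)
  pol <- deterministic_policy(function(S) tibble::tibble(d_rp = 0, rk = 0))
  gamma <- 0.9
  fqe <- ope_fqe(tx, pol, discount = gamma, iterations = 60,
                 featurize = function(S, A) S, ridge = 1e-10)
  # exact policy evaluation: V(s1) = 1 + g*2 + g^2*3
  oracle <- 1 + gamma * 2 + gamma^2 * 3
  expect_equal(fqe$value, oracle, tolerance = 1e-3)
  # value estimates approach the oracle monotonically with iterations
  errs <- vapply(c(1, 3, 6, 12), function(it) {
    abs(ope_fqe(tx, pol, discount = gamma, iterations = it,
                featurize = function(S, A) S, ridge = 1e-10)$value - oracle)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  # geometric bound: |value| <= max reward / (1 - gamma)
  expect_lte(abs(fqe$value), 3 / (1 - gamma))
})

test_that("with an accurate value model DR has lower variance than IS", {
  # bandit with known E[r | a]: q(a) = a1; behavior N(0,1), target N(0.5, 1)
  one_draw <- function(seed) {
    set.seed(seed)
    n <- 40
    a <- rnorm(n)
    tx <- tibble::tibble(
      episode_id = sprintf("d%03d", seq_len(n)), t_h = 0,
      d_rp = a, rk = 0, reward = a + rnorm(n, 0, 0.1),
      log_prop = dnorm(a, 0, 1, log = TRUE), terminal = TRUE,
      state = I(replicate(n, 1, simplify = FALSE)),
      next_state = I(replicate(n, 1, simplify = FALSE)))
    class(tx) <- c("ctdose_transitions", class(tx))
    pol <- list(action = function(S) tibble::tibble(d_rp = 0.5, rk = 0),
                log_density = function(S, d_rp, rk) dnorm(d_rp, 0.5, 1, log = TRUE))
    perfect_q <- tibble::tibble(estimator = "FQE", value = 0.5)
    attr(perfect_q, "beta") <- NULL
    # emulate a perfect value model via the featurize/beta hook
    attr(perfect_q, "featurize") <- function(S, A) matrix(A[, 1], ncol = 1)
    attr(perfect_q, "beta") <- matrix(1)
    c(is = ope_is_wis(tx, pol, discount = 1)$value[1],
      dr = ope_dr(tx, pol, fqe = perfect_q, discount = 1)$value)
  }
  reps <- vapply(1:200, one_draw, numeric(2))
  expect_lt(var(reps["dr", ]), var(reps["is", ]))
  # both unbiased for the target value E[a] = 0.5
  expect_equal(mean(reps["dr", ]), 0.5, tolerance = 0.05)
})

test_that("normalization makes every estimator exactly 1.000 on behavior cloning", {
  tx <- fixture_transitions()
  res <- ope_evaluate(tx, list(rule_based = rule_based_policy()))
  bc <- res[res$policy == "BC", ]
  expect_equal(nrow(bc), 4L)
  expect_setequal(bc$estimator, c("IS", "WIS", "DR", "FQE"))
  expect_identical(bc$normalized, rep(1, 4))
})

test_that("rule-based policy follows its titration rules", {
  pol <- rule_based_policy()
  S <- matrix(0, 3, 18)
  S[, 9] <- c(70, 52.5, 52.5) / 60   # depth above target, at target, at target
  S[, 1] <- c(80, 80, 60) / 80       # MAP fine, fine, hypotensive
  a <- pol$action(S)
  expect_gt(a$d_rp[1], 0)
  expect_equal(a$d_rp[2], 0)
  expect_lte(a$d_rp[3], -6)
  expect_true(all(a$rk == 0))        # the protocol has no ketamine arm
})

test_that("ground-truth rollouts are deterministic and policy-faithful", {
  es <- fixture_small_cohort()
  ro1 <- rollout_in_environment(es, list(behavior = NULL, rule = list(rule = TRUE)),
                                model = fixture_model())
  ro2 <- rollout_in_environment(es, list(behavior = NULL, rule = list(rule = TRUE)),
                                model = fixture_model())
  expect_identical(ro1, ro2)
  # the rule-based arm administers no ketamine
  expect_true(is.nan(ro1$ketamine_mean[ro1$policy == "rule"]) ||
                ro1$ketamine_mean[ro1$policy == "rule"] == 0)
  expect_true(all(ro1$map_band_pct >= 0 & ro1$map_band_pct <= 100))
})

test_that("the reward-weight sweep brackets both objectives and is non-dominated", {
  es <- fixture_small_cohort()
  sw <- pareto_sweep(es, fixture_model(), weights = c(0, 0.5, 1),
                     cql_cfg = cql_config(steps = 60L, n_q = 2L), seed = 3)
  expect_equal(nrow(sw), 3L)
  expect_true(any(sw$pareto))
  # the frontier is non-dominated by construction
  for (i in which(sw$pareto)) {
    expect_false(any(sw$map_obj >= sw$map_obj[i] & sw$il6_obj <= sw$il6_obj[i] &
                       (sw$map_obj > sw$map_obj[i] | sw$il6_obj < sw$il6_obj[i])))
  }
})
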