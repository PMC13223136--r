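# Off-policy evaluation (IS / WIS / DR / FQE), baseline policies, ground-truth
# environment rollouts, and the Pareto sweep over the reward weight.

# A policy, for OPE purposes, is a list with
#   action(S)            -> tibble(d_rp, rk)      (S = policy-state matrix)
#   log_density(S, d_rp, rk) -> numeric           (log action density)
# Deterministic policies are wrapped with a Gaussian smoothing kernel so
# densities exist; see `deterministic_policy()`.

#' Wrap a deterministic action rule as an OPE policy
#'
#' @param action_fn function(S) returning a data frame with `d_rp`, `rk`.
#' @param sigma Gaussian smoothing scales (propofol change, ketamine rate)
#'   used to define the action density of the otherwise deterministic rule.
#' @return An OPE policy object.
#' @export
deterministic_policy <- function(action_fn, sigma = c(2.5, 0.75)) {
  list(
    action = action_fn,
    log_density = function(S, d_rp, rk) {
      a <- action_fn(S)
      stats::dnorm(d_rp, a$d_rp, sigma[1], log = TRUE) +
        stats::dnorm(rk, a$rk, sigma[2], log = TRUE)
    }
  )
}

#' Behavior cloning
#'
#' Maximum-likelihood linear-Gaussian imitation of the logged clinician
#' actions: a linear mean function per action dimension with a diagonal
#' residual scale. Doubles as the fitted behavior-density model for IS/WIS
#' when exact simulator propensities are not requested.
#'
#' @param transitions A `ctdose_transitions` table.
#' @return A `bc_policy` (also a valid OPE policy object).
#' @export
fit_behavior_cloning <- function(transitions) {
  if (!nrow(transitions)) stop("empty transition dataset", call. = FALSE)
  S <- do.call(rbind, transitions$state)
  fit1 <- stats::lm.fit(cbind(1, S), transitions$d_rp)
  fit2 <- stats::lm.fit(cbind(1, S), transitions$rk)
  s1 <- max(stats::sd(fit1$residuals), 1e-3)
  s2 <- max(stats::sd(fit2$residuals), 1e-3)
  b1 <- fit1$coefficients; b2 <- fit2$coefficients
  b1[is.na(b1)] <- 0; b2[is.na(b2)] <- 0
  pol <- list(
    coef = list(d_rp = b1, rk = b2, sd = c(s1, s2)),
    action = function(S) {
      tibble::tibble(d_rp = as.numeric(cbind(1, S) %*% b1),
                     rk = pmax(as.numeric(cbind(1, S) %*% b2), 0))
    },
    log_density = function(S, d_rp, rk) {
      stats::dnorm(d_rp, as.numeric(cbind(1, S) %*% b1), s1, log = TRUE) +
        stats::dnorm(rk, as.numeric(cbind(1, S) %*% b2), s2, log = TRUE)
    }
  )
  class(pol) <- "bc_policy"
  pol
}

#' Rule-based anesthesia protocol
#'
#' Proportional propofol titration toward the depth target (45-60 band
#' midpoint), a hard propofol cut when MAP < 65 mmHg, and no ketamine (the
#' protocol has no ketamine arm). Operates on the policy-state matrix.
#'
#' @param depth_target Depth set point.
#' @return An OPE policy object (deterministic, Gaussian-smoothed density).
#' @export
rule_based_policy <- function(depth_target = 52.5) {
  act <- function(S) {
    depth <- S[, 9] * 60
    map <- S[, 1] * 80
    d_rp <- 0.35 * (depth - depth_target)
    d_rp <- ifelse(map < 65, pmin(d_rp, -6), d_rp)
    tibble::tibble(d_rp = d_rp, rk = 0)
  }
  deterministic_policy(act)
}

#' Wrap a trained CPQL agent as an OPE policy
#'
#' @param agent A `cpql_agent`.
#' @param project Apply the safety projection inside the policy (requires the
#'   previous rates to be part of the state; uses state columns 7-8).
#' @param sigma Smoothing scales for the action density.
#' @return An OPE policy object.
#' @export
agent_policy <- function(agent, project = TRUE, sigma = c(2.5, 0.75)) {
  act <- function(S) {
    a <- agent_action(agent, S)
    if (project) {
      pr <- project_action(a$d_rp, a$rk, S[, 7] * 50, S[, 8] * 10, agent$safety)
      a <- tibble::tibble(d_rp = pr$d_rp, rk = pr$rk)
    }
    a
  }
  deterministic_policy(act, sigma)
}

# ---- returns and importance weights ----------------------------------------

episode_returns <- function(transitions, discount) {
  out <- dplyr::summarise(
    dplyr::group_by(transitions, .data$episode_id),
    ret = sum(.data$reward * discount^(seq_along(.data$reward) - 1)),
    .groups = "drop")
  out
}

# per-step importance ratios, clipped; behavior density from the logged
# propensities unless a fitted behavior model is supplied
step_weights <- function(transitions, policy, behavior = NULL, clip = 100) {
  S <- do.call(rbind, transitions$state)
  lp_t <- policy$log_density(S, transitions$d_rp, transitions$rk)
  lp_b <- if (is.null(behavior)) transitions$log_prop else
    behavior$log_density(S, transitions$d_rp, transitions$rk)
  w <- exp(lp_t - lp_b)
  pmin(w, clip)
}

#' Importance-sampling and weighted importance-sampling OPE
#'
#' Per-trajectory product weights of clipped per-step ratios; IS is the
#' weighted average of discounted returns, WIS the self-normalized variant
#' (weights sum to one).
#'
#' @param transitions A `ctdose_transitions` table.
#' @param policy Target OPE policy.
#' @param behavior Optional fitted behavior model; default uses the exact
#'   logged propensities.
#' @param discount Discount factor.
#' @param clip Per-step weight cap.
#' @return Tibble with rows `IS` and `WIS` (`estimator`, `value`,
#'   `n_episodes`, `n_excluded`).
#' @export
ope_is_wis <- function(transitions, policy, behavior = NULL, discount = 0.99,
                       clip = 100) {
  w <- step_weights(transitions, policy, behavior, clip)
  bad <- !is.finite(w)
  tx <- transitions
  tx$w <- ifelse(bad, NA, w)
  per_ep <- dplyr::summarise(
    dplyr::group_by(tx, .data$episode_id),
    W = prod(.data$w),
    ret = sum(.data$reward * discount^(seq_along(.data$reward) - 1)),
    .groups = "drop")
  excl <- sum(!is.finite(per_ep$W))
  per_ep <- per_ep[is.finite(per_ep$W), ]
  tibble::tibble(
    estimator = c("IS", "WIS"),
    value = c(mean(per_ep$W * per_ep$ret),
              sum(per_ep$W * per_ep$ret) / sum(per_ep$W)),
    n_episodes = nrow(per_ep), n_excluded = excl
  )
}

#' Fitted Q-evaluation
#'
#' Iterative ridge regression of Bellman targets under the target policy on a
#' feature map of (state, action); the value is the mean initial-state Q at
#' the policy action.
#'
#' @param transitions A `ctdose_transitions` table.
#' @param policy Target OPE policy.
#' @param discount Discount factor.
#' @param iterations Bellman iterations.
#' @param featurize function(S, A) returning the regression design matrix;
#'   the default is a linear-plus-interaction basis.
#' @param ridge Ridge penalty.
#' @return Tibble row (`estimator = "FQE"`, `value`, plus the fitted
#'   coefficients as an attribute used by [ope_dr()]).
#' @export
ope_fqe <- function(transitions, policy, discount = 0.99, iterations = 50L,
                    featurize = NULL, ridge = 1e-3) {
  S <- do.call(rbind, transitions$state)
  Sn <- do.call(rbind, transitions$next_state)
  A <- cbind(transitions$d_rp, transitions$rk)
  if (is.null(featurize)) {
    # quadratic basis on unit-scaled actions (conditioning)
    featurize <- function(S, A) {
      An <- cbind(A[, 1] / 15, A[, 2] / 10)
      cbind(1, S, An, An^2, An[, 1] * S, An[, 2] * S)
    }
  }
  an <- policy$action(Sn)
  An <- cbind(an$d_rp, an$rk)
  X <- featurize(S, A)
  Xn <- featurize(Sn, An)
  XtX <- crossprod(X) + ridge * diag(ncol(X))
  r <- transitions$reward
  nonterm <- 1 - as.numeric(transitions$terminal)
  beta <- rep(0, ncol(X))
  rmax <- max(abs(r))
  bound <- rmax / (1 - discount) + 1e-6
  for (it in seq_len(iterations)) {
    # bootstrap targets clipped to the geometric bound (the true Q lies in it)
    qn <- pmin(pmax(as.numeric(Xn %*% beta), -bound), bound)
    y <- r + discount * nonterm * qn
    beta <- solve(XtX, crossprod(X, y))
  }
  v0 <- as.numeric(X %*% beta)
  if (mean(abs(v0)) > bound) {
    stop("FQE diverged: values exceed the geometric reward bound", call. = FALSE)
  }
  first <- !duplicated(transitions$episode_id)
  a0 <- policy$action(S[first, , drop = FALSE])
  X0 <- featurize(S[first, , drop = FALSE], cbind(a0$d_rp, a0$rk))
  # the basis can extrapolate at off-data policy actions; the true Q lies
  # within the geometric bound, so readouts are clipped to it
  q0 <- pmin(pmax(as.numeric(X0 %*% beta), -bound), bound)
  out <- tibble::tibble(estimator = "FQE",
                        value = mean(q0),
                        n_episodes = sum(first), n_excluded = 0L)
  attr(out, "beta") <- beta
  attr(out, "featurize") <- featurize
  attr(out, "bound") <- bound
  out
}

#' Doubly robust OPE
#'
#' Standard per-decision doubly robust estimator combining the FQE value
#' model with importance-weighted TD residuals; with a zero value model it
#' collapses to per-decision IS.
#'
#' @param transitions A `ctdose_transitions` table.
#' @param policy Target OPE policy.
#' @param behavior Optional fitted behavior model (default: exact logged
#'   propensities).
#' @param fqe Result of [ope_fqe()] for the same policy, or `NULL` for a zero
#'   value model.
#' @param discount Discount factor.
#' @param clip Per-step weight cap.
#' @return Tibble row (`estimator = "DR"`).
#' @export
ope_dr <- function(transitions, policy, behavior = NULL, fqe = NULL,
                   discount = 0.99, clip = 100) {
  S <- do.call(rbind, transitions$state)
  if (is.null(fqe)) {
    qhat <- function(S, A) rep(0, nrow(S))
  } else {
    beta <- attr(fqe, "beta"); featurize <- attr(fqe, "featurize")
    bound <- attr(fqe, "bound")
    if (is.null(bound)) bound <- Inf
    qhat <- function(S, A) {
      pmin(pmax(as.numeric(featurize(S, A) %*% beta), -bound), bound)
    }
  }
  w_step <- step_weights(transitions, policy, behavior, clip)
  q_sa <- qhat(S, cbind(transitions$d_rp, transitions$rk))
  a_pi <- policy$action(S)
  v_s <- qhat(S, cbind(a_pi$d_rp, a_pi$rk))
  tx <- tibble::tibble(episode_id = transitions$episode_id,
                       r = transitions$reward, w = w_step, q = q_sa, v = v_s)
  ep <- split(tx, tx$episode_id)
  # per-decision DR: sum_t gamma^(t-1) [ W_{t-1} V(s_t) + W_t (r_t - Q(s_t, a_t)) ]
  vals <- vapply(ep, function(e) {
    W <- 1
    total <- 0
    for (t in seq_len(nrow(e))) {
      gt <- discount^(t - 1)
      Wt <- W * e$w[t]
      total <- total + gt * (W * e$v[t] + Wt * (e$r[t] - e$q[t]))
      W <- Wt
    }
    total
  }, numeric(1))
  tibble::tibble(estimator = "DR", value = mean(vals),
                 n_episodes = length(vals), n_excluded = 0L)
}

#' Run all four OPE estimators for a set of policies
#'
#' Values are reported raw and normalized so that behavior cloning equals
#' 1.000 exactly per estimator. The normalization is the plain ratio to the
#' BC value; when returns are negative (penalty-dominated rewards), a
#' normalized value below 1 indicates an improvement over BC.
#'
#' @param transitions A `ctdose_transitions` table.
#' @param policies Named list of OPE policies; a `BC` entry is fitted
#'   automatically when absent.
#' @param behavior Optional fitted behavior model for the densities (default:
#'   exact logged propensities).
#' @param discount Discount factor.
#' @return Tidy tibble: `policy`, `estimator`, `value`, `normalized`.
#' @export
ope_evaluate <- function(transitions, policies, behavior = NULL,
                         discount = 0.99) {
  if (!"BC" %in% names(policies)) {
    policies <- c(list(BC = fit_behavior_cloning(transitions)), policies)
  }
  rows <- list()
  for (nm in names(policies)) {
    pol <- policies[[nm]]
    iswis <- ope_is_wis(transitions, pol, behavior, discount)
    fqe <- ope_fqe(transitions, pol, discount)
    dr <- ope_dr(transitions, pol, behavior, fqe, discount)
    rows[[nm]] <- dplyr::bind_rows(iswis, dr, fqe)
    rows[[nm]]$policy <- nm
  }
  out <- dplyr::bind_rows(rows)
  bc <- out[out$policy == "BC", c("estimator", "value")]
  out$normalized <- out$value / bc$value[match(out$estimator, bc$estimator)]
  out[, c("policy", "estimator", "value", "normalized", "n_episodes", "n_excluded")]
}

# ---- environment rollouts ---------------------------------------------------

# adapt an OPE/agent policy to the simulator's state-tibble interface,
# propagating the forecaster latent under the policy's own doses and applying
# projection and the abstain gate when configured
make_sim_policy <- function(policy_action, es, model = NULL, agent = NULL,
                            project_cfg = safety_config(), project = TRUE,
                            ramps = NULL, abstain_cfg = abstain_config()) {
  Zstate <- new.env(parent = emptyenv())
  unsafe <- new.env(parent = emptyenv())
  unsafe$n_unsafe <- 0L; unsafe$n_viol <- 0L; unsafe$n <- 0L; unsafe$n_abstain <- 0L
  needs_latent <- !is.null(model)
  if (needs_latent) {
    t_grid <- es$truth$t_h
    lat0 <- episode_latents(es, model, es$static$episode_id, t_grid[1:13])
    for (id in names(lat0)) Zstate[[id]] <- lat0[[id]][13, ]  # z at 1 h
  }
  piw <- NULL
  if (!is.null(ramps) && !is.null(model)) {
    fc <- forecast_episodes(model, es, origins_h = 2)
    fc <- fc[fc$cytokine == "il6" & fc$horizon_h == 12, ]
    piw <- (fc$hi90 - fc$lo90) / pmax(fc$mean, 1)
    names(piw) <- fc$episode_id
  }
  dt <- 5 / 60
  fn <- function(state) {
    n <- nrow(state)
    S <- NULL
    if (needs_latent) {
      L <- t(vapply(state$episode_id, function(id) Zstate[[id]], numeric(length(Zstate[[state$episode_id[1]]]))))
      st <- tibble::tibble(
        map_roll = state$map, hr_roll = state$hr_base, spo2_roll = 97,
        cum_rp = state$cum_rp, cum_rk = state$cum_rk, rv = state$rv,
        rp_prev = state$rp_prev, rk_prev = state$rk_prev,
        depth = state$depth, t_h = state$t_h
      )
      S <- policy_state_matrix(st, L)
    }
    a <- policy_action(state, S)
    unsafe$n <- unsafe$n + n
    raw_rp <- state$rp_prev + a$d_rp
    unsafe$n_unsafe <- unsafe$n_unsafe +
      sum(violates_constraints(raw_rp, a$rk, state$rp_prev, state$rk_prev, project_cfg))
    if (project) {
      pr <- project_action(a$d_rp, a$rk, state$rp_prev, state$rk_prev, project_cfg)
      a$d_rp <- pr$d_rp; a$rk <- pr$rk
    }
    unsafe$n_viol <- unsafe$n_viol +
      sum(violates_constraints(state$rp_prev + a$d_rp, a$rk,
                               state$rp_prev, state$rk_prev, project_cfg))
    if (!is.null(ramps) && !is.null(agent) && !is.null(S)) {
      qv <- q_ensemble(agent, S)$variance
      conf <- confidence_score(piw[state$episode_id], 2, qv, ramps, abstain_cfg)
      hold <- conf$abstain
      unsafe$n_abstain <- unsafe$n_abstain + sum(hold)
      a$d_rp[hold] <- 0
      a$rk[hold] <- state$rk_prev[hold]
    }
    if (needs_latent) {
      # advance each episode's latent one decision step under the chosen doses
      u <- cbind(pmin(pmax(state$rp_prev + a$d_rp, 0), 110) / model$cfg$u_scale[1],
                 pmax(a$rk, 0) / model$cfg$u_scale[2],
                 state$rv / model$cfg$u_scale[3])
      tf <- dyn_time_features(state$t_h)
      U <- cbind(u, tf)
      Z <- t(vapply(state$episode_id, function(id) Zstate[[id]], numeric(ncol(L))))
      dyn <- function(Z, U) mlp_eval(model$theta, cbind(Z, U), 3L, "dyn")
      k1 <- dyn(Z, U); k2 <- dyn(Z + dt / 2 * k1, U)
      k3 <- dyn(Z + dt / 2 * k2, U); k4 <- dyn(Z + dt * k3, U)
      Z <- Z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      for (j in seq_len(n)) Zstate[[state$episode_id[j]]] <- Z[j, ]
    }
    tibble::tibble(d_rp = a$d_rp, rk = a$rk)
  }
  list(fn = fn, stats = unsafe)
}

#' Roll out policies in the ground-truth environment
#'
#' Re-simulates each episode under each policy using the stored noise streams
#' (counterfactual consistency) and computes the outcome statistics: MAP
#' band/hypotension time, MAP coefficient of variation, vasopressor
#' initiation, IL-6 AUC, CRP peak, spike rate, IL-6/IL-10 ratio at 24 h, drug
#' exposure, unsafe-action and constraint-violation percentages and abstain
#' rate. An unsafe action is a pre-projection proposal outside the dose box
#' or rate limits; a violation is a post-projection breach.
#'
#' @param es A simulated `episode_set`.
#' @param policies Named list: each entry either `NULL` (behavior policy), an
#'   OPE policy (rule-based/BC), or a list with `agent` (+ optional `project
#'   = FALSE`, `abstain = TRUE`) for CPQL-style agents.
#' @param model Forecaster (needed for agent policies).
#' @param ramps Confidence ramps (enables the abstain gate for agents).
#' @param horizon_h Outcome window (default 24 h).
#' @return Tidy outcome tibble, one row per policy.
#' @export
rollout_in_environment <- function(es, policies, model = NULL, ramps = NULL,
                                   horizon_h = 24) {
  out <- list()
  for (nm in names(policies)) {
    spec <- policies[[nm]]
    stats_env <- NULL
    if (is.null(spec)) {
      run <- resimulate(es)
    } else if (!is.null(spec$agent)) {
      project <- !isFALSE(spec$project)
      sp <- make_sim_policy(
        function(state, S) agent_action(spec$agent, S),
        es, model = model, agent = spec$agent,
        project_cfg = spec$agent$safety, project = project,
        ramps = if (isTRUE(spec$abstain)) ramps else NULL
      )
      run <- resimulate(es, policy = sp$fn)
      stats_env <- sp$stats
    } else {
      sp <- make_sim_policy(
        function(state, S) {
          depth <- state$depth; map <- state$map
          d_rp <- 0.35 * (depth - 52.5)
          d_rp <- ifelse(map < 65, pmin(d_rp, -6), d_rp)
          if (!is.null(spec$action_state_fn)) spec$action_state_fn(state)
          else tibble::tibble(d_rp = d_rp, rk = 0)
        }, es, model = NULL, project = TRUE)
      run <- resimulate(es, policy = sp$fn)
      stats_env <- sp$stats
    }
    out[[nm]] <- rollout_stats(es, run, horizon_h, stats_env)
    out[[nm]]$policy <- nm
  }
  dplyr::bind_rows(out)[, c("policy", setdiff(names(out[[1]]), "policy"))]
}

rollout_stats <- function(es, run, horizon_h, stats_env = NULL) {
  t_grid <- run$t_h
  sel <- t_grid <= horizon_h
  map <- run$dense$map[, sel, drop = FALSE]
  il6 <- run$dense$il6[, sel, drop = FALSE]
  crp <- run$dense$crp[, sel, drop = FALSE]
  il10 <- run$dense$il10[, sel, drop = FALSE]
  rp <- run$dense$rp[, sel, drop = FALSE]
  rk <- run$dense$rk[, sel, drop = FALSE]
  w_kg <- es$truth$patients$weight_kg
  dt_min <- (t_grid[2] - t_grid[1]) * 60
  auc <- apply(il6, 1, function(x) sum((utils::head(x, -1) + utils::tail(x, -1)) / 2) *
                 (t_grid[2] - t_grid[1]))
  spikes <- true_spike_labels(
    structure(list(truth = list(dense = list(il6 = il6), t_h = t_grid[sel],
                                patients = es$truth$patients)), class = "episode_set"),
    criterion = "relative")
  i24 <- which.min(abs(t_grid - 24))
  tibble::tibble(
    map_band_pct = 100 * mean(map >= 65 & map <= 90),
    map_below65_pct = 100 * mean(map < 65),
    map_cv_pct = 100 * mean(apply(map, 1, function(x) stats::sd(x) / mean(x))),
    vaso_pct = 100 * mean(run$vaso_started),
    il6_auc = mean(auc),
    crp_peak = mean(apply(crp, 1, max)),
    spike_rate_pct = 100 * mean(spikes$spike),
    il6_il10_24h = mean(run$dense$il6[, i24] / run$dense$il10[, i24]),
    propofol_mg = mean(rowSums(rp) * dt_min * w_kg / 1000),
    ketamine_mean = mean(rk[rk > 0]),
    unsafe_pct = if (!is.null(stats_env) && stats_env$n > 0) 100 * stats_env$n_unsafe / stats_env$n else NA_real_,
    violation_pct = if (!is.null(stats_env) && stats_env$n > 0) 100 * stats_env$n_viol / stats_env$n else NA_real_,
    abstain_pct = if (!is.null(stats_env) && stats_env$n > 0) 100 * stats_env$n_abstain / stats_env$n else NA_real_
  )
}

#' Pareto sweep over the hemodynamic reward weight
#'
#' Re-trains the agent on rewards rescaled by the weight `w` in \\[0, 1\\]
#' (`w = 1`: pure MAP stability; `w = 0`: pure inflammatory/drug objective;
#' `w = 0.5` recovers the default weighting up to scale), evaluates each
#' policy by ground-truth rollout, and flags the non-dominated frontier.
#'
#' @param es Simulated `episode_set`.
#' @param model Trained forecaster.
#' @param weights Weight grid in \\[0, 1\\] (default step 0.05).
#' @param cql_cfg Reduced-budget [cql_config()] used per weight.
#' @param reward_cfg Base [reward_config()].
#' @param seed Integer seed.
#' @return Tibble: `weight`, `map_obj` (% time in band), `il6_obj` (mean
#'   IL-6 AUC), `pareto` (non-dominated flag).
#' @export
pareto_sweep <- function(es, model, weights = seq(0, 1, by = 0.05),
                         cql_cfg = cql_config(steps = 120L, n_q = 2L),
                         reward_cfg = reward_config(), seed = 1L) {
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]", call. = FALSE)
  rows <- list()
  for (w in weights) {
    rc <- reward_cfg
    rc$alpha <- 2 * w * reward_cfg$alpha
    rc$beta <- 2 * (1 - w) * reward_cfg$beta
    rc$gamma <- 2 * (1 - w) * reward_cfg$gamma
    rc$delta <- 2 * (1 - w) * reward_cfg$delta
    tx <- build_transitions(es, model, reward_cfg = rc)
    agent <- cql_train(tx, cql_cfg, seed = seed)
    ro <- rollout_in_environment(es, list(pol = list(agent = agent)), model = model)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      weight = w, map_obj = ro$map_band_pct, il6_obj = ro$il6_auc)
  }
  out <- dplyr::bind_rows(rows)
  out$pareto <- vapply(seq_len(nrow(out)), function(i) {
    !any(out$map_obj >= out$map_obj[i] & out$il6_obj <= out$il6_obj[i] &
           (out$map_obj > out$map_obj[i] | out$il6_obj < out$il6_obj[i]))
  }, logical(1))
  out
}

#' Mean discounted return of a simulated run
#'
#' Computes each episode's discounted sum of rewards over its operative-window
#' decision steps from a ground-truth simulation run (factual or
#' counterfactual), using the true dense IL-6 for the reward's AUC term.
#'
#' @param es The simulated `episode_set` the run derives from.
#' @param run A run from [resimulate()].
#' @param reward_cfg [reward_config()].
#' @param discount Per-step discount.
#' @return Mean per-episode discounted return.
#' @export
simulated_return <- function(es, run, reward_cfg = reward_config(),
                             discount = 0.99) {
  a <- run$actions
  a <- a[order(a$episode_id, a$t_h), ]
  auc <- unlist(lapply(split(a, a$episode_id), function(aa) {
    i <- match(aa$episode_id[1], es$truth$patients$episode_id)
    il6_auc_truth(run$dense$il6[i, ], run$t_h, aa$t_h, 6)
  }))
  r <- compute_reward(a$map, auc, a$rp, a$rk, reward_cfg)
  mean(tapply(seq_len(nrow(a)), a$episode_id,
              function(i) sum(r[i] * discount^(seq_along(i) - 1))))
}
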