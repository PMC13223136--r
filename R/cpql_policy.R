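# The dosing agent: policy state construction, multi-objective reward, hard
# safety projection, conservative Q-learning (continuous actions,
# actor-critic), composite-confidence abstain gate, and the recommendation
# loop.

#' Reward configuration
#'
#' `R = alpha * 1[MAP in band] - beta * IL6_AUC(t, t+6h) - gamma * rp
#' - delta * max(rk - rk_ref, 0)` with the IL-6 area under the curve in
#' pg.h/mL and rates in mcg/kg/min.
#'
#' @param alpha,beta,gamma,delta Reward weights (defaults 2.0, 0.01, 0.005,
#'   0.02).
#' @param rk_ref Ketamine saturation threshold (10 mcg/kg/min) above which
#'   additional ketamine is penalized.
#' @param map_band MAP target band (mmHg).
#' @return List of class `reward_config`.
#' @export
reward_config <- function(alpha = 2.0, beta = 0.01, gamma = 0.005, delta = 0.02,
                          rk_ref = 10, map_band = c(65, 90)) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, delta >= 0)
  structure(as.list(environment()), class = "reward_config")
}

#' Safety configuration
#'
#' Absolute dose ceilings and per-5-min titration rate limits enforced by
#' [project_action()].
#'
#' @param propofol_max,ketamine_max Ceilings (100, 20 mcg/kg/min).
#' @param propofol_step,ketamine_step Per-interval change limits (20, 5).
#' @param d_rp_box Bound of the agent's propofol-adjustment action space
#'   (+/- 15); the effective per-step change is the intersection with the
#'   rate limit.
#' @return List of class `safety_config`.
#' @export
safety_config <- function(propofol_max = 100, ketamine_max = 20,
                          propofol_step = 20, ketamine_step = 5,
                          d_rp_box = 15) {
  stopifnot(propofol_max >= 0, ketamine_max >= 0,
            propofol_step >= 0, ketamine_step >= 0)
  structure(as.list(environment()), class = "safety_config")
}

#' Abstain configuration
#'
#' @param threshold Composite confidence threshold on the 0-5 scale below
#'   which the recommendation is withheld (2.5).
#' @param weights Component weights (PI width, observation density,
#'   Q-ensemble variance); equal by default.
#' @return List of class `abstain_config`.
#' @export
abstain_config <- function(threshold = 2.5,
                           weights = c(pi_width = 1, density = 1, q_var = 1) / 3) {
  stopifnot(threshold >= 0, threshold <= 5, all(weights >= 0))
  structure(list(threshold = threshold, weights = weights / sum(weights)),
            class = "abstain_config")
}

#' Multi-objective dosing reward
#'
#' @param map MAP (mmHg) at the decision step.
#' @param il6_auc Forecast IL-6 area under the curve over the next 6 h
#'   (pg.h/mL).
#' @param rp Propofol rate after the action (mcg/kg/min).
#' @param rk Ketamine rate after the action (mcg/kg/min).
#' @param cfg [reward_config()].
#' @return Reward value(s); bounded above by `alpha`.
#' @export
compute_reward <- function(map, il6_auc, rp, rk, cfg = reward_config()) {
  cfg$alpha * as.numeric(map >= cfg$map_band[1] & map <= cfg$map_band[2]) -
    cfg$beta * il6_auc - cfg$gamma * rp - cfg$delta * pmax(rk - cfg$rk_ref, 0)
}

#' Hard safety projection
#'
#' Clips a proposed action onto the admissible box and the per-interval rate
#' limits, given the previous rates: the propofol change is clipped to the
#' per-5-min step limit (+/- 20), the ketamine change to +/- 5, and the
#' resulting absolute rates to their ceilings. (The +/- 15 proposal box is a
#' property of the agent's action space; arbitrary external proposals are
#' clipped here by the rate limits.) Total and idempotent: never errors on
#' finite input.
#'
#' @param d_rp Proposed propofol rate change (mcg/kg/min).
#' @param rk Proposed ketamine rate (absolute, mcg/kg/min).
#' @param rp_prev,rk_prev Rates before the action.
#' @param cfg [safety_config()].
#' @return List with `rp`, `rk` (post-projection absolute rates), `d_rp`
#'   (post-projection change) and `projected` (logical: proposal modified).
#' @export
project_action <- function(d_rp, rk, rp_prev, rk_prev, cfg = safety_config()) {
  d <- pmin(pmax(d_rp, -cfg$propofol_step), cfg$propofol_step)
  rp <- pmin(pmax(rp_prev + d, 0), cfg$propofol_max)
  rk1 <- pmin(pmax(rk, 0), cfg$ketamine_max)
  rk1 <- pmin(pmax(rk1, rk_prev - cfg$ketamine_step), rk_prev + cfg$ketamine_step)
  rk1 <- pmin(pmax(rk1, 0), cfg$ketamine_max)
  list(rp = rp, rk = rk1, d_rp = rp - rp_prev,
       projected = abs(rp - (rp_prev + d_rp)) > 1e-9 | abs(rk1 - rk) > 1e-9)
}

#' Check an action against the safety constraints
#' @param rp,rk Absolute rates after the action.
#' @param rp_prev,rk_prev Rates before.
#' @param cfg [safety_config()].
#' @return Logical: `TRUE` when any ceiling or rate limit is violated.
#' @export
violates_constraints <- function(rp, rk, rp_prev, rk_prev, cfg = safety_config()) {
  rp < -1e-9 | rp > cfg$propofol_max + 1e-9 |
    rk < -1e-9 | rk > cfg$ketamine_max + 1e-9 |
    abs(rp - rp_prev) > cfg$propofol_step + 1e-9 |
    abs(rk - rk_prev) > cfg$ketamine_step + 1e-9
}

# ---- policy state and transitions ------------------------------------------

# normalize a raw state tibble into the numeric matrix fed to the networks
policy_state_matrix <- function(state, latent) {
  base <- cbind(
    map = state$map_roll / 80, hr = state$hr_roll / 80, spo2 = state$spo2_roll / 100,
    cum_rp = state$cum_rp / 20000, cum_rk = state$cum_rk / 2000,
    rv = state$rv / 0.1, rp_prev = state$rp_prev / 50, rk_prev = state$rk_prev / 10,
    depth = state$depth / 60, t = state$t_h / 24
  )
  cbind(base, latent)
}

#' Build offline transitions from a simulated cohort
#'
#' Harvests (state, action, reward, next state, behavior propensity, terminal)
#' tuples on the 5-min decision grid of the operative window. The state
#' couples 30-min rolling vitals, cumulative doses, current rates and the
#' forecaster's latent z(t), propagated continuously through the episode
#' under the recorded infusions. The reward's IL-6 AUC term uses the
#' simulator's dense truth by default (oracle route) or the forecaster's
#' predicted AUC.
#'
#' @param es A simulated `episode_set` (with truth).
#' @param model A trained `ctdose_forecaster`.
#' @param reward_cfg [reward_config()].
#' @param use_forecast_auc If `TRUE`, the reward uses the forecaster's
#'   trapezoid AUC over the next 6 h instead of the simulator truth.
#' @param episode_ids Episodes to harvest (default: all).
#' @return A tibble of transitions with a `state`/`next_state` matrix column
#'   pair, actions, rewards and log-propensities; class `ctdose_transitions`.
#' @export
build_transitions <- function(es, model, reward_cfg = reward_config(),
                              use_forecast_auc = FALSE, episode_ids = NULL) {
  if (is.null(es$truth)) stop("transitions require simulator truth", call. = FALSE)
  tr <- es$truth
  if (is.null(episode_ids)) episode_ids <- es$static$episode_id
  acts <- tr$actions[tr$actions$episode_id %in% episode_ids, ]
  if (!nrow(acts)) stop("no logged behavior actions", call. = FALSE)
  dense <- tr$dense
  t_grid <- tr$t_h
  dt <- t_grid[2] - t_grid[1]
  lat <- episode_latents(es, model, episode_ids, t_grid)
  rows <- list()
  for (id in unique(acts$episode_id)) {
    a <- acts[acts$episode_id == id, ]
    i <- match(id, tr$patients$episode_id)
    k <- round(a$t_h / dt) + 1L
    # 30-min rolling means over the 5-min dense grid
    roll <- function(x, kk) {
      vapply(kk, function(j) mean(x[max(1, j - 5):j]), numeric(1))
    }
    st <- tibble::tibble(
      episode_id = id, t_h = a$t_h,
      map_roll = roll(dense$map[i, ], k), hr_roll = tr$patients$hr_base[i] +
        0.5 * pmax(65 - roll(dense$map[i, ], k), 0),
      spo2_roll = 97,
      cum_rp = cumsum(dense$rp[i, ])[k] * 5, cum_rk = cumsum(dense$rk[i, ])[k] * 5,
      rv = a$rv, rp_prev = c(tr$patients$rp_init[i], a$rp[-nrow(a)]),
      rk_prev = c(0, a$rk[-nrow(a)]), depth = a$depth
    )
    auc <- il6_auc_truth(dense$il6[i, ], t_grid, a$t_h, 6)
    X <- policy_state_matrix(st, lat[[id]][k, , drop = FALSE])
    kn <- pmin(k + 1L, ncol(dense$map))
    stn <- st
    stn$map_roll <- roll(dense$map[i, ], kn)
    stn$cum_rp <- cumsum(dense$rp[i, ])[kn] * 5
    stn$cum_rk <- cumsum(dense$rk[i, ])[kn] * 5
    stn$rp_prev <- a$rp; stn$rk_prev <- a$rk
    Xn <- policy_state_matrix(stn, lat[[id]][kn, , drop = FALSE])
    r <- compute_reward(dense$map[i, k], auc, a$rp, a$rk, reward_cfg)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      episode_id = id, t_h = a$t_h,
      d_rp = a$rp - st$rp_prev, rk = a$rk,
      reward = r, log_prop = a$log_prop,
      terminal = seq_len(nrow(a)) == nrow(a),
      state = I(asplit(X, 1)), next_state = I(asplit(Xn, 1))
    )
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("ctdose_transitions", class(out)))
}

# true IL-6 AUC over [t, t+w] by trapezoid on the dense grid
il6_auc_truth <- function(il6_row, t_grid, t0, w) {
  vapply(t0, function(tt) {
    sel <- t_grid >= tt & t_grid <= tt + w
    x <- t_grid[sel]; y <- il6_row[sel]
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }, numeric(1))
}

# continuous latent path per episode on the dense grid: encode once early,
# then propagate through the recorded infusions with the learned dynamics.
# Vectorized across episodes (shared time grid, per-episode controls).
episode_latents <- function(es, model, episode_ids, t_grid) {
  enc_h <- 0.5
  eps_ev <- split(es$events, es$events$episode_id)
  Z0 <- t(vapply(episode_ids, function(id) {
    ev <- eps_ev[[id]]
    encode_episode(ev[ev$t_sec <= enc_h * 3600, ], model$encoder)
  }, numeric(model$encoder$cfg$d)))
  Z <- init_latent(Z0, model$theta)
  k <- ncol(Z)
  ctrl <- lapply(episode_ids, function(id) interpolate_controls(eps_ev[[id]]))
  U_at <- function(tt) {
    m <- t(vapply(ctrl, function(f) as.numeric(f(tt)), numeric(3)))
    cbind(sweep(m, 2L, model$cfg$u_scale, "/"),
          dyn_time_features(rep(tt, length(ctrl))))
  }
  out <- array(NA_real_, c(length(episode_ids), length(t_grid), k))
  out[, 1, ] <- Z
  dt <- t_grid[2] - t_grid[1]
  dyn <- function(Z, U) mlp_eval(model$theta, cbind(Z, U), 3L, "dyn")
  for (j in seq_len(length(t_grid) - 1L)) {
    if ("ct" %in% model$ablate) { out[, j + 1L, ] <- Z; next }
    u0 <- U_at(t_grid[j]); um <- U_at(t_grid[j] + dt / 2); u1 <- U_at(t_grid[j + 1L])
    k1 <- dyn(Z, u0); k2 <- dyn(Z + dt / 2 * k1, um)
    k3 <- dyn(Z + dt / 2 * k2, um); k4 <- dyn(Z + dt * k3, u1)
    Z <- Z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[, j + 1L, ] <- Z
  }
  lat <- lapply(seq_along(episode_ids), function(i) out[i, , , drop = TRUE])
  names(lat) <- episode_ids
  lat
}

# ---- conservative Q-learning -----------------------------------------------

#' CQL agent configuration
#'
#' @param q_hidden,actor_hidden Hidden widths of the Q and actor perceptrons.
#' @param n_q Ensemble size (K >= 2 so the ensemble variance is defined).
#' @param cql_weight Weight of the conservative (out-of-distribution) penalty.
#' @param discount Discount factor per 5-min step.
#' @param steps,batch,lr Gradient steps, minibatch size, Adam learning rate.
#' @param n_ood Out-of-distribution action samples per state for the penalty.
#' @param tau Polyak rate of the target networks.
#' @param n_step Multi-step bootstrapping horizon for the Bellman targets
#'   (accumulated within-episode rewards; shortens the credit-assignment
#'   chain for delayed dose effects).
#' @param bc_alpha Scale of the value term in the behavior-anchored actor
#'   objective: the actor maximizes `bc_alpha / mean|Q|` times the minimum
#'   ensemble Q minus `bc_weight` times the squared distance to the logged
#'   action, keeping the policy in the data support (a second conservative
#'   mechanism alongside the critic penalty).
#' @param bc_weight Weight of the behavior-anchor term; 0 recovers the pure
#'   conservative-Q actor.
#' @return List of class `cql_config`.
#' @export
cql_config <- function(q_hidden = 32L, actor_hidden = 32L, n_q = 5L,
                       cql_weight = 1.0, discount = 0.99, steps = 400L,
                       batch = 128L, lr = 3e-3, n_ood = 8L, tau = 0.99,
                       n_step = 4L, bc_alpha = 2.5, bc_weight = 1) {
  stopifnot(n_q >= 2L, discount > 0, discount < 1, n_step >= 1L)
  structure(as.list(environment()), class = "cql_config")
}

# actions normalized to [-1, 1]^2; box defined by safety/action bounds
action_to_unit <- function(d_rp, rk, safety = safety_config()) {
  lim <- min(safety$d_rp_box, safety$propofol_step)
  cbind(d_rp / lim, 2 * rk / safety$ketamine_max - 1)
}

unit_to_action <- function(a, safety = safety_config()) {
  lim <- min(safety$d_rp_box, safety$propofol_step)
  list(d_rp = a[, 1] * lim, rk = (a[, 2] + 1) / 2 * safety$ketamine_max)
}

q_forward <- function(nodes, prefix, s, a) {
  x <- ad_cbind(list(s, a))
  h <- ad_tanh(nn_linear(nodes, paste0(prefix, 1), x))
  h <- ad_tanh(nn_linear(nodes, paste0(prefix, 2), h))
  nn_linear(nodes, paste0(prefix, 3), h)
}

q_eval <- function(theta, prefix, S, A) {
  mlp_eval(theta, cbind(S, A), 3L, prefix)
}

actor_forward <- function(nodes, s) {
  h <- ad_tanh(nn_linear(nodes, "pi1", s))
  h <- ad_tanh(nn_linear(nodes, "pi2", h))
  ad_tanh(nn_linear(nodes, "pi3", h))
}

actor_eval <- function(theta, S) {
  tanh(mlp_eval(theta, S, 3L, "pi"))
}

#' Train a conservative Q-learning dosing agent
#'
#' Actor-critic CQL for the continuous two-dimensional action (propofol
#' adjustment, ketamine rate), normalized to the unit box. Each of the `n_q`
#' Q-functions minimizes the Bellman error plus `cql_weight` times the
#' conservative gap `logsumexp_{a ~ mu} Q(s, a) - Q(s, a_data)` with `mu` =
#' uniform-over-box samples plus the current actor action; the actor ascends
#' the minimum ensemble Q.
#'
#' @param transitions A `ctdose_transitions` table from [build_transitions()].
#' @param cfg [cql_config()].
#' @param safety [safety_config()] (defines the action box).
#' @param seed Integer seed.
#' @return A `cpql_agent`: actor/Q weights, configs, training curves.
#' @export
cql_train <- function(transitions, cfg = cql_config(), safety = safety_config(),
                      seed = 1L) {
  if (!nrow(transitions)) stop("empty transition dataset", call. = FALSE)
  S <- do.call(rbind, transitions$state)
  Sn <- do.call(rbind, transitions$next_state)
  A <- action_to_unit(transitions$d_rp, transitions$rk, safety)
  A <- pmin(pmax(A, -1), 1)
  ds <- ncol(S)
  # n-step targets within episodes: accumulated discounted rewards, the
  # bootstrap state n steps ahead, and the effective discount
  ep_idx <- split(seq_len(nrow(transitions)), transitions$episode_id)
  R <- numeric(nrow(S)); gam_eff <- numeric(nrow(S)); term <- numeric(nrow(S))
  boot <- integer(nrow(S))
  for (ii in ep_idx) {
    L <- length(ii)
    for (j in seq_len(L)) {
      m <- min(cfg$n_step, L - j + 1L)
      R[ii[j]] <- sum(transitions$reward[ii[j:(j + m - 1L)]] * cfg$discount^(0:(m - 1L)))
      gam_eff[ii[j]] <- cfg$discount^m
      term[ii[j]] <- as.numeric(j + m - 1L == L)  # window ends at the terminal
      boot[ii[j]] <- ii[j + m - 1L]
    }
  }
  Sn <- Sn[boot, , drop = FALSE]

  qp <- function(i) paste0("q", i, "_")
  theta <- with_seed_local(seed, {
    th <- mlp_init(c(ds, cfg$actor_hidden, cfg$actor_hidden, 2L), "pi")
    th$pi3_W <- th$pi3_W * 0.05   # start near the box center (tanh unsaturated)
    for (i in seq_len(cfg$n_q)) {
      th <- c(th, mlp_init(c(ds + 2L, cfg$q_hidden, cfg$q_hidden, 1L), qp(i)))
    }
    th
  })
  target <- theta
  state <- adam_state(theta)
  losses <- numeric(cfg$steps)

  with_seed_local(seed + 1L, {
    for (step in seq_len(cfg$steps)) {
      idx <- sample.int(nrow(S), min(cfg$batch, nrow(S)))
      s <- S[idx, , drop = FALSE]; sn <- Sn[idx, , drop = FALSE]
      a <- A[idx, , drop = FALSE]; r <- R[idx]; tm <- term[idx]
      # Bellman target under the target networks and current actor
      an <- actor_eval(target, sn)
      qn <- sapply(seq_len(cfg$n_q), function(i) q_eval(target, qp(i), sn, an))
      y <- r + gam_eff[idx] * (1 - tm) * apply(matrix(qn, ncol = cfg$n_q), 1, min)
      n <- length(idx)
      a_ood <- matrix(stats::runif(n * 2L * cfg$n_ood, -1, 1), ncol = 2L)
      s_ood <- s[rep(seq_len(n), cfg$n_ood), , drop = FALSE]
      a_pi <- actor_eval(theta, s)

      # critic pass: update the Q ensemble (actor actions enter as constants)
      closs <- NULL
      grads <- NULL
      ad_with_tape({
        nodes <- nn_nodes(theta)
        sN <- ad_const(s)
        qloss <- NULL
        for (i in seq_len(cfg$n_q)) {
          qd <- q_forward(nodes, qp(i), sN, ad_const(a))
          bell <- ad_mean(ad_square(ad_sub(qd, ad_const(matrix(y, ncol = 1)))))
          q_o <- q_forward(nodes, qp(i), ad_const(rbind(s_ood, s)),
                           ad_const(rbind(a_ood, a_pi)))
          # logsumexp over the (n_ood + 1) sampled actions per state
          m <- matrix(q_o$val, nrow = n)
          mx <- apply(m, 1, max)
          w <- exp(m - mx) / rowSums(exp(m - mx))   # softmax weights (stop-grad)
          lse <- ad_sum(ad_mul(q_o, ad_const(matrix(as.numeric(w), ncol = 1))))
          gap <- ad_scale(ad_sub(lse, ad_sum(qd)), 1 / n)
          li <- ad_add(ad_scale(bell, 0.5), ad_scale(gap, cfg$cql_weight))
          qloss <- if (is.null(qloss)) li else ad_add(qloss, li)
        }
        ad_backward(qloss)
        grads <- nn_grads(nodes)
        closs <- qloss$val[1, 1]
      })
      # actor pass: ascend the minimum ensemble Q with frozen critics
      ad_with_tape({
        anodes <- nn_nodes(theta[grepl("^pi", names(theta))])
        qconst <- lapply(theta[!grepl("^pi", names(theta))], ad_const)
        nodes2 <- c(anodes, qconst)
        sN <- ad_const(s)
        apol <- actor_forward(nodes2, sN)
        qpi <- lapply(seq_len(cfg$n_q), function(i) q_forward(nodes2, qp(i), sN, apol))
        qmin_val <- do.call(pmin, lapply(qpi, function(x) x$val))
        qmin <- NULL
        for (i in seq_len(cfg$n_q)) {
          mask <- ad_const(matrix(as.numeric(qpi[[i]]$val == qmin_val), ncol = 1))
          contrib <- ad_mul(qpi[[i]], mask)
          qmin <- if (is.null(qmin)) contrib else ad_add(qmin, contrib)
        }
        lam <- cfg$bc_alpha / max(mean(abs(qmin_val)), 1e-6)
        aloss <- ad_add(ad_scale(ad_mean(qmin), -lam),
                        ad_scale(ad_mean(ad_square(ad_sub(apol, ad_const(a)))),
                                 cfg$bc_weight))
        ad_backward(aloss)
        agrads <- nn_grads(anodes)
        for (k in names(agrads)) grads[[k]] <- agrads[[k]]
        losses[step] <- closs + aloss$val[1, 1]
      })
      upd <- adam_step(theta, grads, state, cfg$lr)
      theta <- upd$theta; state <- upd$state
      # Polyak target update
      for (k in names(theta)) target[[k]] <- cfg$tau * target[[k]] + (1 - cfg$tau) * theta[[k]]
    }
  })

  structure(list(theta = theta, cfg = cfg, safety = safety,
                 state_dim = ds, loss_history = losses, seed = seed),
            class = "cpql_agent")
}

#' Actor action for a batch of policy states
#'
#' @param agent A `cpql_agent`.
#' @param S State matrix (rows = decision steps).
#' @return Tibble `d_rp`, `rk` (raw proposal, before projection).
#' @export
agent_action <- function(agent, S) {
  a <- actor_eval(agent$theta, S)
  out <- unit_to_action(a, agent$safety)
  tibble::tibble(d_rp = out$d_rp, rk = out$rk)
}

#' Q-ensemble values and variance
#' @param agent A `cpql_agent`.
#' @param S State matrix.
#' @param A Action matrix in unit coordinates (defaults to the actor action).
#' @return List with `q` (n x K matrix) and `variance` (per-state ensemble
#'   variance).
#' @export
q_ensemble <- function(agent, S, A = NULL) {
  if (is.null(A)) A <- actor_eval(agent$theta, S)
  q <- sapply(seq_len(agent$cfg$n_q), function(i) {
    q_eval(agent$theta, paste0("q", i, "_"), S, A)
  })
  q <- matrix(q, nrow = nrow(S))
  list(q = q, variance = apply(q, 1, stats::var))
}

# ---- confidence / abstain ---------------------------------------------------

#' Fit confidence-score ramps on the training distribution
#'
#' Each component (forecast PI width, lab observation density, Q-ensemble
#' variance) is mapped to \\[0, 5\\] by a fixed piecewise-linear ramp anchored
#' at the 5th and 95th percentiles of the training cohort; lower PI width,
#' higher density and lower variance score higher. Ramps are frozen here and
#' reused at recommendation time.
#'
#' @param pi_widths Training-cohort relative PI widths.
#' @param densities Training-cohort lab recency values (hours since the last
#'   inflammatory lab; larger = staler).
#' @param q_vars Training-cohort Q-ensemble variances.
#' @return List of class `confidence_ramps`.
#' @export
fit_confidence_ramps <- function(pi_widths, densities, q_vars) {
  anchor <- function(x) stats::quantile(x, c(0.05, 0.95), na.rm = TRUE, names = FALSE)
  structure(list(pi_width = anchor(pi_widths), density = anchor(densities),
                 q_var = anchor(q_vars)), class = "confidence_ramps")
}

ramp_score <- function(x, anchors, decreasing = TRUE) {
  lo <- anchors[1]; hi <- anchors[2]
  if (hi <= lo) hi <- lo + 1e-9
  f <- pmin(pmax((x - lo) / (hi - lo), 0), 1)
  5 * if (decreasing) 1 - f else f
}

#' Composite confidence score and abstain decision
#'
#' @param pi_width Relative width of the calibrated 90% IL-6 interval.
#' @param density Hours since the last inflammatory laboratory result.
#' @param q_var Q-ensemble variance at the proposed action.
#' @param ramps Frozen [fit_confidence_ramps()].
#' @param cfg [abstain_config()].
#' @return Tibble with component scores, `score` (0-5), `abstain`, `reason`
#'   (names the worst component; empty when recommending).
#' @export
confidence_score <- function(pi_width, density, q_var, ramps,
                             cfg = abstain_config()) {
  s_pi <- ramp_score(pi_width, ramps$pi_width, decreasing = TRUE)
  s_de <- ramp_score(density, ramps$density, decreasing = TRUE)
  s_qv <- ramp_score(q_var, ramps$q_var, decreasing = TRUE)
  w <- cfg$weights
  score <- w[["pi_width"]] * s_pi + w[["density"]] * s_de + w[["q_var"]] * s_qv
  comp <- cbind(pi_width = s_pi, density = s_de, q_var = s_qv)
  worst <- colnames(comp)[apply(comp, 1, which.min)]
  # a component at its floor always defers (a stale-data alert even when the
  # other components are healthy)
  floored <- apply(comp, 1, min) <= 0
  abstain <- score < cfg$threshold | floored
  reason <- ifelse(
    abstain,
    ifelse(worst == "density",
           sprintf("no inflammatory lab result recorded in the past %.1f h", density),
           ifelse(worst == "pi_width", "forecast interval too wide",
                  "Q-ensemble disagreement on the proposed action")),
    ""
  )
  tibble::tibble(score_pi = s_pi, score_density = s_de, score_qvar = s_qv,
                 score = score, abstain = abstain, reason = reason)
}

# ---- recommendation loop ----------------------------------------------------

#' Per-step dose recommendations for simulated episodes
#'
#' Walks each episode's 5-min operative-window decision grid: builds the
#' policy state, queries the actor, projects the proposal onto the safety
#' constraints (unless disabled, for the unconstrained-RL baseline), and
#' gates the recommendation by the composite confidence score. Every emitted
#' recommendation is re-checked against the constraints.
#'
#' @param es A simulated `episode_set`.
#' @param agent A `cpql_agent`.
#' @param model The `ctdose_forecaster` that defines the latent state.
#' @param ramps [fit_confidence_ramps()] output.
#' @param project Apply the hard projection layer (default `TRUE`).
#' @param abstain_cfg [abstain_config()].
#' @param episode_ids Episodes to process.
#' @return Tibble: `episode_id, t_sec, delta_propofol, ketamine_rate,
#'   projected_flag, violation, confidence, abstained, reason`.
#' @export
recommend <- function(es, agent, model, ramps, project = TRUE,
                      abstain_cfg = abstain_config(), episode_ids = NULL) {
  if (is.null(episode_ids)) episode_ids <- es$static$episode_id
  if (is.null(es$truth)) stop("recommend() expects a simulated episode_set", call. = FALSE)
  tr <- es$truth
  t_grid <- tr$t_h
  dt <- t_grid[2] - t_grid[1]
  lat <- episode_latents(es, model, episode_ids, t_grid)
  if (ncol(lat[[1]]) + 10L != agent$state_dim) {
    stop("forecaster latent width does not match the agent's state layout", call. = FALSE)
  }
  # per-episode 12-h IL-6 PI width at the default origin (forecast uncertainty)
  fc <- forecast_episodes(model, es, episode_ids = episode_ids, origins_h = 2)
  fc <- fc[fc$cytokine == "il6" & fc$horizon_h == 12, ]
  piw <- (fc$hi90 - fc$lo90) / pmax(fc$mean, 1)
  names(piw) <- fc$episode_id
  ev <- es$events
  rows <- list()
  for (id in episode_ids) {
    i <- match(id, tr$patients$episode_id)
    steps <- which(t_grid < tr$patients$op_end_h[i])
    dense <- tr$dense
    rp_prev <- tr$patients$rp_init[i]
    rk_prev <- 0
    lab_t <- ev$t_sec[ev$episode_id == id & ev$modality %in% cytokine_tokens() &
                        is.finite(ev$value)] / 3600
    for (k in steps) {
      t_h <- t_grid[k]
      st <- tibble::tibble(
        map_roll = mean(dense$map[i, max(1, k - 5):k]),
        hr_roll = tr$patients$hr_base[i],
        spo2_roll = 97,
        cum_rp = sum(dense$rp[i, 1:k]) * 5, cum_rk = sum(dense$rk[i, 1:k]) * 5,
        rv = dense$rv[i, k], rp_prev = rp_prev, rk_prev = rk_prev,
        depth = 95 - tr$patients$depth_slope[i] * rp_prev, t_h = t_h
      )
      S <- policy_state_matrix(st, lat[[id]][k, , drop = FALSE])
      act <- agent_action(agent, S)
      if (project) {
        pr <- project_action(act$d_rp, act$rk, rp_prev, rk_prev, agent$safety)
      } else {
        pr <- list(rp = rp_prev + act$d_rp, rk = act$rk,
                   d_rp = act$d_rp, projected = FALSE)
      }
      qv <- q_ensemble(agent, S)$variance
      recency <- if (any(lab_t <= t_h)) (t_h - max(lab_t[lab_t <= t_h])) else 24
      conf <- confidence_score(piw[[id]], recency, qv, ramps, abstain_cfg)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        episode_id = id, t_sec = t_h * 3600,
        delta_propofol = pr$d_rp, ketamine_rate = pr$rk,
        projected_flag = pr$projected,
        violation = violates_constraints(pr$rp, pr$rk, rp_prev, rk_prev, agent$safety),
        confidence = conf$score, abstained = conf$abstain, reason = conf$reason
      )
      if (!conf$abstain) { rp_prev <- pr$rp; rk_prev <- pr$rk }
    }
  }
  dplyr::bind_rows(rows)
}
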