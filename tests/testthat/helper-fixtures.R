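# Shared fixtures, built once per test run and memoized. All are smoke-scale:
# small cohorts, narrow networks, few epochs — enough for the contracts and
# directional properties exercised by the suite.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# a medium cohort for generator-level statistics
fixture_cohort <- function() {
  memo("cohort200", simulate_cohort(sim_config(n = 200, seed = 401,
                                               vitals_every_min = 30)))
}

# a small cohort for model training
fixture_small_cohort <- function() {
  memo("cohort40", simulate_cohort(sim_config(n = 40, seed = 402,
                                              vitals_every_min = 30)))
}

fixture_standardizer <- function() {
  memo("std", suppressWarnings(fit_standardizer(fixture_small_cohort())))
}

smoke_encoder_config <- function(...) {
  args <- utils::modifyList(
    list(layers = 2L, heads = 2L, d = 16L, dropout = 0.1,
         pretrain_epochs = 2L, lr = 2e-3, max_events = 80L),
    list(...))
  do.call(encoder_config, args)
}

fixture_encoder <- function() {
  memo("encoder", pretrain_masked_modality(
    subset_episodes(fixture_small_cohort(),
                    fixture_small_cohort()$static$episode_id[1:15]),
    fixture_standardizer(), smoke_encoder_config(), seed = 7))
}

smoke_forecaster_config <- function(...) {
  args <- utils::modifyList(
    list(latent_width = 8L, dyn_hidden = 16L, epochs = 60L,
         lr = 8e-3, origins_h = c(2, 6), substep_h = 2),
    list(...))
  do.call(forecaster_config, args)
}

fixture_model <- function() {
  memo("model", {
    m <- train_forecaster(fixture_small_cohort(), fixture_encoder(),
                          smoke_forecaster_config(), seed = 9)
    calibrate_forecaster(m, fixture_small_cohort())
  })
}

fixture_transitions <- function() {
  memo("transitions", build_transitions(fixture_small_cohort(), fixture_model(),
                                        episode_ids = fixture_small_cohort()$static$episode_id[1:25]))
}

fixture_agent <- function() {
  memo("agent", cql_train(fixture_transitions(),
                          cql_config(steps = 200L, n_q = 3L, batch = 128L),
                          seed = 11))
}

fixture_ramps <- function() {
  memo("ramps", {
    tx <- fixture_transitions()
    S <- do.call(rbind, tx$state)
    qv <- q_ensemble(fixture_agent(), S[1:200, , drop = FALSE])$variance
    fit_confidence_ramps(stats::runif(200, 0.3, 3), stats::runif(200, 0, 8), qv)
  })
}

# deterministic constant-rate cytokine trajectory for one typical patient
# (noise-free oracle used in dose-response tests)
oracle_trajectory <- function(rp, rk, hours = 12, gt = gt_params(),
                              map_base = 83, amp = 38) {
  st <- list(il6 = 46, crp = 14, tnfa = 18, il10 = 12.4,
             base_il6 = 46, base_crp = 14, base_tnfa = 18, base_il10 = 12.4,
             amp_il6 = amp, amp_tnfa = 20)
  map <- map_base; rv <- 0; dt <- 5 / 60
  for (k in seq_len(round(hours * 12))) {
    rv <- if (map < 58) rv + 0.03 else if (map > 72) rv * 0.5 else rv
    map <- map_dynamics(map, map_base, rp, rv, dt, gt)
    st <- cytokine_dynamics(st, (k - 1) * dt, rp, rk, perfusion_index_of(map), dt, gt)
  }
  st
}

# perfusion index mirror of the generator's internal coupling
perfusion_index_of <- function(map) 1 + 0.25 * pmax(65 - map, 0) / 10

# tiny deterministic transition set with known linear behavior, for OPE tests
linear_behavior_transitions <- function(n_ep = 40, steps = 1, seed = 5,
                                        sd_a = c(1, 0.5),
                                        reward_fn = function(a) 1 - (a[1] - 0.5)^2) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_ep)) {
    s <- matrix(stats::runif(4, -1, 1), 1)
    for (t in seq_len(steps)) {
      mu <- c(2 * s[1] - s[2], 1 + s[3])
      a <- mu + stats::rnorm(2) * sd_a
      lp <- sum(stats::dnorm(a, mu, sd_a, log = TRUE))
      r <- reward_fn(a)
      sn <- matrix(stats::runif(4, -1, 1), 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        episode_id = sprintf("e%03d", i), t_h = t * 5 / 60,
        d_rp = a[1], rk = a[2], reward = r, log_prop = lp,
        terminal = t == steps,
        state = I(list(as.numeric(s))), next_state = I(list(as.numeric(sn))))
      s <- sn
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ctdose_transitions", class(out))
  out
}

# 100-episode pipeline shared by the acceptance criteria: cohort, smoke
# forecaster, offline transitions, CPQL agent and confidence ramps
fixture_big <- function() {
  memo("big", {
    es <- simulate_cohort(sim_config(n = 100, seed = 402, vitals_every_min = 30))
    std <- suppressWarnings(fit_standardizer(es))
    enc <- pretrain_masked_modality(
      subset_episodes(es, es$static$episode_id[1:20]), std,
      smoke_encoder_config(), seed = 7)
    m <- train_forecaster(es, enc, smoke_forecaster_config(), seed = 9)
    m <- calibrate_forecaster(m, es)
    tx <- build_transitions(es, m)
    agent <- cql_train(tx, cql_config(steps = 600L, n_q = 3L, batch = 256L,
                                      lr = 1e-3, n_step = 12L, n_ood = 8L,
                                      bc_alpha = 20, cql_weight = 0.5),
                       seed = 11)
    S <- do.call(rbind, tx$state)
    qv <- q_ensemble(agent, S[1:400, , drop = FALSE])$variance
    fc <- forecast_episodes(m, es, origins_h = 2)
    fc <- fc[fc$cytokine == "il6" & fc$horizon_h == 12, ]
    ramps <- fit_confidence_ramps((fc$hi90 - fc$lo90) / pmax(fc$mean, 1),
                                  stats::runif(400, 0, 6), qv)
    list(es = es, model = m, tx = tx, agent = agent, ramps = ramps)
  })
}
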