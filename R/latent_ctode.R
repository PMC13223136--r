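# Latent continuous-time dynamics between observations, conditioned on drug
# infusions; Gaussian forecast heads; and the NLL + CRPS training loop.

#' Forecaster configuration
#'
#' @param latent_width Width of the latent state z(t) (128 at full scale;
#'   desk-scale profiles use 8-16).
#' @param dyn_hidden Hidden width of the three-layer dynamics perceptron.
#' @param horizons_h Forecast horizons in hours.
#' @param origins_h Prediction origins (hours post induction) used to build
#'   supervision; origins slide every 2 h at full scale.
#' @param lambda_crps Weight of the CRPS regularizer added to the Gaussian
#'   negative log-likelihood.
#' @param epochs,lr Training epochs (full-batch Adam) and learning rate.
#' @param substep_h Step (h) of the fixed-step RK4 integrator used for
#'   differentiable training-time propagation.
#' @param sigma_floor Additive floor on predictive scales (softplus head).
#' @param vitals_weight Weight of the MAP/HR/SpO2 decoder-head likelihood
#'   (the learned environment surrogate) in the training objective.
#' @param split Named fractions for the episode-level train/calibration/test
#'   partition.
#' @param u_scale Reference scales dividing the raw propofol, ketamine and
#'   vasopressor rates before they enter the dynamics function.
#' @return A list of class `forecaster_config`.
#' @export
forecaster_config <- function(latent_width = 16L, dyn_hidden = 32L,
                              horizons_h = c(2, 4, 6, 8, 12, 16, 20, 24),
                              origins_h = c(4, 6), lambda_crps = 0.5,
                              epochs = 150L, lr = 5e-3, substep_h = 1,
                              sigma_floor = 1e-4, vitals_weight = 1,
                              split = c(train = 0.7, calib = 0.15, test = 0.15),
                              u_scale = c(propofol = 50, ketamine = 10, vasopressor = 0.1)) {
  stopifnot(latent_width >= 2, all(horizons_h > 0), lambda_crps >= 0,
            abs(sum(split) - 1) < 1e-8)
  structure(as.list(environment()), class = "forecaster_config")
}

#' Adaptive ODE solver settings
#'
#' @param rtol,atol Relative/absolute tolerances of the adaptive
#'   Dormand-Prince solver used at inference time.
#' @param max_step Maximum step size (h).
#' @return List of class `ode_config`.
#' @export
ode_config <- function(rtol = 1e-5, atol = 1e-6, max_step = 1) {
  stopifnot(rtol > 0, atol > 0)
  structure(list(rtol = rtol, atol = atol, max_step = max_step), class = "ode_config")
}

# ---- controls --------------------------------------------------------------

#' Piecewise-linear infusion control signal
#'
#' Linearly interpolates each drug's recorded rates over time and holds the
#' last record constant beyond it. A drug with no recorded rate is treated as
#' identically zero with a warning.
#'
#' @param events One episode's event tibble (raw values).
#' @param window Numeric length-2: time window in hours the signal must cover.
#' @return A `control_signal`: function(t_h) returning a `length(t_h) x 3`
#'   matrix of raw rates (propofol, ketamine, vasopressor).
#' @export
interpolate_controls <- function(events, window = c(0, 30)) {
  fns <- lapply(infusion_tokens(), function(m) {
    ev <- events[events$modality == m & is.finite(events$value), ]
    if (nrow(ev) == 0L) {
      warning("no recorded ", m, " rate: treating as zero", call. = FALSE)
      return(function(t_h) rep(0, length(t_h)))
    }
    if (nrow(ev) == 1L) {
      v <- ev$value[1]
      return(function(t_h) rep(v, length(t_h)))
    }
    t_knot <- ev$t_sec / 3600
    v_knot <- ev$value
    function(t_h) stats::approx(t_knot, v_knot, xout = t_h, rule = 2)$y
  })
  names(fns) <- infusion_tokens()
  structure(function(t_h) {
    cbind(propofol = fns$propofol(t_h), ketamine = fns$ketamine(t_h),
          vasopressor = fns$vasopressor(t_h))
  }, class = "control_signal")
}

#' Constant control signal
#'
#' Convenience constructor for counterfactual dose settings (partial
#' dependence, dose surfaces): every drug held at a fixed rate.
#'
#' @param propofol,ketamine,vasopressor Constant rates (mcg/kg/min).
#' @return A `control_signal`.
#' @export
constant_controls <- function(propofol = 0, ketamine = 0, vasopressor = 0) {
  structure(function(t_h) {
    cbind(propofol = rep(propofol, length(t_h)),
          ketamine = rep(ketamine, length(t_h)),
          vasopressor = rep(vasopressor, length(t_h)))
  }, class = "control_signal")
}

# ---- model components ------------------------------------------------------

# elapsed-time channels appended to the control input of the dynamics
# function: a slow linear ramp plus one diurnal-scale harmonic pair. They give
# the vector field an explicit clock so the inflammatory phase (rise vs
# resolution) is not forced to be explained through the dose channels.
dyn_time_features <- function(t_h) {
  cbind(t_h / 24, sin(2 * pi * t_h / 24), cos(2 * pi * t_h / 24))
}

forecaster_init <- function(cfg, d_context) {
  k <- cfg$latent_width
  theta <- c(
    mlp_init(c(d_context, max(2L * k, 32L), k), "phi"),   # two-layer init map
    mlp_init(c(k + 6L, cfg$dyn_hidden, cfg$dyn_hidden, k), "dyn"),
    nn_linear_init(k, 8L, "head"),   # 4 cytokines x (mu, raw sigma)
    nn_linear_init(k, 6L, "vhead")   # MAP/HR/SpO2 decoder x (mu, raw sigma)
  )
  # start the vector field near zero so propagation begins as carry-forward
  theta$dyn3_W <- theta$dyn3_W * 0.05
  theta
}

# plain (tapeless) MLP evaluation on numeric matrices
mlp_eval <- function(theta, x, n_layers, prefix, act = tanh) {
  h <- x
  for (i in seq_len(n_layers)) {
    p <- paste0(prefix, i)
    h <- sweep(h %*% theta[[paste0(p, "_W")]], 2L, as.numeric(theta[[paste0(p, "_b")]]), "+")
    if (i < n_layers) h <- act(h)
  }
  h
}

#' Initialize the latent state from a context vector
#'
#' Applies the learned two-layer init map to the encoder context.
#'
#' @param z_obs Context vector (length `d`) or matrix of contexts (rows).
#' @param theta Forecaster weights (a trained model's `$theta`).
#' @return Latent matrix (`n x latent_width`).
#' @export
init_latent <- function(z_obs, theta) {
  if (is.null(dim(z_obs))) z_obs <- matrix(z_obs, nrow = 1)
  if (ncol(z_obs) != nrow(theta$phi1_W)) {
    stop("context width does not match the init map", call. = FALSE)
  }
  mlp_eval(theta, z_obs, 2L, "phi")
}

#' Propagate a latent state through time
#'
#' Solves dz/dt = f(z, u(t)) from `t0_h` to `t1_h` with the adaptive
#' Dormand-Prince solver, conditioned on the infusion control signal.
#'
#' @param z Latent state (numeric vector).
#' @param t0_h,t1_h Start and target times (hours); `t1_h >= t0_h`.
#' @param controls A `control_signal`.
#' @param dynamics Either a trained model's `$theta` (three-layer dynamics
#'   perceptron) or a function(z, u) returning dz/dt.
#' @param cfg_ode [ode_config()].
#' @param u_scale Rate scales (see [forecaster_config()]); ignored when
#'   `dynamics` is a bare function.
#' @return Latent state at `t1_h`.
#' @export
propagate <- function(z, t0_h, t1_h, controls, dynamics,
                      cfg_ode = ode_config(),
                      u_scale = c(propofol = 50, ketamine = 10, vasopressor = 0.1)) {
  if (t1_h < t0_h) stop("target time must be >= current time", call. = FALSE)
  if (t1_h == t0_h) return(z)
  f <- if (is.function(dynamics)) {
    function(t, y, parms) list(dynamics(y, as.numeric(controls(t))))
  } else {
    function(t, y, parms) {
      u <- c(as.numeric(controls(t)) / u_scale, as.numeric(dyn_time_features(t)))
      dz <- mlp_eval(dynamics, matrix(c(y, u), nrow = 1), 3L, "dyn")
      list(as.numeric(dz))
    }
  }
  sol <- deSolve::ode(y = z, times = c(t0_h, t1_h), func = f, parms = NULL,
                      method = deSolve::rkMethod("rk45dp7"),
                      rtol = cfg_ode$rtol, atol = cfg_ode$atol,
                      hmax = cfg_ode$max_step)
  if (attr(sol, "istate")[1] != 0 || any(!is.finite(sol[nrow(sol), -1]))) {
    stop("ODE solver failure: istate = ", attr(sol, "istate")[1], call. = FALSE)
  }
  as.numeric(sol[nrow(sol), -1])
}

# differentiable fixed-step RK4 over the horizon grid; returns list of latent
# nodes at the horizon knots. U is a function(t_h) -> B x 3 matrix of scaled
# control inputs (constants on the tape).
rk4_latent_path <- function(z0_node, nodes, knots, horizon_idx, U, counters = NULL) {
  if (!is.null(counters)) counters$propagate <- counters$propagate + 1L
  f <- function(z, u_const) {
    mlp_forward_dyn(nodes, ad_cbind(list(z, u_const)))
  }
  z <- z0_node
  out <- vector("list", length(horizon_idx))
  hit <- match(seq_along(knots), horizon_idx)
  if (!is.na(hit[1])) out[[hit[1]]] <- z
  for (j in seq_len(length(knots) - 1L)) {
    dt <- knots[j + 1L] - knots[j]
    u0 <- ad_const(U(knots[j]))
    um <- ad_const(U(knots[j] + dt / 2))
    u1 <- ad_const(U(knots[j + 1L]))
    k1 <- f(z, u0)
    k2 <- f(ad_add(z, ad_scale(k1, dt / 2)), um)
    k3 <- f(ad_add(z, ad_scale(k2, dt / 2)), um)
    k4 <- f(ad_add(z, ad_scale(k3, dt)), u1)
    incr <- ad_add(ad_add(k1, ad_scale(ad_add(k2, k3), 2)), k4)
    z <- ad_add(z, ad_scale(incr, dt / 6))
    if (!is.na(hit[j + 1L])) out[[hit[j + 1L]]] <- z
  }
  out
}

mlp_forward_dyn <- function(nodes, x) {
  h <- ad_tanh(nn_linear(nodes, "dyn1", x))
  h <- ad_tanh(nn_linear(nodes, "dyn2", h))
  nn_linear(nodes, "dyn3", h)
}

# Gaussian heads: latent node -> list(mu node (B x 4), sigma node (B x 4))
forecast_heads <- function(nodes, z, sigma_floor) {
  out <- nn_linear(nodes, "head", z)
  mu <- ad_slice_cols(out, 1:4)
  sigma <- ad_add(ad_softplus(ad_slice_cols(out, 5:8)),
                  ad_const(matrix(sigma_floor, 1, 1)))
  list(mu = mu, sigma = sigma)
}

# closed-form Gaussian CRPS as a tape node (y constant)
ad_crps_gaussian <- function(mu, sigma, y) {
  zst <- ad_mul(ad_sub(ad_const(y), mu), ad_recip(sigma))
  term <- ad_add(ad_mul(zst, ad_add(ad_scale(ad_pnorm(zst), 2), ad_const(matrix(-1, 1, 1)))),
                 ad_scale(ad_dnorm(zst), 2))
  ad_mul(sigma, ad_add(term, ad_const(matrix(-1 / sqrt(pi), 1, 1))))
}

ad_nll_gaussian <- function(mu, sigma, y) {
  r <- ad_sub(ad_const(y), mu)
  ad_add(ad_log(sigma), ad_scale(ad_square(ad_mul(r, ad_recip(sigma))), 0.5))
}

# ---- supervision assembly --------------------------------------------------

split_episodes <- function(ids, split, seed) {
  ids <- sort(unique(ids))
  n <- length(ids)
  perm <- with_seed_local(seed, sample(ids))
  n_tr <- max(1L, round(split[["train"]] * n))
  n_ca <- max(1L, round(split[["calib"]] * n))
  list(train = sort(perm[seq_len(n_tr)]),
       calib = sort(perm[n_tr + seq_len(min(n_ca, n - n_tr))]),
       test = sort(perm[setdiff(seq_len(n), seq_len(n_tr + n_ca))]))
}

# supervision rows for one split: one row per (episode, origin, cytokine, lab)
build_supervision <- function(es, origins_h, horizons_h) {
  ev <- es$events
  labs <- ev[ev$modality %in% cytokine_tokens() & is.finite(ev$value), ]
  rows <- list()
  for (o in origins_h) {
    sel <- labs[labs$t_sec / 3600 > o & labs$t_sec / 3600 <= o + max(horizons_h), ]
    if (!nrow(sel)) next
    dt_h <- sel$t_sec / 3600 - o
    h_idx <- vapply(dt_h, function(d) which.min(abs(horizons_h - d)), integer(1))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      episode_id = sel$episode_id, origin_h = o, cytokine = sel$modality,
      t_obs_h = sel$t_sec / 3600, horizon_idx = h_idx,
      horizon_h = horizons_h[h_idx], y = sel$value, y_log = log1p(sel$value)
    )
  }
  dplyr::bind_rows(rows)
}

# vitals supervision: per (episode, origin, horizon, vital) the single
# observation nearest to origin + h, standardized. Trains the decoder heads of
# the learned environment surrogate and anchors the latent hemodynamic state.
build_vitals_supervision <- function(es, std, origins_h, horizons_h) {
  vit <- c("map", "hr", "spo2")
  ev <- es$events[es$events$modality %in% vit & is.finite(es$events$value), ]
  rows <- list()
  for (o in origins_h) {
    sel <- ev[ev$t_sec / 3600 > o & ev$t_sec / 3600 <= o + max(horizons_h), ]
    if (!nrow(sel)) next
    dt_h <- sel$t_sec / 3600 - o
    h_idx <- vapply(dt_h, function(d) which.min(abs(horizons_h - d)), integer(1))
    sel$gap <- abs(dt_h - horizons_h[h_idx])
    sel$horizon_idx <- h_idx
    sel$origin_h <- o
    rows[[length(rows) + 1L]] <- sel
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(out)
  out <- dplyr::slice_min(
    dplyr::group_by(out, .data$episode_id, .data$origin_h, .data$modality, .data$horizon_idx),
    .data$gap, n = 1, with_ties = FALSE)
  out <- dplyr::ungroup(out)
  out$y_std <- standardize_values(std, out$modality, out$value)
  out
}

# encode contexts for each (episode, origin); returns list(keys tibble, Z matrix)
encode_contexts <- function(es, encoder, origins_h) {
  eps <- split(es$events, es$events$episode_id)
  keys <- list(); zs <- list()
  for (id in names(eps)) {
    for (o in origins_h) {
      ev <- eps[[id]][eps[[id]]$t_sec <= o * 3600, ]
      if (nrow(ev) == 0L) next
      keys[[length(keys) + 1L]] <- tibble::tibble(episode_id = id, origin_h = o)
      zs[[length(zs) + 1L]] <- encode_episode(ev, encoder)
    }
  }
  list(keys = dplyr::bind_rows(keys), Z = do.call(rbind, zs))
}

# ---- training --------------------------------------------------------------

#' Train the continuous-time forecaster
#'
#' Fits the init map, dynamics function and Gaussian heads by full-batch Adam
#' on the Gaussian negative log-likelihood plus `lambda_crps` times the
#' closed-form Gaussian CRPS, evaluated at the observed laboratory draws
#' (assigned to their nearest forecast horizon). Cytokines are modeled on the
#' log1p scale. The encoder is frozen.
#'
#' @param es Simulated or user `episode_set`.
#' @param encoder A `ctdose_encoder` (pre-trained, or fresh for the "-SSL"
#'   ablation arm).
#' @param cfg [forecaster_config()].
#' @param seed Integer seed (splits, init, epoch order).
#' @param ablate Character subset of `c("ct", "ssl", "calib")`: "-CT" replaces
#'   continuous-time propagation by last-latent carry-forward; "-SSL" discards
#'   the pre-trained encoder weights; "-Calib" marks the model so
#'   [calibrate_forecaster()] is skipped downstream.
#' @param splits Optional named list of episode-id vectors (`train`, `calib`,
#'   `test`); must be disjoint.
#' @return A `ctdose_forecaster` model bundle.
#' @export
train_forecaster <- function(es, encoder, cfg = forecaster_config(), seed = 1L,
                             ablate = character(), splits = NULL) {
  if ("ssl" %in% ablate) {
    encoder <- new_encoder(encoder$std, encoder$cfg, seed = seed + 17L)
  }
  if (is.null(splits)) {
    splits <- split_episodes(es$static$episode_id, cfg$split, seed)
  }
  if (anyDuplicated(unlist(splits))) stop("splits overlap by episode", call. = FALSE)

  tr <- subset_episodes(es, splits$train)
  sup <- build_supervision(tr, cfg$origins_h, cfg$horizons_h)
  if (!nrow(sup)) stop("no supervision pairs in the training split", call. = FALSE)
  vsup <- build_vitals_supervision(tr, encoder$std, cfg$origins_h, cfg$horizons_h)
  ctx <- encode_contexts(tr, encoder, cfg$origins_h)
  key <- paste(ctx$keys$episode_id, ctx$keys$origin_h)
  sup$b <- match(paste(sup$episode_id, sup$origin_h), key)
  sup <- sup[!is.na(sup$b), ]
  vsup$b <- match(paste(vsup$episode_id, vsup$origin_h), key)
  vsup <- vsup[!is.na(vsup$b), ]

  # per-batch-row control evaluators on the horizon grid
  eps_events <- split(tr$events, tr$events$episode_id)
  ctrl <- lapply(seq_len(nrow(ctx$keys)), function(i) {
    interpolate_controls(eps_events[[ctx$keys$episode_id[i]]])
  })
  u_scale <- cfg$u_scale
  U_at <- function(t_rel_h) {
    # absolute time = origin + relative offset, per batch row
    m <- t(vapply(seq_along(ctrl), function(i) {
      as.numeric(ctrl[[i]](ctx$keys$origin_h[i] + t_rel_h))
    }, numeric(3)))
    cbind(sweep(m, 2L, u_scale, "/"), dyn_time_features(ctx$keys$origin_h + t_rel_h))
  }
  knots <- sort(unique(c(seq(0, max(cfg$horizons_h), by = cfg$substep_h), cfg$horizons_h)))
  horizon_idx <- match(cfg$horizons_h, knots)
  U_cache <- lapply(sort(unique(c(knots, knots[-length(knots)] + diff(knots) / 2))),
                    U_at)
  names(U_cache) <- as.character(sort(unique(c(knots, knots[-length(knots)] + diff(knots) / 2))))
  U_fn <- function(t_rel_h) U_cache[[as.character(t_rel_h)]]

  # per-cytokine standardization of the log1p-scale targets
  y_loc <- vapply(cytokine_tokens(), function(cc) mean(sup$y_log[sup$cytokine == cc]),
                  numeric(1))
  y_scale <- vapply(cytokine_tokens(), function(cc) {
    s <- stats::sd(sup$y_log[sup$cytokine == cc])
    if (!is.finite(s) || s <= 0) 1 else s
  }, numeric(1))
  sup$y_std <- (sup$y_log - y_loc[sup$cytokine]) / y_scale[sup$cytokine]

  theta <- with_seed_local(seed, forecaster_init(cfg, ncol(ctx$Z)))
  state <- adam_state(theta)
  counters <- new.env(parent = emptyenv())
  counters$propagate <- 0L
  groups <- split(seq_len(nrow(sup)),
                  list(sup$horizon_idx, sup$cytokine), drop = TRUE)
  cyt_col <- match(sup$cytokine, cytokine_tokens())
  vgroups <- split(seq_len(nrow(vsup)),
                   list(vsup$horizon_idx, vsup$modality), drop = TRUE)
  vit_col <- match(vsup$modality, c("map", "hr", "spo2"))
  n_vsup <- nrow(vsup)
  Zobs <- ctx$Z
  n_sup <- nrow(sup)
  losses <- numeric(cfg$epochs)

  loss_pass <- function(theta, update = TRUE, lr = cfg$lr) {
    ad_with_tape({
      nodes <- nn_nodes(theta)
      z0 <- ad_tanh(nn_linear(nodes, "phi1", ad_const(Zobs)))
      z0 <- nn_linear(nodes, "phi2", z0)
      zh <- if ("ct" %in% ablate) {
        rep(list(z0), length(cfg$horizons_h))
      } else {
        rk4_latent_path(z0, nodes, knots, horizon_idx, U_fn, counters)
      }
      terms <- list(); wts <- numeric(0)
      for (g in groups) {
        hidx <- sup$horizon_idx[g[1]]
        ccol <- cyt_col[g[1]]
        heads <- forecast_heads(nodes, zh[[hidx]], cfg$sigma_floor)
        mu <- ad_slice_rows(ad_slice_cols(heads$mu, ccol), sup$b[g])
        sg <- ad_slice_rows(ad_slice_cols(heads$sigma, ccol), sup$b[g])
        y <- matrix(sup$y_std[g], ncol = 1)
        lt <- ad_add(ad_nll_gaussian(mu, sg, y),
                     ad_scale(ad_crps_gaussian(mu, sg, y), cfg$lambda_crps))
        terms[[length(terms) + 1L]] <- ad_sum(lt)
      }
      vterms <- list()
      for (g in vgroups) {
        hidx <- vsup$horizon_idx[g[1]]
        vcol <- vit_col[g[1]]
        vh <- nn_linear(nodes, "vhead", zh[[hidx]])
        mu <- ad_slice_rows(ad_slice_cols(vh, vcol), vsup$b[g])
        sg <- ad_add(ad_softplus(ad_slice_rows(ad_slice_cols(vh, 3L + vcol), vsup$b[g])),
                     ad_const(matrix(cfg$sigma_floor, 1, 1)))
        y <- matrix(vsup$y_std[g], ncol = 1)
        vterms[[length(vterms) + 1L]] <- ad_sum(ad_nll_gaussian(mu, sg, y))
      }
      tot <- terms[[1]]
      if (length(terms) > 1) for (i in 2:length(terms)) tot <- ad_add(tot, terms[[i]])
      loss <- ad_scale(tot, 1 / n_sup)
      if (length(vterms) && cfg$vitals_weight > 0) {
        vtot <- vterms[[1]]
        if (length(vterms) > 1) for (i in 2:length(vterms)) vtot <- ad_add(vtot, vterms[[i]])
        loss <- ad_add(loss, ad_scale(vtot, cfg$vitals_weight / max(n_vsup, 1L)))
      }
      if (update) {
        ad_backward(loss)
        upd <- adam_step(theta, nn_grads(nodes), state, lr)
        list(loss = loss$val[1, 1], theta = upd$theta, state = upd$state)
      } else {
        list(loss = loss$val[1, 1], theta = theta, state = state)
      }
    })
  }

  init_loss <- loss_pass(theta, update = FALSE)$loss
  for (e in seq_len(cfg$epochs)) {
    r <- loss_pass(theta, update = TRUE, lr = lr_cosine(cfg$lr, e, cfg$epochs))
    theta <- r$theta; state <- r$state
    losses[e] <- r$loss
  }

  structure(list(
    encoder = encoder, theta = theta, cfg = cfg, splits = splits,
    ablate = ablate, counters = counters, y_loc = y_loc, y_scale = y_scale,
    loss_history = losses, init_loss = init_loss,
    calibration = NULL, seed = seed
  ), class = "ctdose_forecaster")
}

#' Subset an episode set by episode ids
#' @param es An `episode_set`.
#' @param ids Episode ids to keep.
#' @return An `episode_set` (truth, if present, is carried but not subset).
#' @export
subset_episodes <- function(es, ids) {
  keep_e <- es$events$episode_id %in% ids
  keep_s <- es$static$episode_id %in% ids
  out <- es
  out$events <- es$events[keep_e, , drop = FALSE]
  out$static <- es$static[keep_s, , drop = FALSE]
  out
}

# ---- inference -------------------------------------------------------------

# tapeless forward for a batch of contexts; returns list over horizons of
# list(mu, sigma) matrices (B x 4), on the log1p scale
forecaster_forward_eval <- function(model, Zobs, U_fn) {
  cfg <- model$cfg
  theta <- model$theta
  z <- mlp_eval(theta, Zobs, 2L, "phi")
  knots <- sort(unique(c(seq(0, max(cfg$horizons_h), by = cfg$substep_h), cfg$horizons_h)))
  horizon_idx <- match(cfg$horizons_h, knots)
  out <- vector("list", length(cfg$horizons_h))
  dyn <- function(z, u) mlp_eval(theta, cbind(z, u), 3L, "dyn")
  store <- function(j, z) {
    hh <- match(j, horizon_idx)
    if (!is.na(hh)) {
      o <- sweep(z %*% theta$head_W, 2L, as.numeric(theta$head_b), "+")
      out[[hh]] <<- list(mu = o[, 1:4, drop = FALSE],
                         sigma = log1p(exp(-abs(o[, 5:8, drop = FALSE]))) +
                           pmax(o[, 5:8, drop = FALSE], 0) + cfg$sigma_floor)
    }
  }
  store(1L, z)
  if ("ct" %in% model$ablate) {
    for (j in seq_along(knots)[-1]) store(j, z)
  } else {
    for (j in seq_len(length(knots) - 1L)) {
      dt <- knots[j + 1L] - knots[j]
      k1 <- dyn(z, U_fn(knots[j]))
      k2 <- dyn(z + dt / 2 * k1, U_fn(knots[j] + dt / 2))
      k3 <- dyn(z + dt / 2 * k2, U_fn(knots[j] + dt / 2))
      k4 <- dyn(z + dt * k3, U_fn(knots[j + 1L]))
      z <- z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      store(j + 1L, z)
    }
  }
  out
}

#' Forecast cytokine trajectories for episodes
#'
#' Encodes each requested episode at each origin, propagates the latent state
#' across the horizon grid under the episode's recorded infusion controls
#' (or an override), and reads one Gaussian per cytokine and horizon.
#' Calibration (temperature + conformal), when attached to the model, shapes
#' the 90% bounds; otherwise raw Gaussian 90% bounds are returned.
#'
#' @param model A `ctdose_forecaster`.
#' @param es An `episode_set`.
#' @param episode_ids Episodes to forecast (default: all in `es`).
#' @param origins_h Prediction origins (default: the model's).
#' @param controls_override Optional `control_signal` replacing every
#'   episode's recorded infusions (counterfactual dosing).
#' @return Tibble: `episode_id, origin_h, cytokine, horizon_h, mu_log,
#'   sigma_log, mean, lo90, hi90` (mean and bounds on the raw pg/mL scale).
#' @export
forecast_episodes <- function(model, es, episode_ids = NULL,
                              origins_h = NULL, controls_override = NULL) {
  if (is.null(episode_ids)) episode_ids <- es$static$episode_id
  if (is.null(origins_h)) origins_h <- model$cfg$origins_h
  sub <- subset_episodes(es, episode_ids)
  ctx <- encode_contexts(sub, model$encoder, origins_h)
  if (!nrow(ctx$keys)) stop("no encodable contexts", call. = FALSE)
  eps_events <- split(sub$events, sub$events$episode_id)
  ctrl <- lapply(seq_len(nrow(ctx$keys)), function(i) {
    if (!is.null(controls_override)) controls_override
    else interpolate_controls(eps_events[[ctx$keys$episode_id[i]]])
  })
  U_fn <- function(t_rel_h) {
    m <- t(vapply(seq_along(ctrl), function(i) {
      as.numeric(ctrl[[i]](ctx$keys$origin_h[i] + t_rel_h))
    }, numeric(3)))
    cbind(sweep(m, 2L, model$cfg$u_scale, "/"),
          dyn_time_features(ctx$keys$origin_h + t_rel_h))
  }
  fh <- forecaster_forward_eval(model, ctx$Z, U_fn)
  rows <- list()
  for (h in seq_along(model$cfg$horizons_h)) {
    for (ci in seq_along(cytokine_tokens())) {
      cc <- cytokine_tokens()[ci]
      mu <- fh[[h]]$mu[, ci] * model$y_scale[[cc]] + model$y_loc[[cc]]
      sg <- fh[[h]]$sigma[, ci] * model$y_scale[[cc]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        episode_id = ctx$keys$episode_id, origin_h = ctx$keys$origin_h,
        cytokine = cc,
        horizon_h = model$cfg$horizons_h[h],
        mu_log = mu, sigma_log = sg
      )
    }
  }
  out <- apply_calibration(model, dplyr::bind_rows(rows))
  class(out) <- c("ctdose_forecast", class(out))
  out
}

# attach mean and 90% bounds, honoring any fitted calibration
apply_calibration <- function(model, fc) {
  cal <- model$calibration
  tt <- if (is.null(cal)) rep(1, nrow(fc)) else cal$temperature$T[match(fc$cytokine, cal$temperature$cytokine)]
  qq <- if (is.null(cal)) rep(stats::qnorm(0.95), nrow(fc)) else cal$conformal$q[match(fc$cytokine, cal$conformal$cytokine)]
  s <- fc$sigma_log * tt
  fc$mean <- expm1(fc$mu_log)
  fc$lo90 <- expm1(fc$mu_log - qq * s)
  fc$hi90 <- expm1(fc$mu_log + qq * s)
  fc
}

#' Pair forecasts with held-out observations
#'
#' Forecasts every episode of a split at the model's origins and joins each
#' observed laboratory value (raw scale) to its nearest-horizon forecast.
#'
#' @param model A `ctdose_forecaster`.
#' @param es The full `episode_set` the model was trained from (or a
#'   compatible one).
#' @param split One of "train", "calib", "test", or a vector of episode ids.
#' @return Tibble of prediction-observation pairs.
#' @export
forecast_pairs <- function(model, es, split = "test") {
  ids <- if (length(split) == 1L && split %in% names(model$splits)) {
    model$splits[[split]]
  } else split
  sub <- subset_episodes(es, ids)
  sup <- build_supervision(sub, model$cfg$origins_h, model$cfg$horizons_h)
  if (!nrow(sup)) stop("no observation pairs in this split", call. = FALSE)
  fc <- forecast_episodes(model, sub, episode_ids = unique(sup$episode_id))
  dplyr::inner_join(
    sup, fc,
    by = c("episode_id", "origin_h", "cytokine", "horizon_h")
  )
}
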