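# Mechanistic synthetic cohort: coupled cytokine/hemodynamic dynamics with
# drug dose-response, a confounded clinician behavior policy, irregular lab
# sampling, and stored noise streams so counterfactual re-simulation under a
# different policy reproduces the factual trajectory exactly when doses agree.

#' Ground-truth simulator parameters
#'
#' Pharmacodynamic and kinetic constants of the synthetic cohort. Defaults
#' encode the study conditions the package emulates: a biphasic post-induction
#' IL-6 pulse peaking 8-12 h after induction, a U-shaped propofol effect with
#' maximal suppression at `m_p` = 55 mcg/kg/min, saturating ketamine
#' suppression with half-max `e50` = 6 mcg/kg/min acting more strongly on
#' TNF-alpha than on IL-6, dose-proportional MAP depression with vasopressor
#' offset, and hypoperfusion-amplified cytokine release below MAP 65 mmHg.
#'
#' @param m_p Propofol rate (mcg/kg/min) of maximal IL-6 suppression.
#' @param w_p Width (mcg/kg/min) of the U-shaped propofol effect.
#' @param s_p Maximal fractional suppression by propofol.
#' @param e50 Ketamine half-max dose (mcg/kg/min).
#' @param emax_il6,emax_tnfa,emax_il10 Ketamine ceiling suppression fractions
#'   per cytokine (TNF-alpha weighted most strongly).
#' @param pulse_peak_h Peak time (h) of the inflammatory production pulse.
#' @param kout_il6,kout_tnfa Cytokine turnover rates (1/h).
#' @param crp_tau,il10_tau First-order lag times (h) for CRP and IL-10
#'   responses to IL-6.
#' @param crp_gain,il10_gain Gains of CRP (mg/L per pg/mL) and IL-10 on the
#'   IL-6 excess.
#' @param perf_coef Hypoperfusion amplification per 10 mmHg below MAP 65.
#' @param map_kappa MAP mean-reversion rate (1/h).
#' @param map_prop_sens MAP depression (mmHg) per mcg/kg/min propofol.
#' @param map_vaso_sens MAP rise (mmHg) per mcg/kg/min norepinephrine-equiv.
#' @return A named list of class `gt_params`.
#' @export
gt_params <- function(m_p = 55, w_p = 18, s_p = 0.5,
                      e50 = 6, emax_il6 = 0.35, emax_tnfa = 0.60, emax_il10 = 0.10,
                      pulse_peak_h = 7, kout_il6 = 0.35, kout_tnfa = 0.5,
                      crp_tau = 8, il10_tau = 6, crp_gain = 0.25, il10_gain = 0.15,
                      perf_coef = 0.25, map_kappa = 3, map_prop_sens = 0.28,
                      map_vaso_sens = 120) {
  p <- as.list(environment())
  stopifnot(m_p > 0, w_p > 0, e50 > 0, s_p >= 0, s_p < 1)
  structure(p, class = "gt_params")
}

#' Simulator configuration
#'
#' @param n Number of episodes.
#' @param seed Integer seed; fully determines the cohort.
#' @param gt Ground-truth parameters, see [gt_params()].
#' @param duration_h Episode length in hours post-induction.
#' @param op_window_h Range (h) of the operative-window duration, sampled
#'   uniformly per episode; dosing decisions occur on the 5-min grid inside
#'   this window.
#' @param lab_intensity Per-2-h-slot draw probability of the inflammatory
#'   panel (0.52 reproduces the ~48% lab missingness the package emulates).
#' @param informative_sampling If `TRUE`, draw intensity increases with the
#'   current true IL-6 (clinician-suspicion proxy).
#' @param ordered_missing_prob Probability that a drawn panel is "ordered but
#'   unresulted", emitting the indicator token instead of values.
#' @param lab_noise_sd Log-scale SD of multiplicative cytokine measurement
#'   noise.
#' @param vitals_every_min Emission cadence of MAP/HR/SpO2 events.
#' @param ket_b0,ket_b1 Intercept and log-CRP coefficient of the logistic
#'   ketamine-assignment model (negative `ket_b1` sends ketamine
#'   preferentially to less-inflamed patients, the measured confounding).
#' @param policy_sd_rp,policy_sd_rk Gaussian titration noise of the behavior
#'   policy (mcg/kg/min per 5-min step).
#' @param tbsa_strata Target proportions of the TBSA strata
#'   (<20%, 20-39%, >=40%).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 100, seed = 1L, gt = gt_params(),
                       duration_h = 30, op_window_h = c(1.5, 3.5),
                       lab_intensity = 0.44, informative_sampling = TRUE,
                       ordered_missing_prob = 0.05, lab_noise_sd = 0.15,
                       vitals_every_min = 15,
                       ket_b0 = -0.65, ket_b1 = -0.9,
                       policy_sd_rp = 2.5, policy_sd_rk = 0.5,
                       tbsa_strata = c(0.645, 0.241, 0.114)) {
  cfg <- as.list(environment())
  stopifnot(n >= 1, duration_h > 0, lab_intensity >= 0,
            all(tbsa_strata >= 0), abs(sum(tbsa_strata) - 1) < 1e-8)
  structure(cfg, class = "sim_config")
}

# ---- mechanistic pieces ----------------------------------------------------

#' Drug effect factors of the ground-truth model
#'
#' `f_propofol` is the U-shaped multiplicative factor on cytokine production
#' (suppression maximal at `m_p`); `f_ketamine` is the saturating Emax factor
#' `1 - emax * rk / (rk + e50)`.
#'
#' @param rp,rk Propofol / ketamine rates (mcg/kg/min).
#' @param gt [gt_params()].
#' @param emax Ceiling suppression fraction (cytokine specific).
#' @return Numeric factor(s) in (0, 1].
#' @export
f_propofol <- function(rp, gt = gt_params()) {
  if (any(rp < 0)) stop("negative dose", call. = FALSE)
  1 - gt$s_p * exp(-(rp - gt$m_p)^2 / (2 * gt$w_p^2))
}

#' @rdname f_propofol
#' @export
f_ketamine <- function(rk, emax, gt = gt_params()) {
  if (any(rk < 0)) stop("negative dose", call. = FALSE)
  1 - emax * rk / (rk + gt$e50)
}

pulse_shape <- function(t_h, tp) ifelse(t_h <= 0, 0, (t_h / tp) * exp(1 - t_h / tp))

perfusion_index <- function(map) 1 + 0.25 * pmax(65 - map, 0) / 10

cytokine_deriv <- function(t_h, st, rp, rk, perf, gt) {
  fp <- f_propofol(rp, gt)
  g <- pulse_shape(t_h, gt$pulse_peak_h)
  drive6 <- st$base_il6 + st$amp_il6 * g * fp * f_ketamine(rk, gt$emax_il6, gt) * perf
  driveT <- st$base_tnfa + st$amp_tnfa * g * fp * f_ketamine(rk, gt$emax_tnfa, gt) * perf
  list(
    il6  = gt$kout_il6 * (drive6 - st$il6),
    tnfa = gt$kout_tnfa * (driveT - st$tnfa),
    crp  = (st$base_crp + gt$crp_gain * (st$il6 - st$base_il6) - st$crp) / gt$crp_tau,
    il10 = (st$base_il10 + gt$il10_gain * f_ketamine(rk, gt$emax_il10, gt) *
              (st$il6 - st$base_il6) - st$il10) / gt$il10_tau
  )
}

#' One deterministic cytokine update step (RK4)
#'
#' Advances the four-cytokine state (IL-6, CRP, TNF-alpha, IL-10) by `dt_h`
#' hours under constant drug rates and perfusion index. This is the
#' ground-truth generative kernel; all arguments are vectorized over episodes.
#'
#' @param state List/tibble with elements `il6`, `crp`, `tnfa`, `il10` and the
#'   patient constants `base_*` and `amp_*` (baselines and pulse amplitudes).
#' @param t_h Time (h) since induction at the start of the step.
#' @param rp,rk Propofol / ketamine rates (mcg/kg/min), non-negative.
#' @param perf Perfusion index (1 = normal; >1 amplifies release).
#' @param dt_h Step size in hours, positive.
#' @param gt [gt_params()].
#' @return The state list with updated cytokine fields.
#' @export
cytokine_dynamics <- function(state, t_h, rp, rk, perf, dt_h, gt = gt_params()) {
  if (dt_h <= 0) stop("dt must be positive", call. = FALSE)
  if (any(rp < 0) || any(rk < 0)) stop("negative dose", call. = FALSE)
  vars <- c("il6", "tnfa", "crp", "il10")
  k1 <- cytokine_deriv(t_h, state, rp, rk, perf, gt)
  s2 <- state; for (v in vars) s2[[v]] <- state[[v]] + dt_h / 2 * k1[[v]]
  k2 <- cytokine_deriv(t_h + dt_h / 2, s2, rp, rk, perf, gt)
  s3 <- state; for (v in vars) s3[[v]] <- state[[v]] + dt_h / 2 * k2[[v]]
  k3 <- cytokine_deriv(t_h + dt_h / 2, s3, rp, rk, perf, gt)
  s4 <- state; for (v in vars) s4[[v]] <- state[[v]] + dt_h * k3[[v]]
  k4 <- cytokine_deriv(t_h + dt_h, s4, rp, rk, perf, gt)
  out <- state
  for (v in vars) {
    out[[v]] <- state[[v]] + dt_h / 6 * (k1[[v]] + 2 * k2[[v]] + 2 * k3[[v]] + k4[[v]])
  }
  out
}

#' One MAP update step
#'
#' Mean-reverting MAP with dose-proportional propofol depression, vasopressor
#' offset, and an optional stochastic disturbance (process noise plus
#' surgical-stimulus dips). The resulting MAP feeds the perfusion index used
#' by [cytokine_dynamics()].
#'
#' @param map Current MAP (mmHg), vectorized over episodes.
#' @param map_base Patient baseline MAP (mmHg).
#' @param rp,rv Propofol and norepinephrine-equivalent vasopressor rates.
#' @param dt_h Step (h).
#' @param gt [gt_params()].
#' @param disturbance Additive disturbance for this step (default 0:
#'   noise-free dynamics).
#' @return Updated MAP.
#' @export
map_dynamics <- function(map, map_base, rp, rv, dt_h, gt = gt_params(),
                         disturbance = 0) {
  if (any(rp < 0) || any(rv < 0)) stop("negative dose", call. = FALSE)
  target <- map_base - gt$map_prop_sens * rp + gt$map_vaso_sens * rv
  map + gt$map_kappa * (target - map) * dt_h + disturbance
}

#' Sample inflammatory-panel draw times
#'
#' Inhomogeneous draw schedule on a 2-h slot grid. With the informative flag
#' set, slot intensity increases with the supplied true IL-6 at the slot time
#' (a clinician-suspicion proxy producing missing-not-at-random sampling).
#'
#' @param duration_h Episode duration (h), positive.
#' @param intensity Baseline per-slot draw probability.
#' @param informative Logical; modulate intensity by IL-6?
#' @param seed Integer seed.
#' @param il6_at Optional function(t_h) returning true IL-6, required when
#'   `informative` is `TRUE`.
#' @return Numeric vector of draw times (h).
#' @export
sample_lab_times <- function(duration_h, intensity, informative = FALSE,
                             seed = 1L, il6_at = NULL) {
  if (duration_h <= 0) stop("duration must be positive", call. = FALSE)
  slots <- seq(2, duration_h, by = 2)
  p <- rep(intensity, length(slots))
  if (informative) {
    if (is.null(il6_at)) stop("il6_at required for informative sampling", call. = FALSE)
    p <- stats::plogis(stats::qlogis(pmin(pmax(intensity, 1e-6), 1 - 1e-6)) +
                         1.5 * (il6_at(slots) / 100 - 0.5))
  }
  u <- with_seed_local(seed, stats::runif(length(slots)))
  slots[u < p]
}

# ---- behavior policy -------------------------------------------------------

#' Clinician-like behavior policy (one 5-min decision, vectorized)
#'
#' Titrates propofol toward a depth-of-anesthesia target with
#' hypotension-triggered reductions, and (in the ketamine arm) titrates
#' ketamine toward a patient target. Actions are Gaussian-jittered and the
#' log-propensity of every emitted action is returned, so importance-sampling
#' estimators can use exact behavior densities.
#'
#' @param state Tibble with columns `depth`, `map`, `rp_prev`, `rk_prev`,
#'   `arm` (1 = ketamine arm), `rk_target`, `depth_target`.
#' @param cfg [sim_config()] (titration noise scales).
#' @param eps_rp,eps_rk Standard-normal jitter draws (one per row); supplied
#'   by the simulator's stored noise streams, defaults draw fresh.
#' @return Tibble with `d_rp` (propofol change), `rk` (ketamine rate), and
#'   `log_prop` (log propensity of the emitted action).
#' @export
behavior_policy_sim <- function(state, cfg = sim_config(),
                                eps_rp = stats::rnorm(nrow(state)),
                                eps_rk = stats::rnorm(nrow(state))) {
  step_mean <- 0.35 * (state$depth - state$depth_target)
  step_mean <- ifelse(state$map < 65, pmin(step_mean, -6), step_mean)
  d_rp <- step_mean + cfg$policy_sd_rp * eps_rp
  rk_mean <- ifelse(state$arm > 0,
                    state$rk_prev + 0.3 * (state$rk_target - state$rk_prev), 0)
  rk <- ifelse(state$arm > 0, pmax(rk_mean + cfg$policy_sd_rk * eps_rk, 0), 0)
  log_prop <- stats::dnorm(d_rp, step_mean, cfg$policy_sd_rp, log = TRUE) +
    ifelse(state$arm > 0, stats::dnorm(rk, rk_mean, cfg$policy_sd_rk, log = TRUE), 0)
  tibble::tibble(d_rp = d_rp, rk = rk, log_prop = log_prop,
                 mean_d_rp = step_mean, mean_rk = rk_mean,
                 sd_rp = cfg$policy_sd_rp,
                 sd_rk = ifelse(state$arm > 0, cfg$policy_sd_rk, NA_real_))
}

# ---- cohort assembly -------------------------------------------------------

draw_patients <- function(cfg) {
  n <- cfg$n
  stratum <- sample.int(3L, n, replace = TRUE, prob = cfg$tbsa_strata)
  tbsa <- c(stats::runif(n, 1, 19.5), stats::runif(n, 20, 39.5),
            stats::runif(n, 40, 75))[(stratum - 1L) * n + seq_len(n)]
  age <- pmin(pmax(round(stats::rnorm(n, 72.4, 6.8)), 65), 97)
  crp0 <- exp(stats::rnorm(n, log(14), 0.6))
  il6_0 <- exp(stats::rnorm(n, log(46), 0.8))
  p_ket <- stats::plogis(cfg$ket_b0 + cfg$ket_b1 * (log(crp0) - log(14)))
  arm <- as.integer(stats::runif(n) < p_ket)
  bmi <- round(stats::rnorm(n, 26.8, 5.4), 1)
  tibble::tibble(
    episode_id = sprintf("ep%04d", seq_len(n)),
    age = age,
    sex = as.integer(stats::runif(n) < 0.42),
    bmi = bmi,
    cci = pmin(stats::rpois(n, 3.5), 12L),
    tbsa = round(tbsa, 1),
    mechanism = sample(c("flame", "scald", "chemical", "electrical"), n,
                       replace = TRUE, prob = c(0.62, 0.24, 0.08, 0.06)),
    inhalation = as.integer(stats::runif(n) < 0.231),
    baux = age + round(tbsa, 1),
    group = ifelse(arm == 1, "propofol+ketamine", "propofol-only"),
    weight_kg = pmax(45, round(bmi * 2.89, 1)),  # bmi x 1.70 m squared
    # patient-level random effects (hidden truth)
    base_il6 = il6_0,
    base_crp = crp0,
    base_tnfa = exp(stats::rnorm(n, log(18), 0.6)),
    base_il10 = il6_0 / exp(stats::rnorm(n, log(3.7), 0.3)),
    amp_il6 = exp(stats::rnorm(n, log(38), 0.9) + 0.012 * (tbsa - 18)),
    amp_tnfa = exp(stats::rnorm(n, log(20), 0.8) + 0.010 * (tbsa - 18)),
    map_base = stats::rnorm(n, 83, 7),
    hr_base = stats::rnorm(n, 78, 8),
    depth_slope = pmin(pmax(stats::rnorm(n, 0.80, 0.30), 0.30), 1.5),
    depth_target = stats::runif(n, 46, 60),
    rp_init = pmin(pmax(stats::rnorm(n, 60, 12), 25), 90),
    rk_target = pmin(pmax(stats::rnorm(n, 8, 2.5), 2), 14),
    op_end_h = stats::runif(n, cfg$op_window_h[1], cfg$op_window_h[2]),
    sed_stop_h = stats::runif(n, 10, 24),
    arm = arm,
    p_ket = p_ket
  )
}

sim_noise <- function(cfg, nsteps, nslots) {
  n <- cfg$n
  list(
    map_z   = matrix(stats::rnorm(n * nsteps), n, nsteps),
    stim_u  = matrix(stats::runif(n * nsteps), n, nsteps),
    eps_rp  = matrix(stats::rnorm(n * nsteps), n, nsteps),
    eps_rk  = matrix(stats::rnorm(n * nsteps), n, nsteps),
    lab_u   = matrix(stats::runif(n * nslots), n, nslots),
    order_u = matrix(stats::runif(n * nslots), n, nslots),
    lab_z   = array(stats::rnorm(n * nslots * 4), c(n, nslots, 4)),
    base_lab_z = matrix(stats::rnorm(n * 4), n, 4),
    vital_sd_seed = sample.int(.Machine$integer.max %/% 2, 1)
  )
}

# Core engine. `policy` is NULL (behavior policy) or a function(state tibble)
# returning list/tibble with d_rp and rk; `project` optionally post-processes
# proposals. Fully deterministic given `patients` and `noise`.
sim_run <- function(patients, noise, cfg, policy = NULL, project = NULL,
                    record_events = TRUE) {
  gt <- cfg$gt
  n <- nrow(patients)
  dt <- 5 / 60
  nsteps <- round(cfg$duration_h / dt)
  t_grid <- (0:nsteps) * dt

  st <- list(il6 = patients$base_il6, crp = patients$base_crp,
             tnfa = patients$base_tnfa, il10 = patients$base_il10,
             base_il6 = patients$base_il6, base_crp = patients$base_crp,
             base_tnfa = patients$base_tnfa, base_il10 = patients$base_il10,
             amp_il6 = patients$amp_il6, amp_tnfa = patients$amp_tnfa)
  map <- patients$map_base
  rp <- patients$rp_init
  rk <- rep(0, n)
  rv <- rep(0, n)
  cum_rp <- rep(0, n); cum_rk <- rep(0, n)
  vaso_started <- rep(FALSE, n)

  dense <- list(il6 = matrix(NA_real_, n, nsteps + 1), crp = matrix(NA_real_, n, nsteps + 1),
                tnfa = matrix(NA_real_, n, nsteps + 1), il10 = matrix(NA_real_, n, nsteps + 1),
                map = matrix(NA_real_, n, nsteps + 1), rp = matrix(NA_real_, n, nsteps + 1),
                rk = matrix(NA_real_, n, nsteps + 1), rv = matrix(NA_real_, n, nsteps + 1))
  dense$il6[, 1] <- st$il6; dense$crp[, 1] <- st$crp
  dense$tnfa[, 1] <- st$tnfa; dense$il10[, 1] <- st$il10
  dense$map[, 1] <- map; dense$rp[, 1] <- rp; dense$rk[, 1] <- 0; dense$rv[, 1] <- 0

  act_rows <- list()

  for (k in seq_len(nsteps)) {
    t_h <- t_grid[k]
    in_window <- t_h < patients$op_end_h
    depth <- 95 - patients$depth_slope * rp +
      3 * noise$map_z[, k]  # reuse stream for depth jitter (same per-step draw)

    if (any(in_window)) {
      state <- tibble::tibble(
        t_h = t_h, depth = depth, map = map, rp_prev = rp, rk_prev = rk,
        arm = patients$arm, rk_target = patients$rk_target,
        depth_target = patients$depth_target, rv = rv,
        cum_rp = cum_rp, cum_rk = cum_rk,
        il6 = st$il6, crp = st$crp, tnfa = st$tnfa, il10 = st$il10,
        hr_base = patients$hr_base, episode_id = patients$episode_id,
        weight_kg = patients$weight_kg
      )
      if (is.null(policy)) {
        act <- behavior_policy_sim(state, cfg, noise$eps_rp[, k], noise$eps_rk[, k])
      } else {
        act <- tibble::as_tibble(policy(state))
        act$log_prop <- if ("log_prop" %in% names(act)) act$log_prop else NA_real_
      }
      prop_rp <- rp + act$d_rp
      prop_rk <- act$rk
      if (!is.null(project)) {
        pr <- project(act$d_rp, prop_rk, rp, rk)
        new_rp <- pr$rp; new_rk <- pr$rk
      } else {
        new_rp <- pmin(pmax(prop_rp, 0), 110)  # behavior keeps within charted pump range
        # ketamine infusions start ~20 min after induction
        new_rk <- if (t_h >= 1 / 3) pmin(pmax(prop_rk, 0), 20) else rep(0, n)
      }
      rp <- ifelse(in_window, new_rp, rp)
      rk <- ifelse(in_window, new_rk, rk)
      if (record_events) {
        act_rows[[length(act_rows) + 1L]] <- tibble::tibble(
          episode_id = patients$episode_id[in_window],
          t_h = t_h,
          rp = rp[in_window], rk = rk[in_window], rv = rv[in_window],
          d_rp = act$d_rp[in_window], prop_rp = prop_rp[in_window],
          prop_rk = prop_rk[in_window],
          log_prop = act$log_prop[in_window],
          map = map[in_window], depth = depth[in_window]
        )
      }
    }
    # post-window ICU sedation: step down to a constant maintenance rate at
    # the end of surgery, stop at the patient's sedation-stop time
    just_ended <- !in_window & (t_h - dt) < patients$op_end_h
    rp <- ifelse(just_ended, 0.75 * rp, rp)
    rk <- ifelse(just_ended, 0.75 * rk, rk)
    stopped <- t_h >= patients$sed_stop_h
    rp <- ifelse(stopped, 0, rp)
    rk <- ifelse(stopped, 0, rk)

    # vasopressor rescue rule (shared by all policies)
    rv <- ifelse(map < 58, rv + 0.03, rv)
    rv <- ifelse(map > 72, rv * 0.5, rv)
    vaso_started <- vaso_started | rv >= 0.05  # a clinically meaningful norepi-equivalent dose

    # dynamics
    stim <- ifelse(in_window & noise$stim_u[, k] < 0.04, -12, 0)
    dist <- 6 * sqrt(dt) * noise$map_z[, k] + stim
    map <- map_dynamics(map, patients$map_base, rp, rv, dt, gt, dist)
    perf <- perfusion_index(map)
    st <- cytokine_dynamics(st, t_h, rp, rk, perf, dt, gt)
    cum_rp <- cum_rp + rp * 5  # mcg/kg accumulated (rate x 5 min)
    cum_rk <- cum_rk + rk * 5

    dense$il6[, k + 1] <- st$il6; dense$crp[, k + 1] <- st$crp
    dense$tnfa[, k + 1] <- st$tnfa; dense$il10[, k + 1] <- st$il10
    dense$map[, k + 1] <- map; dense$rp[, k + 1] <- rp
    dense$rk[, k + 1] <- rk; dense$rv[, k + 1] <- rv
  }

  list(t_h = t_grid, dense = dense,
       actions = if (length(act_rows)) dplyr::bind_rows(act_rows) else NULL,
       vaso_started = vaso_started)
}

emit_events <- function(patients, run, noise, cfg) {
  n <- nrow(patients)
  t_h <- run$t_h
  dense <- run$dense
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df

  with_seed_local(noise$vital_sd_seed, {
    vit_t <- seq(0, cfg$duration_h, by = cfg$vitals_every_min / 60)
    vi <- round(vit_t / (t_h[2] - t_h[1])) + 1L
    for (m in c("map", "hr", "spo2")) {
      truth <- switch(m,
        map = dense$map[, vi, drop = FALSE],
        hr = patients$hr_base + 0.5 * pmax(65 - dense$map[, vi, drop = FALSE], 0) +
          0.05 * (dense$il6[, vi, drop = FALSE] - patients$base_il6),
        spo2 = matrix(97, n, length(vi))
      )
      noise_sd <- c(map = 2, hr = 2.5, spo2 = 0.7)[[m]]
      val <- truth + matrix(stats::rnorm(n * length(vi), 0, noise_sd), n)
      if (m == "spo2") val <- pmin(val, 100)
      add(tibble::tibble(
        episode_id = rep(patients$episode_id, length(vi)),
        t_sec = rep(vit_t, each = n) * 3600,
        modality = m, value = as.numeric(val)
      ))
    }
    slow_t <- seq(0, cfg$duration_h, by = 1)
    si <- round(slow_t / (t_h[2] - t_h[1])) + 1L
    add(tibble::tibble(
      episode_id = rep(patients$episode_id, length(si)),
      t_sec = rep(slow_t, each = n) * 3600, modality = "temp",
      value = 36.4 + 0.002 * as.numeric(dense$il6[, si, drop = FALSE] - patients$base_il6) +
        stats::rnorm(n * length(si), 0, 0.2)
    ))
    add(tibble::tibble(
      episode_id = rep(patients$episode_id, length(si)),
      t_sec = rep(slow_t, each = n) * 3600, modality = "rr",
      value = round(16 + 0.03 * pmax(65 - as.numeric(dense$map[, si, drop = FALSE]), 0) +
                      stats::rnorm(n * length(si), 0, 1.5))
    ))
    add(tibble::tibble(
      episode_id = rep(patients$episode_id, length(si)),
      t_sec = rep(slow_t, each = n) * 3600, modality = "urine",
      value = pmax(stats::rnorm(n * length(si), 35, 12), 0)
    ))
    # depth proxy during the operative window
    dep_t <- seq(0, max(patients$op_end_h), by = cfg$vitals_every_min / 60)
    di <- round(dep_t / (t_h[2] - t_h[1])) + 1L
    dep_val <- 95 - patients$depth_slope * dense$rp[, di, drop = FALSE] +
      matrix(stats::rnorm(n * length(di), 0, 3), n)
    keep <- outer(patients$op_end_h, dep_t, ">=")
    dd <- tibble::tibble(
      episode_id = rep(patients$episode_id, length(di)),
      t_sec = rep(dep_t, each = n) * 3600, modality = "depth",
      value = as.numeric(dep_val)
    )[as.logical(keep), ]
    add(dd)
    # cumulative fentanyl every 2 h: bolus at induction + intra-op rate
    fent_t <- seq(0, cfg$duration_h, by = 2)
    fent_rate <- stats::runif(n, 20, 70)            # mcg/h while in theatre
    fent_bolus <- stats::runif(n, 50, 150)
    fent_val <- fent_bolus + fent_rate * pmin(outer(patients$op_end_h, fent_t, pmin)[, 1:length(fent_t)], cfg$duration_h)
    add(tibble::tibble(
      episode_id = rep(patients$episode_id, length(fent_t)),
      t_sec = rep(fent_t, each = n) * 3600, modality = "fentanyl_cum",
      value = as.numeric(fent_val)
    ))
    # fluid balance (rolling 2-h crystalloid, mL)
    add(tibble::tibble(
      episode_id = rep(patients$episode_id, length(fent_t)),
      t_sec = rep(fent_t, each = n) * 3600, modality = "fluid",
      value = pmax(stats::rnorm(n * length(fent_t), 250, 80), 0)
    ))
  })

  # infusion events recorded at change points: a new pump rate is charted when
  # it moves by more than the charting tolerance since the last record
  dtg <- t_h[2] - t_h[1]
  chart_tol <- c(propofol = 1, ketamine = 0.25, vasopressor = 0.01)
  for (m in c("propofol", "ketamine", "vasopressor")) {
    mat <- switch(m, propofol = dense$rp, ketamine = dense$rk, vasopressor = dense$rv)
    idx_list <- lapply(seq_len(n), function(i) {
      v <- mat[i, ]
      rec <- 1L
      last <- v[1]
      for (j in 2:length(v)) {
        if (abs(v[j] - last) > chart_tol[[m]]) { rec <- c(rec, j); last <- v[j] }
      }
      rec
    })
    add(tibble::tibble(
      episode_id = rep(patients$episode_id, lengths(idx_list)),
      t_sec = t_h[unlist(idx_list)] * 3600, modality = m,
      value = mat[cbind(rep(seq_len(n), lengths(idx_list)), unlist(idx_list))]
    ))
  }

  # inflammatory labs: baseline panel + 2-h slots thinned by (informative) intensity
  slots <- seq(2, cfg$duration_h, by = 2)
  sidx <- round(slots / dtg) + 1L
  p <- matrix(cfg$lab_intensity, n, length(slots))
  if (cfg$informative_sampling) {
    p <- stats::plogis(stats::qlogis(pmin(pmax(cfg$lab_intensity, 1e-6), 1 - 1e-6)) +
                         1.0 * (dense$il6[, sidx, drop = FALSE] / 100 - 0.5))
  }
  drawn <- noise$lab_u[, seq_along(slots), drop = FALSE] < p
  unresulted <- drawn & (noise$order_u[, seq_along(slots), drop = FALSE] < cfg$ordered_missing_prob)
  cyt <- cytokine_tokens()
  for (j in seq_along(cyt)) {
    truth <- switch(cyt[j], il6 = dense$il6, crp = dense$crp,
                    tnfa = dense$tnfa, il10 = dense$il10)
    # baseline panel shortly after induction, always drawn
    add(tibble::tibble(
      episode_id = patients$episode_id, t_sec = 0.25 * 3600, modality = cyt[j],
      value = truth[, round(0.25 / dtg) + 1L] * exp(cfg$lab_noise_sd * noise$base_lab_z[, j])
    ))
    idx <- which(drawn & !unresulted, arr.ind = TRUE)
    if (nrow(idx)) {
      add(tibble::tibble(
        episode_id = patients$episode_id[idx[, 1]],
        t_sec = slots[idx[, 2]] * 3600, modality = cyt[j],
        value = truth[cbind(idx[, 1], sidx[idx[, 2]])] *
          exp(cfg$lab_noise_sd * noise$lab_z[cbind(idx[, 1], idx[, 2], j)])
      ))
    }
  }
  oidx <- which(unresulted, arr.ind = TRUE)
  if (nrow(oidx)) {
    add(tibble::tibble(
      episode_id = patients$episode_id[oidx[, 1]],
      t_sec = slots[oidx[, 2]] * 3600, modality = "lab_ordered", value = 1
    ))
  }

  dplyr::bind_rows(rows)
}

#' Simulate a synthetic perioperative cohort
#'
#' Draws a cohort of elderly burn episodes, runs the clinician behavior
#' policy through the mechanistic ground-truth dynamics, and emits an
#' [episode_set()] in the event-triplet schema plus hidden truth (dense
#' noise-free trajectories, logged behavior actions with exact propensities,
#' patient random effects, and the stored noise streams needed for exact
#' counterfactual re-simulation).
#'
#' @param cfg A [sim_config()].
#' @return An `episode_set` whose `truth` element holds the hidden state.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  with_seed_local(cfg$seed, {
    patients <- draw_patients(cfg)
    nsteps <- round(cfg$duration_h * 12)
    noise <- sim_noise(cfg, nsteps, length(seq(2, cfg$duration_h, by = 2)))
  })
  run <- sim_run(patients, noise, cfg)
  events <- emit_events(patients, run, noise, cfg)
  static <- patients[, c("episode_id", "age", "sex", "bmi", "cci", "tbsa",
                         "mechanism", "inhalation", "baux", "group", "weight_kg")]
  truth <- list(t_h = run$t_h, dense = run$dense, actions = run$actions,
                vaso_started = run$vaso_started, patients = patients,
                noise = noise, config = cfg)
  episode_set(events, static, truth)
}

#' Re-simulate a cohort under a different dosing policy
#'
#' Uses the stored patient effects and noise streams of a simulated cohort,
#' so an episode re-simulated with identical doses reproduces its factual
#' trajectory exactly (counterfactual consistency). The vasopressor rescue
#' rule is shared across policies; the policy controls (delta propofol,
#' ketamine rate).
#'
#' @param es An `episode_set` from [simulate_cohort()] (must carry truth).
#' @param policy `NULL` for the behavior policy, or a function(state tibble)
#'   returning a data frame with `d_rp` and `rk`.
#' @param project Optional projection function(d_rp, rk, rp_prev, rk_prev)
#'   returning list(rp, rk) of post-projection absolute rates.
#' @return The raw simulation run (dense trajectories + action log).
#' @export
resimulate <- function(es, policy = NULL, project = NULL) {
  if (is.null(es$truth)) stop("episode_set carries no simulator truth", call. = FALSE)
  sim_run(es$truth$patients, es$truth$noise, es$truth$config,
          policy = policy, project = project)
}
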