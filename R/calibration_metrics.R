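# Two-stage interval calibration (temperature scaling, then inductive
# conformal correction) and the forecasting evaluation suite.

#' Fit per-cytokine temperature scaling
#'
#' Finds the positive scalar `T` per cytokine maximizing the Gaussian
#' likelihood of the held-out observations under `N(mu, (T * sigma)^2)`.
#' For a Gaussian this has the closed form `T = sqrt(mean(z^2))` with
#' `z = (y - mu) / sigma`.
#'
#' @param pairs Prediction-observation pairs as returned by
#'   [forecast_pairs()] (columns `cytokine`, `mu_log`, `sigma_log`, `y_log`).
#' @param min_n Minimum pairs per cytokine (default 20).
#' @return Tibble of class `ctdose_temperature` with `cytokine`, `T`, `n`.
#' @export
fit_temperature <- function(pairs, min_n = 20L) {
  if (any(pairs$sigma_log <= 0)) stop("degenerate sigma in calibration pairs", call. = FALSE)
  out <- lapply(unique(pairs$cytokine), function(cc) {
    p <- pairs[pairs$cytokine == cc, ]
    if (nrow(p) < min_n) {
      stop("need >= ", min_n, " calibration pairs for ", cc, "; got ", nrow(p),
           call. = FALSE)
    }
    z <- (p$y_log - p$mu_log) / p$sigma_log
    tibble::tibble(cytokine = cc, T = sqrt(mean(z^2)), n = nrow(p))
  })
  structure(dplyr::bind_rows(out), class = c("ctdose_temperature", "tbl_df", "tbl", "data.frame"))
}

#' Fit inductive conformal offsets
#'
#' Computes the per-cytokine nonconformity quantile on a calibration split
#' disjoint from training and test. The score is the temperature-normalized
#' absolute residual `s = |y - mu| / (T * sigma)`; the offset is the
#' `ceiling((n + 1) * level)`-th smallest score, giving distribution-free
#' marginal coverage `>= level` for exchangeable data. Calibrated intervals
#' are `mu +/- q * T * sigma`.
#'
#' @param pairs Calibration pairs (see [fit_temperature()]).
#' @param temperature A `ctdose_temperature`.
#' @param level Target coverage (default 0.90).
#' @return Tibble of class `ctdose_conformal` with `cytokine`, `q`, `n`.
#' @export
fit_conformal <- function(pairs, temperature, level = 0.90) {
  out <- lapply(unique(pairs$cytokine), function(cc) {
    p <- pairs[pairs$cytokine == cc, ]
    tt <- temperature$T[match(cc, temperature$cytokine)]
    s <- abs(p$y_log - p$mu_log) / (tt * p$sigma_log)
    min_n <- 2L * ceiling(1 / (1 - level) - 1e-9) - 1L   # 19 at level 0.90
    if (length(s) < min_n) {
      stop("conformal calibration needs at least ", min_n, " scores at level ",
           level, "; got ", length(s), call. = FALSE)
    }
    k <- ceiling((length(s) + 1) * level)
    tibble::tibble(cytokine = cc, q = sort(s)[k], n = length(s))
  })
  structure(dplyr::bind_rows(out), class = c("ctdose_conformal", "tbl_df", "tbl", "data.frame"))
}

#' Calibrate a trained forecaster
#'
#' Runs the two-stage procedure (temperature scaling then conformal
#' correction) on the model's calibration split and attaches the result, so
#' subsequent [forecast_episodes()] calls emit calibrated 90% bounds.
#'
#' Nonconformity scores within one episode share patient-level effects, so
#' pooling every pair would break the exchangeability the conformal rank
#' argument needs (the test episode contributes a single fresh cluster). The
#' conformal stage therefore subsamples at most `k` scores per (episode,
#' cytokine), with `k` the smallest count that still leaves the required
#' minimum number of scores; temperature scaling, a global variance fit, uses
#' all pairs. Models trained with the "-Calib" ablation flag are returned
#' unchanged.
#'
#' @param model A `ctdose_forecaster`.
#' @param es The episode set holding the calibration split episodes.
#' @param level Interval level (default 0.90).
#' @return The model with a `calibration` component.
#' @export
calibrate_forecaster <- function(model, es, level = 0.90) {
  if ("calib" %in% model$ablate) {
    message("model carries the -Calib ablation flag; skipping calibration")
    return(model)
  }
  pairs <- forecast_pairs(model, es, "calib")
  temp <- fit_temperature(pairs)
  min_n <- 2L * ceiling(1 / (1 - level) - 1e-9) - 1L
  n_ep <- length(unique(pairs$episode_id))
  k <- max(1L, ceiling((min_n + 1L) / max(n_ep, 1L)))
  sub <- with_seed_local(model$seed + 777L, {
    dplyr::ungroup(dplyr::slice_sample(
      dplyr::group_by(pairs, .data$episode_id, .data$cytokine),
      n = k))
  })
  conf <- fit_conformal(sub, temp, level)
  model$calibration <- list(temperature = temp, conformal = conf, level = level,
                            scores_per_episode = k)
  model
}

#' Closed-form Gaussian CRPS
#'
#' `CRPS(N(mu, sd), y) = sd * (z * (2 * pnorm(z) - 1) + 2 * dnorm(z)
#' - 1 / sqrt(pi))` with `z = (y - mu) / sd`. Positively homogeneous of
#' degree 1; tends to `|y - mu|` in the far tails.
#'
#' @param mean,sd Gaussian parameters (`sd > 0`), vectorized.
#' @param y Observations.
#' @return CRPS values.
#' @export
crps_gaussian <- function(mean, sd, y) {
  if (any(sd <= 0)) stop("sd must be positive", call. = FALSE)
  z <- (y - mean) / sd
  sd * (z * (2 * stats::pnorm(z) - 1) + 2 * stats::dnorm(z) - 1 / sqrt(pi))
}

#' Forecast evaluation metrics
#'
#' Per-cytokine, per-horizon MAE and RMSE (raw pg/mL or mg/L scale),
#' empirical 90% interval coverage (closed intervals: boundary hits count as
#' covered), and mean CRPS (computed on the modeling log1p scale).
#'
#' @param pairs Prediction-observation pairs from [forecast_pairs()].
#' @param by Grouping columns (default cytokine and horizon; use
#'   `by = "cytokine"` for pooled-over-horizon rows).
#' @return Tidy tibble of metrics.
#' @export
forecast_metrics <- function(pairs, by = c("cytokine", "horizon_h")) {
  if (!nrow(pairs)) stop("no prediction-observation pairs", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(pairs, dplyr::across(dplyr::all_of(by))),
    n = dplyr::n(),
    mae = mean(abs(.data$mean - .data$y)),
    rmse = sqrt(mean((.data$mean - .data$y)^2)),
    coverage90 = mean(.data$y >= .data$lo90 & .data$y <= .data$hi90),
    crps = mean(crps_gaussian(.data$mu_log, .data$sigma_log, .data$y_log)),
    .groups = "drop"
  )
}

# ---- spike labels and detection --------------------------------------------

#' Label inflammatory spikes
#'
#' Relative criterion: an IL-6 rise of at least 40 pg/mL between any two
#' points at most 6 h apart. Absolute criterion: IL-6 reaching 100 pg/mL.
#'
#' @param series Tibble with `episode_id`, `t_h`, `value` (IL-6).
#' @param criterion `"relative"` or `"absolute"`.
#' @param rise,window_h,threshold Criterion parameters (40 pg/mL within 6 h;
#'   100 pg/mL).
#' @return Tibble `episode_id`, `spike` (0/1).
#' @export
label_spikes <- function(series, criterion = c("relative", "absolute"),
                         rise = 40, window_h = 6, threshold = 100) {
  criterion <- match.arg(criterion)
  one <- function(df) {
    if (criterion == "absolute") return(as.integer(any(df$value >= threshold)))
    if (nrow(df) < 2L) stop("relative criterion needs >= 2 points per episode", call. = FALSE)
    o <- order(df$t_h)
    t <- df$t_h[o]; v <- df$value[o]
    for (i in seq_len(length(v) - 1L)) {
      j <- which(t > t[i] & t - t[i] <= window_h)
      if (length(j) && max(v[j]) - v[i] >= rise) return(1L)
    }
    0L
  }
  out <- vapply(split(series, series$episode_id), one, integer(1))
  tibble::tibble(episode_id = names(out), spike = as.integer(out))
}

#' Spike labels from simulator ground truth
#'
#' @param es A simulated `episode_set` (with truth).
#' @param criterion See [label_spikes()].
#' @return Tibble `episode_id`, `spike`.
#' @export
true_spike_labels <- function(es, criterion = "relative") {
  if (is.null(es$truth)) stop("episode_set carries no simulator truth", call. = FALSE)
  d <- es$truth$dense$il6
  ids <- es$truth$patients$episode_id
  series <- tibble::tibble(
    episode_id = rep(ids, ncol(d)),
    t_h = rep(es$truth$t_h, each = nrow(d)),
    value = as.numeric(d)
  )
  label_spikes(series, criterion)
}

#' Model-based spike detector scores
#'
#' The detector score is the model's probability that the forecasted IL-6
#' rise reaches `rise` pg/mL within `window_h` hours of the origin: the
#' maximum over horizons `h <= window_h` of `P(Y(t0 + h) >= y0 + rise)` under
#' the (calibrated) Gaussian forecast on the log1p scale, where `y0` is the
#' last observed IL-6 at the origin.
#'
#' @param model A `ctdose_forecaster`.
#' @param es Episode set.
#' @param episode_ids Episodes to score.
#' @param origin_h Prediction origin.
#' @param rise,window_h Spike criterion parameters.
#' @return Tibble `episode_id`, `score`, `y0`.
#' @export
spike_scores <- function(model, es, episode_ids, origin_h = 6,
                         rise = 40, window_h = 6) {
  fc <- forecast_episodes(model, es, episode_ids = episode_ids,
                          origins_h = origin_h)
  fc <- fc[fc$cytokine == "il6" & fc$horizon_h <= window_h, ]
  tt <- if (is.null(model$calibration)) 1 else
    model$calibration$temperature$T[match("il6", model$calibration$temperature$cytokine)]
  ev <- es$events
  y0 <- vapply(unique(fc$episode_id), function(id) {
    labs <- ev[ev$episode_id == id & ev$modality == "il6" &
                 ev$t_sec <= origin_h * 3600 & is.finite(ev$value), ]
    if (nrow(labs)) labs$value[which.max(labs$t_sec)] else NA_real_
  }, numeric(1))
  fc$y0 <- y0[match(fc$episode_id, unique(fc$episode_id))]
  fc$p <- 1 - stats::pnorm((log1p(fc$y0 + rise) - fc$mu_log) / (fc$sigma_log * tt))
  out <- dplyr::summarise(dplyr::group_by(fc, .data$episode_id),
                          score = max(.data$p), y0 = .data$y0[1], .groups = "drop")
  out
}

#' AUROC by rank statistic
#'
#' Mann-Whitney AUROC with midrank tie handling. Errors when only one class
#' is present (the AUROC is undefined).
#'
#' @param scores Numeric detector scores.
#' @param labels Binary labels (0/1).
#' @return AUROC in \[0, 1\].
#' @export
spike_auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUROC undefined: labels contain a single class", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
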