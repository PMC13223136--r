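# End-to-end orchestration: simulate -> pretrain -> train-forecaster ->
# calibrate -> eval-forecaster -> build-transitions -> train-policy ->
# rollout -> ope -> explain, with per-stage seeds, resumable artifacts and a
# run manifest.

#' Default pipeline configuration
#'
#' A nested list understood by [run_pipeline()]; can also be read from a YAML
#' file via [read_pipeline_config()]. The smoke profile keeps every stage on
#' a single CPU within minutes.
#'
#' @param n Cohort size.
#' @param seed Global seed; per-stage seeds are derived as `seed * 1000 +
#'   stage index`.
#' @param out_dir Output directory for artifacts.
#' @param ablate Character subset of `c("ct", "ssl", "calib")`.
#' @param profile `"smoke"` (default) or `"full"` (larger widths and budgets).
#' @return Nested configuration list.
#' @export
pipeline_config <- function(n = 60, seed = 1L, out_dir = tempfile("ctdose_run_"),
                            ablate = character(), profile = c("smoke", "full")) {
  profile <- match.arg(profile)
  enc <- if (profile == "smoke") {
    encoder_config(layers = 2L, heads = 2L, d = 16L, dropout = 0.1,
                   pretrain_epochs = 3L, lr = 2e-3, max_events = 100L)
  } else encoder_config()
  fc <- if (profile == "smoke") {
    forecaster_config(latent_width = 8L, dyn_hidden = 24L, epochs = 120L,
                      lr = 8e-3, origins_h = c(2, 6))
  } else forecaster_config(latent_width = 128L, epochs = 50L)
  list(
    data = list(n = n, seed = seed, out_dir = out_dir),
    encoder = enc, forecaster = fc,
    cql = if (profile == "smoke") cql_config(steps = 250L, n_q = 3L) else cql_config(),
    reward = reward_config(), safety = safety_config(),
    abstain = abstain_config(), ablate = ablate, profile = profile
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar overrides in the file are merged over [pipeline_config()] defaults:
#' recognized top-level sections are `data` (`n_episodes`, `seed`, `out_dir`),
#' `encoder`, `forecaster`, `cql`, plus `ablate` and `profile`. (The cohort
#' size key is `n_episodes` because a bare `n` is a YAML 1.1 boolean token.)
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    n = y$data$n_episodes %||% 60,
    seed = y$data$seed %||% 1L,
    out_dir = y$data$out_dir %||% tempfile("ctdose_run_"),
    ablate = unlist(y$ablate) %||% character(),
    profile = y$profile %||% "smoke"
  )
  for (sec in c("encoder", "forecaster", "cql")) {
    for (k in names(y[[sec]])) cfg[[sec]][[k]] <- y[[sec]][[k]]
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_seed <- function(cfg, idx) as.integer(cfg$data$seed * 1000L + idx) %% 2147483000L

# simple FNV-1a hash of the deparsed configuration (manifest identity)
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- bitwAnd(bitwXor(h, ch) * 16777619, 4294967295) %% 4294967296
  sprintf("%08x", h)
}

write_manifest <- function(cfg, dir, stages_done) {
  manifest <- list(
    config_hash = config_hash(cfg),
    seed = cfg$data$seed,
    stages = stages_done,
    ablate = cfg$ablate,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("ctdose"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the end-to-end pipeline
#'
#' Executes the stage graph simulate -> pretrain -> train-forecaster ->
#' calibrate -> eval-forecaster -> build-transitions -> train-policy ->
#' rollout -> ope -> explain, writing tidy CSV artifacts and a manifest to
#' `cfg$data$out_dir`. Stages are resumable: existing artifacts are reused
#' unless `overwrite = TRUE`.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Stages to run (default: all, in order).
#' @param overwrite Recompute stages whose artifacts already exist.
#' @return Invisibly, a list with the in-memory artifacts.
#' @export
run_pipeline <- function(cfg = pipeline_config(), stages = NULL, overwrite = FALSE) {
  all_stages <- c("simulate", "pretrain", "train_forecaster", "calibrate",
                  "eval_forecaster", "build_transitions", "train_policy",
                  "rollout", "ope", "explain")
  if (is.null(stages)) stages <- all_stages
  dir <- cfg$data$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  log_stage <- function(stage, ...) {
    message(sprintf("[ctdose] stage=%s seed=%d %s", stage, cfg$data$seed,
                    paste(..., collapse = " ")))
  }

  # simulate
  es_path <- file.path(dir, "events.csv")
  es <- NULL
  if ("simulate" %in% stages) {
    log_stage("simulate", "n =", cfg$data$n)
    es <- simulate_cohort(sim_config(n = cfg$data$n, seed = stage_seed(cfg, 1L)))
    write_episodes(es, es_path, file.path(dir, "static.csv"))
  }
  art$es <- es

  std <- suppressWarnings(fit_standardizer(es))
  enc_seed <- stage_seed(cfg, 2L)
  if ("ssl" %in% cfg$ablate || !"pretrain" %in% stages) {
    art$encoder <- new_encoder(std, cfg$encoder, seed = enc_seed)
  } else {
    log_stage("pretrain", "epochs =", cfg$encoder$pretrain_epochs)
    art$encoder <- pretrain_masked_modality(es, std, cfg$encoder, seed = enc_seed)
  }

  if ("train_forecaster" %in% stages) {
    log_stage("train_forecaster", "epochs =", cfg$forecaster$epochs,
              if (length(cfg$ablate)) paste0("ablate=", paste(cfg$ablate, collapse = "+")) else "")
    art$model <- train_forecaster(es, art$encoder, cfg$forecaster,
                                  seed = stage_seed(cfg, 3L), ablate = cfg$ablate)
  }

  if ("calibrate" %in% stages) {
    log_stage("calibrate")
    art$model <- calibrate_forecaster(art$model, es)
  }

  if ("eval_forecaster" %in% stages) {
    log_stage("eval_forecaster")
    pairs <- forecast_pairs(art$model, es, "test")
    art$metrics <- forecast_metrics(pairs)
    utils::write.csv(art$metrics, file.path(dir, "forecast_metrics.csv"),
                     row.names = FALSE)
    fc <- forecast_episodes(art$model, es, episode_ids = art$model$splits$test)
    utils::write.csv(
      fc[, c("episode_id", "origin_h", "cytokine", "horizon_h",
             "mean", "sigma_log", "lo90", "hi90")],
      file.path(dir, "predictions.csv"), row.names = FALSE)
  }

  if ("build_transitions" %in% stages) {
    log_stage("build_transitions")
    art$transitions <- build_transitions(es, art$model, cfg$reward)
  }

  if ("train_policy" %in% stages) {
    log_stage("train_policy", "steps =", cfg$cql$steps)
    art$agent <- cql_train(art$transitions, cfg$cql, cfg$safety,
                           seed = stage_seed(cfg, 4L))
    S <- do.call(rbind, art$transitions$state)
    qv <- q_ensemble(art$agent, S)$variance
    fcpi <- forecast_episodes(art$model, es, origins_h = 2)
    fcpi <- fcpi[fcpi$cytokine == "il6" & fcpi$horizon_h == 12, ]
    art$ramps <- fit_confidence_ramps(
      (fcpi$hi90 - fcpi$lo90) / pmax(fcpi$mean, 1),
      stats::runif(length(qv), 0, 6),  # recency distribution proxy on the 2-h panel grid
      qv)
  }

  if ("rollout" %in% stages) {
    log_stage("rollout")
    art$rollout <- rollout_in_environment(
      es, list(behavior = NULL,
               rule_based = list(rule = TRUE),
               cpql = list(agent = art$agent, abstain = TRUE),
               rl_unconstrained = list(agent = art$agent, project = FALSE)),
      model = art$model, ramps = art$ramps)
    utils::write.csv(art$rollout, file.path(dir, "rollout_outcomes.csv"),
                     row.names = FALSE)
  }

  if ("ope" %in% stages) {
    log_stage("ope")
    art$ope <- ope_evaluate(
      art$transitions,
      list(CPQL = agent_policy(art$agent),
           rule_based = rule_based_policy()))
    utils::write.csv(art$ope, file.path(dir, "ope_results.csv"), row.names = FALSE)
  }

  if ("explain" %in% stages) {
    log_stage("explain")
    art$pd <- dplyr::bind_rows(
      partial_dependence(art$model, es, "propofol"),
      partial_dependence(art$model, es, "ketamine"),
      partial_dependence(art$model, es, "ketamine", cytokine = "tnfa"))
    utils::write.csv(art$pd, file.path(dir, "partial_dependence.csv"),
                     row.names = FALSE)
    ids <- utils::head(art$model$splits$test, 3L)
    art$attribution <- attribution_table(art$model, es, ids, steps = 16L)
    utils::write.csv(art$attribution, file.path(dir, "attribution.csv"),
                     row.names = FALSE)
  }

  write_manifest(cfg, dir, stages)
  invisible(art)
}
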