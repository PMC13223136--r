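# Episode containers, tabular I/O, standardization and lab masking.

#' Modality vocabulary
#'
#' The fixed, ordered vocabulary of modality tokens used throughout the
#' package. Codes are stable small integers; they define the tie-break order
#' for events that share a timestamp and are serialized with every model.
#'
#' @return A tibble with columns `modality` (token) and `code` (integer).
#' @export
#' @examples
#' modality_vocabulary()
modality_vocabulary <- function() {
  tokens <- c(
    "map", "hr", "spo2", "temp", "rr", "urine",
    "propofol", "ketamine", "vasopressor", "fluid", "fentanyl_cum", "depth",
    "il6", "crp", "tnfa", "il10", "lab_ordered"
  )
  tibble::tibble(modality = tokens, code = seq_along(tokens))
}

#' @noRd
cytokine_tokens <- function() c("il6", "crp", "tnfa", "il10")

#' @noRd
lab_tokens <- function() c(cytokine_tokens(), "lab_ordered")

#' @noRd
infusion_tokens <- function() c("propofol", "ketamine", "vasopressor")

modality_code <- function(modality) {
  voc <- modality_vocabulary()
  code <- voc$code[match(modality, voc$modality)]
  if (anyNA(code)) {
    bad <- unique(modality[is.na(code)])
    stop("unknown modality token(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  code
}

#' Construct an episode set
#'
#' Bundles an events table (one event triplet per row) and a static-feature
#' table into the container used by every other function in the package.
#' Events are sorted by time with ties broken by modality code; unknown
#' modality tokens are rejected; the Baux identity (baux = age + tbsa) and
#' the TBSA range are checked when those columns are present.
#'
#' @param events Data frame with columns `episode_id`, `t_sec` (seconds since
#'   anesthetic induction, t = 0 at induction), `modality`, `value`. A
#'   missing `value` is allowed only for the `lab_ordered` indicator-style
#'   usage where the event itself carries the information.
#' @param static Data frame with one row per `episode_id`; recognised columns
#'   are `age`, `sex`, `bmi`, `cci`, `tbsa`, `mechanism`, `inhalation`,
#'   `baux`, `group`.
#' @param truth Optional list of hidden ground truth (attached by the
#'   simulator; see [simulate_cohort()]).
#' @return An object of class `episode_set`.
#' @export
episode_set <- function(events, static, truth = NULL) {
  req_e <- c("episode_id", "t_sec", "modality", "value")
  miss <- setdiff(req_e, names(events))
  if (length(miss)) stop("events table is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"episode_id" %in% names(static)) {
    stop("static table is missing column(s): episode_id", call. = FALSE)
  }
  events <- tibble::as_tibble(events)
  static <- tibble::as_tibble(static)
  if (!all(is.finite(events$t_sec))) stop("non-finite timestamps", call. = FALSE)
  code <- modality_code(events$modality)
  events <- events[order(events$episode_id, events$t_sec, code), , drop = FALSE]
  if (all(c("age", "tbsa", "baux") %in% names(static))) {
    if (any(abs(static$baux - (static$age + static$tbsa)) > 1e-8)) {
      stop("baux must equal age + tbsa", call. = FALSE)
    }
  }
  if ("tbsa" %in% names(static) && any(static$tbsa < 0 | static$tbsa > 100)) {
    stop("tbsa must lie in [0, 100]", call. = FALSE)
  }
  structure(list(events = events, static = static, truth = truth),
            class = "episode_set")
}

#' @export
print.episode_set <- function(x, ...) {
  cat(sprintf("<episode_set: %d episodes, %d events%s>\n",
              nrow(x$static), nrow(x$events),
              if (!is.null(x$truth)) ", with ground truth" else ""))
  invisible(x)
}

#' Number of episodes in an episode set
#' @param es An `episode_set`.
#' @return Integer count.
#' @export
n_episodes <- function(es) nrow(es$static)

#' Read episodes from CSV tables
#'
#' Inverse of [write_episodes()]. Unsorted input is sorted, never rejected;
#' unknown modality tokens raise an error.
#'
#' @param events_path,static_path Paths to the events and static CSV tables.
#' @return An `episode_set`.
#' @export
read_episodes <- function(events_path, static_path) {
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  st <- utils::read.csv(static_path, stringsAsFactors = FALSE)
  episode_set(ev, st)
}

#' Write episodes to CSV tables
#'
#' Numeric columns are written with 17 significant digits so that
#' `read_episodes(write_episodes(es))` round-trips values exactly.
#'
#' @param es An `episode_set`.
#' @param events_path,static_path Output paths.
#' @return `es`, invisibly.
#' @export
write_episodes <- function(es, events_path, static_path) {
  fmt <- function(df) {
    for (k in names(df)) {
      if (is.double(df[[k]])) df[[k]] <- sprintf("%.17g", df[[k]])
    }
    df
  }
  utils::write.csv(fmt(as.data.frame(es$events)), events_path,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(as.data.frame(es$static)), static_path,
                   row.names = FALSE, quote = FALSE)
  invisible(es)
}

#' Convert absolute (e.g. Unix) timestamps to induction-relative seconds
#'
#' @param t Numeric vector of absolute timestamps (seconds).
#' @param induction_time Absolute timestamp of anesthetic induction.
#' @return `t - induction_time`.
#' @export
as_relative_time <- function(t, induction_time) t - induction_time

#' Flag analysis-eligible episodes
#'
#' An episode is analysis-eligible when it carries at least two inflammatory
#' laboratory results in the (6 h, 24 h] post-induction window.
#'
#' @param es An `episode_set`.
#' @return A tibble with `episode_id` and logical `eligible`.
#' @export
analysis_eligible <- function(es) {
  ev <- es$events
  labs <- ev[ev$modality %in% cytokine_tokens() &
               ev$t_sec > 6 * 3600 & ev$t_sec <= 24 * 3600 &
               is.finite(ev$value), ]
  counts <- table(labs$episode_id)
  tibble::tibble(
    episode_id = es$static$episode_id,
    eligible = as.integer(counts[as.character(es$static$episode_id)]) >= 2 &
      !is.na(counts[as.character(es$static$episode_id)])
  )
}

# ---- standardizer ----------------------------------------------------------

#' Fit a per-modality standardizer
#'
#' Estimates a location (mean) and scale (population standard deviation) per
#' modality on the supplied training episodes. Parameters are frozen at fit
#' time: applying the standardizer never re-estimates. A modality with zero
#' variance (or fewer than two observations) gets scale 1 with a warning.
#'
#' @param es Training `episode_set`.
#' @return A `ctdose_standardizer`: a tibble with `modality`, `center`, `scale`.
#' @export
fit_standardizer <- function(es) {
  voc <- modality_vocabulary()
  ev <- es$events[is.finite(es$events$value), ]
  out <- lapply(voc$modality, function(m) {
    v <- ev$value[ev$modality == m]
    if (length(v) < 2L) {
      warning("modality '", m, "' has fewer than 2 observations; scale set to 1",
              call. = FALSE)
      return(tibble::tibble(modality = m,
                            center = if (length(v)) mean(v) else 0, scale = 1))
    }
    s <- sqrt(mean((v - mean(v))^2))
    if (s <= 0) {
      warning("modality '", m, "' has zero variance; scale set to 1", call. = FALSE)
      s <- 1
    }
    tibble::tibble(modality = m, center = mean(v), scale = s)
  })
  structure(dplyr::bind_rows(out), class = c("ctdose_standardizer", class(out[[1]])))
}

#' Apply a fitted standardizer
#'
#' @param std A `ctdose_standardizer` from [fit_standardizer()].
#' @param es An `episode_set`.
#' @return A new `episode_set` with standardized event values; `std` is not
#'   modified.
#' @export
apply_standardizer <- function(std, es) {
  i <- match(es$events$modality, std$modality)
  es$events$value <- (es$events$value - std$center[i]) / std$scale[i]
  es
}

#' Invert a standardizer for one modality
#' @noRd
unstandardize <- function(std, modality, z) {
  i <- match(modality, std$modality)
  z * std$scale[i] + std$center[i]
}

standardize_values <- function(std, modality, v) {
  i <- match(modality, std$modality)
  (v - std$center[i]) / std$scale[i]
}

# ---- lab masking -----------------------------------------------------------

#' Mask a fraction of laboratory events
#'
#' Removes exactly `round(fraction * n)` inflammatory laboratory events
#' (IL-6, CRP, TNF-alpha, IL-10), chosen uniformly at random across the
#' cohort. Non-lab events are untouched. Used for the missingness stress
#' tests.
#'
#' @param es An `episode_set`.
#' @param fraction Fraction of lab events to remove, in \[0, 1).
#' @param seed Integer seed controlling the draw.
#' @return A new `episode_set`.
#' @export
mask_labs <- function(es, fraction, seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)", call. = FALSE)
  is_lab <- es$events$modality %in% cytokine_tokens()
  idx <- which(is_lab)
  k <- round(fraction * length(idx))
  if (k > 0) {
    drop_idx <- with_seed_local(seed, sample(idx, k))
    es$events <- es$events[-drop_idx, , drop = FALSE]
  }
  es
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

with_seed_local <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}
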