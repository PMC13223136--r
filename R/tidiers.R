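# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained forecaster
#'
#' One row per parameter block with its dimensions and norm.
#'
#' @param x A `ctdose_forecaster`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ctdose_forecaster
#' @export
tidy.ctdose_forecaster <- function(x, ...) {
  tibble::tibble(
    block = names(x$theta),
    rows = vapply(x$theta, nrow, integer(1)),
    cols = vapply(x$theta, ncol, integer(1)),
    frobenius = vapply(x$theta, function(m) sqrt(sum(m^2)), numeric(1))
  )
}

#' One-line summary of a trained forecaster
#'
#' @param x A `ctdose_forecaster`.
#' @param ... Unused.
#' @return A one-row tibble: parameter count, training loss before/after,
#'   ablation flags, calibration status, split sizes.
#' @method glance ctdose_forecaster
#' @export
glance.ctdose_forecaster <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(vapply(x$theta, length, integer(1))),
    latent_width = x$cfg$latent_width,
    init_loss = x$init_loss,
    final_loss = utils::tail(x$loss_history, 1),
    epochs = length(x$loss_history),
    ablate = paste(x$ablate, collapse = "+"),
    calibrated = !is.null(x$calibration),
    n_train = length(x$splits$train),
    n_calib = length(x$splits$calib),
    n_test = length(x$splits$test)
  )
}

#' Tidy a calibrated model's calibration parameters
#'
#' @param x A `ctdose_forecaster` with calibration attached.
#' @param ... Unused.
#' @return Tibble with per-cytokine temperature `T` and conformal offset `q`.
#' @export
tidy_calibration <- function(x, ...) {
  if (is.null(x$calibration)) stop("model is not calibrated", call. = FALSE)
  dplyr::inner_join(x$calibration$temperature,
                    x$calibration$conformal[, c("cytokine", "q")],
                    by = "cytokine")
}

#' Tidy a CPQL agent
#'
#' @param x A `cpql_agent`.
#' @param ... Unused.
#' @return Tibble of parameter blocks.
#' @method tidy cpql_agent
#' @export
tidy.cpql_agent <- function(x, ...) {
  tibble::tibble(
    block = names(x$theta),
    rows = vapply(x$theta, nrow, integer(1)),
    cols = vapply(x$theta, ncol, integer(1)),
    frobenius = vapply(x$theta, function(m) sqrt(sum(m^2)), numeric(1))
  )
}

#' One-line summary of a CPQL agent
#'
#' @param x A `cpql_agent`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance cpql_agent
#' @export
glance.cpql_agent <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(vapply(x$theta, length, integer(1))),
    n_q = x$cfg$n_q,
    cql_weight = x$cfg$cql_weight,
    discount = x$cfg$discount,
    steps = x$cfg$steps,
    final_loss = utils::tail(x$loss_history, 1)
  )
}
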