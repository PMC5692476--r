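# broom-style tidiers for foldkit fit objects.

#' Tidy a global exponential fit
#'
#' @param x A `foldkit_expfit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: shared rates (with
#'   linearized standard errors) followed by per-transient amplitudes and
#'   offsets.
#' @method tidy foldkit_expfit
#' @export
tidy.foldkit_expfit <- function(x, ...) {
  rates <- tibble(
    term = names(x$rates),
    estimate = unname(x$rates),
    std_error = unname(x$rate_se),
    transient = NA_character_
  )
  per_trace <- x$traces %>%
    tidyr::pivot_longer(
      cols = -c("condition", "replicate", "batch"),
      names_to = "term", values_to = "estimate") %>%
    mutate(std_error = NA_real_,
           transient = paste(.data$condition, .data$replicate,
                             .data$batch, sep = "/")) %>%
    select("term", "estimate", "std_error", "transient")
  bind_rows(rates, per_trace)
}

#' @rdname tidy.foldkit_expfit
#' @method glance foldkit_expfit
#' @export
glance.foldkit_expfit <- function(x, ...) {
  tibble(
    n_exponentials = x$n_exponentials,
    n_transients = nrow(x$traces),
    n_obs = x$n_obs,
    n_parameters = x$n_parameters,
    rss = x$rss,
    aicc = x$aicc
  )
}

#' Fitted values and residuals of a global exponential fit
#'
#' @param x A `foldkit_expfit`.
#' @param ... Unused.
#' @return The fit's data with `.fitted` and `.resid` columns.
#' @method augment foldkit_expfit
#' @export
augment.foldkit_expfit <- function(x, ...) {
  traces <- split_transients(x$data)
  lin <- project_linear(traces, unname(x$rates))
  purrr::map2_dfr(traces, lin$fitted, function(tr, f) {
    tr$.fitted <- f
    tr$.resid <- tr$signal - f
    tr
  })
}

#' Tidy a Hill-equation fit
#'
#' @param x A `foldkit_hillfit`.
#' @param ... Unused.
#' @return A tibble of `term`, `estimate`, `std_error` including both the
#'   apparent (`K_d_app`, molar) and raw (`K_D`, molar^n) dissociation
#'   constants.
#' @method tidy foldkit_hillfit
#' @export
tidy.foldkit_hillfit <- function(x, ...) {
  x$parameters
}

#' @rdname tidy.foldkit_hillfit
#' @method glance foldkit_hillfit
#' @export
glance.foldkit_hillfit <- function(x, ...) {
  tibble(
    n_obs = x$n_obs,
    rss = x$rss,
    hill_n_fixed = x$hill_n_fixed,
    saturation_warning = x$saturation_warning
  )
}

#' Tidy a logistic (sigmoidal) transient fit
#'
#' @param x A `foldkit_sigmoid`.
#' @param ... Unused.
#' @return A tibble of `term` and `estimate`.
#' @method tidy foldkit_sigmoid
#' @export
tidy.foldkit_sigmoid <- function(x, ...) {
  tibble(term = names(x$parameters), estimate = unname(x$parameters))
}

#' Tidy a membrane profile
#'
#' @param x A `foldkit_membrane_profile`.
#' @param ... Unused.
#' @return The across-replica summary tibble (`selection`, `metric`,
#'   `bond`, `mean`, `sd`, `n_replicas`).
#' @method tidy foldkit_membrane_profile
#' @export
tidy.foldkit_membrane_profile <- function(x, ...) {
  x$summary
}

#' @rdname tidy.foldkit_membrane_profile
#' @method glance foldkit_membrane_profile
#' @export
glance.foldkit_membrane_profile <- function(x, ...) {
  tibble(
    n_replicas = max(x$summary$n_replicas),
    n_selections = length(unique(x$summary$selection)),
    cutoff = x$settings$cutoff,
    bulk_cutoff = x$settings$bulk_cutoff,
    burn_in_fraction = x$settings$burn_in_fraction
  )
}
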