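#' Extract the folding half-time (t50) from a transient
#'
#' The t50 is the time taken to reach 50% of the total observed fluorescence
#' change. The minimum signal value is located, the maximum is defined by a
#' horizontal baseline fitted to the trailing `baseline_fraction` of the
#' samples, and the t50 is the first time, at or after the time of the
#' minimum, at which the signal crosses the level halfway between the two,
#' located by linear interpolation between bracketing samples. Because it
#' makes no model assumption, the t50 is the appropriate rate surrogate for
#' lag-phase (sigmoidal) transients that no sum of exponentials fits well.
#'
#' @param data A data frame with columns `time_s` and `signal` holding one
#'   transient (at least 10 samples, strictly increasing time).
#' @param baseline_fraction Fraction of trailing samples averaged to define
#'   the plateau level; in (0, 0.5]. Default 0.1.
#' @return A one-row tibble with columns `t50` (seconds), `f_min`,
#'   `baseline_level`, `half_level`, `baseline_fraction`, and
#'   `crossing_method` (`"linear_interpolation"`).
#' @examples
#' tr <- tibble::tibble(time_s = 0:600,
#'                      signal = 10 * (1 - exp(-0.0149 * (0:600))))
#' extract_t50(tr)  # ~ log(2)/0.0149 = 46.5 s
#' @export
extract_t50 <- function(data, baseline_fraction = 0.1) {
  data <- check_transient_tbl(data)
  traces <- split_transients(data)
  if (length(traces) > 1) {
    abort_input("`data` holds more than one transient; map over replicates")
  }
  check_number(baseline_fraction, "baseline_fraction", positive = TRUE)
  if (baseline_fraction > 0.5) {
    abort_input("`baseline_fraction` must be in (0, 0.5]")
  }
  t <- data$time_s
  y <- data$signal
  n <- length(y)

  i_min <- which.min(y)
  f_min <- y[i_min]
  n_tail <- max(1L, floor(baseline_fraction * n))
  baseline <- mean(y[(n - n_tail + 1L):n])
  if (baseline <= f_min) {
    abort_fit("no folding detected: trailing baseline is not above the minimum")
  }
  half <- (f_min + baseline) / 2

  # first crossing at or after the global minimum
  idx <- i_min:n
  above <- y[idx] >= half
  if (!any(above)) {
    abort_fit("no folding detected: signal never reaches the half level")
  }
  j <- idx[which(above)[1]]
  if (j == i_min) {
    t50 <- t[j]
  } else {
    # linear interpolation between the bracketing samples
    t50 <- t[j - 1] + (half - y[j - 1]) * (t[j] - t[j - 1]) / (y[j] - y[j - 1])
  }
  tibble(
    t50 = t50,
    f_min = f_min,
    baseline_level = baseline,
    half_level = half,
    baseline_fraction = baseline_fraction,
    crossing_method = "linear_interpolation"
  )
}

#' Fit a four-parameter logistic to a lag-phase folding transient
#'
#' Transients that show a lag phase before a rapid fluorescence increase are
#' displayed with a sigmoidal fit. The model is
#' \deqn{y(t) = L + (U - L) / (1 + e^{-s (t - t_m)})}
#' with lower/upper asymptotes `L`, `U`, midpoint time `t_m` (seconds) and
#' steepness `s` (per second). This fit is for display and summary only;
#' half-times are always computed model-free by [extract_t50()].
#'
#' @inheritParams extract_t50
#' @return An object of class `foldkit_sigmoid`: a list with `parameters`
#'   (named vector `lower`, `upper`, `midpoint`, `steepness`), `rss`, and
#'   `data`. Supports [tidy()] and [autoplot()].
#' @export
fit_sigmoid <- function(data) {
  data <- check_transient_tbl(data)
  traces <- split_transients(data)
  if (length(traces) > 1) {
    abort_input("`data` holds more than one transient; map over replicates")
  }
  t <- data$time_s
  y <- data$signal
  if (diff(range(y)) == 0) {
    abort_fit("sigmoid fit failed: signal is constant")
  }
  start <- list(
    lower = min(y),
    upper = max(y),
    midpoint = t[which.min(abs(y - (min(y) + max(y)) / 2))],
    steepness = 4 / max(diff(range(t)) / 4, .Machine$double.eps)
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ lower + (upper - lower) / (1 + exp(-steepness * (t - midpoint))),
      data = data.frame(t = t, y = y),
      start = start,
      lower = c(-Inf, -Inf, -Inf, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    abort_fit("sigmoid fit failed to converge")
  }
  cf <- stats::coef(fit)
  if (cf[["upper"]] < cf[["lower"]]) {
    # re-express with upper > lower by flipping the steepness sign
    cf[c("lower", "upper")] <- cf[c("upper", "lower")]
    cf[["steepness"]] <- -cf[["steepness"]]
  }
  if (cf[["steepness"]] <= 0 || cf[["upper"]] <= cf[["lower"]]) {
    abort_fit("sigmoid fit degenerate: no rising phase found")
  }
  structure(
    list(parameters = cf,
         rss = sum(stats::residuals(fit)^2),
         data = data),
    class = "foldkit_sigmoid"
  )
}

#' @export
print.foldkit_sigmoid <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "Logistic fit: midpoint %.4g s, steepness %.4g /s, range [%.4g, %.4g]\n",
    p[["midpoint"]], p[["steepness"]], p[["lower"]], p[["upper"]]))
  invisible(x)
}
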