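#' Generate synthetic fluorescence folding transients
#'
#' Produces seeded replicate transients from one of three generating
#' models:
#' \itemize{
#'   \item `single_exp`: \eqn{y = A_1 e^{-k_1 t} + c};
#'   \item `double_exp`: \eqn{y = A_1 e^{-k_1 t} + A_2 e^{-k_2 t} + c};
#'   \item `lag_sigmoid`: a four-parameter logistic
#'     \eqn{y = c + A / (1 + e^{-k (t - t_m)})}, emulating transients with a
#'     lag phase before a rapid fluorescence increase.
#' }
#' Negative amplitudes give rising exponential transients (fluorescence
#' increases on folding). Noise is multiplicative Gaussian:
#' \eqn{y_{obs} = y (1 + \epsilon)}, \eqn{\epsilon \sim N(0,
#' \mathrm{noise\_fraction}^2)}.
#'
#' @param model Generating model (see above).
#' @param rates Rate constant(s) in per second: one value for `single_exp`,
#'   two (fast, slow) for `double_exp`, the steepness for `lag_sigmoid`.
#' @param amplitudes Amplitude(s) in signal units, matching `rates` in
#'   length for the exponential models; the rise amplitude for
#'   `lag_sigmoid`.
#' @param offset Constant offset `c` in signal units.
#' @param midpoint Midpoint time of the `lag_sigmoid` model, seconds
#'   (default `duration / 2`).
#' @param noise_fraction Multiplicative Gaussian noise level (0 = exact).
#' @param duration Trace length in seconds.
#' @param sample_interval Sampling interval in seconds; the trace must hold
#'   at least 10 samples.
#' @param n_replicates Number of replicate traces.
#' @param condition Condition label stored with the traces.
#' @param batch Batch identifier (single value or one per replicate).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tibble with columns `time_s`, `signal`, `condition`,
#'   `replicate`, `batch` — the transient-table format the kinetics
#'   functions consume.
#' @examples
#' tr <- generate_transients(rates = 0.0149, noise_fraction = 0.02,
#'                           n_replicates = 3, seed = 7)
#' @export
generate_transients <- function(model = c("single_exp", "double_exp",
                                          "lag_sigmoid"),
                                rates = 0.0149,
                                amplitudes = NULL,
                                offset = 6,
                                midpoint = NULL,
                                noise_fraction = 0.02,
                                duration = 600,
                                sample_interval = 1,
                                n_replicates = 3,
                                condition = NULL,
                                batch = "batch1",
                                seed = NULL) {
  model <- match.arg(model)
  if (any(rates <= 0)) abort_input("`rates` must be positive")
  check_number(noise_fraction, "noise_fraction")
  if (noise_fraction < 0) abort_input("`noise_fraction` must be >= 0")
  check_number(duration, "duration", positive = TRUE)
  check_number(sample_interval, "sample_interval", positive = TRUE)
  if (duration / sample_interval < 10) {
    abort_input("spec must yield at least 10 samples")
  }
  if (n_replicates < 1) abort_input("`n_replicates` must be >= 1")
  if (is.null(condition)) condition <- model
  if (is.null(amplitudes)) {
    amplitudes <- switch(model,
      single_exp = -5,
      double_exp = c(-3, -3),
      lag_sigmoid = 5)
  }
  if (model == "double_exp" && length(rates) != 2) {
    abort_input("`double_exp` needs two rates")
  }
  if (model %in% c("single_exp", "double_exp") &&
      length(amplitudes) != length(rates)) {
    abort_input("`amplitudes` must match `rates` in length")
  }
  if (is.null(midpoint)) midpoint <- duration / 2
  if (length(batch) == 1) batch <- rep(batch, n_replicates)
  if (length(batch) != n_replicates) {
    abort_input("`batch` must have length 1 or n_replicates")
  }

  t <- seq(0, duration, by = sample_interval)
  mu <- switch(model,
    single_exp = amplitudes[1] * exp(-rates[1] * t) + offset,
    double_exp = amplitudes[1] * exp(-rates[1] * t) +
      amplitudes[2] * exp(-rates[2] * t) + offset,
    lag_sigmoid = offset + amplitudes[1] /
      (1 + exp(-rates[1] * (t - midpoint)))
  )
  if (!is.null(seed)) set.seed(as.integer(seed))
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    eps <- if (noise_fraction > 0) rnorm(length(t), 0, noise_fraction) else 0
    tibble(
      time_s = t,
      signal = mu * (1 + eps),
      condition = condition,
      replicate = paste0("r", r),
      batch = batch[r]
    )
  })
}
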