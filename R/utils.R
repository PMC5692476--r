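# Internal helpers shared across modules.

# Classed abort so callers can distinguish bad input from fit failure.
abort_input <- function(msg, ...) {
  rlang::abort(msg, class = c("foldkit_input_error", "foldkit_error"), ...)
}

abort_fit <- function(msg, ...) {
  rlang::abort(msg, class = c("foldkit_fit_error", "foldkit_error"), ...)
}

# Validate a transient table: columns, monotone time, enough samples.
check_transient_tbl <- function(data, min_samples = 10,
                                call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    abort_input("`data` must be a data frame of time/signal observations.")
  }
  data <- as_tibble(data)
  if (!all(c("time_s", "signal") %in% names(data))) {
    abort_input("`data` must have columns `time_s` and `signal`.")
  }
  if (!"replicate" %in% names(data)) data$replicate <- "r1"
  if (!"condition" %in% names(data)) data$condition <- "unspecified"
  if (!"batch" %in% names(data)) data$batch <- NA_character_
  if (any(!is.finite(data$time_s)) || any(!is.finite(data$signal))) {
    abort_input("`time_s` and `signal` must be finite.")
  }
  split_keys <- transient_keys(data)
  for (g in split(data, split_keys)) {
    if (nrow(g) < min_samples) {
      abort_input(sprintf(
        "each transient needs at least %d samples (replicate '%s' has %d)",
        min_samples, g$replicate[[1]], nrow(g)))
    }
    if (any(diff(g$time_s) <= 0)) {
      abort_input(sprintf(
        "`time_s` must be strictly increasing within replicate '%s'",
        g$replicate[[1]]))
    }
  }
  data
}

# NA-safe grouping key per trace.
transient_keys <- function(data) {
  factor(paste(data$condition, data$replicate, data$batch, sep = "\r"))
}

# Split a transient table into one tibble per trace, stable order.
split_transients <- function(data) {
  unname(split(data, transient_keys(data)))
}

# Derive a stream-specific 32-bit seed from a master seed.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + as.integer(stream) * 10007L) %% 2147483587L
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || (finite && !is.finite(x))) {
    abort_input(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort_input(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
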