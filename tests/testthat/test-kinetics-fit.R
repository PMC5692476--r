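test_that("noiseless single-exponential parameters are recovered exactly", {
  tr <- make_transient(function(t) 5 * exp(-0.01 * t) + 2)
  fit <- fit_exponential_global(tr, 1)
  expect_equal(unname(fit$rates[["k1"]]), 0.01, tolerance = 1e-6)
  expect_equal(fit$traces$A1, 5, tolerance = 1e-6)
  expect_equal(fit$traces$offset, 2, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
})

test_that("replicates share one rate but keep individual amplitudes", {
  k <- 0.0149
  amps <- c(5, 4, 6)
  tr <- dplyr::bind_rows(lapply(1:3, function(i) {
    make_transient(function(t) amps[i] * exp(-k * t) + 1,
                   replicate = paste0("r", i))
  }))
  fit <- fit_exponential_global(tr, 1)
  expect_equal(unname(fit$rates[["k1"]]), k, tolerance = 1e-6)
  expect_equal(sort(fit$traces$A1), sort(amps), tolerance = 1e-5)
  expect_lt(fit$rss, 1e-8)
})

test_that("fitting N identical noiseless replicates matches fitting one", {
  tr1 <- make_transient(function(t) -5 * exp(-0.02 * t) + 6)
  trN <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_transient(function(t) -5 * exp(-0.02 * t) + 6,
                   replicate = paste0("r", i))
  }))
  f1 <- fit_exponential_global(tr1, 1)
  fN <- fit_exponential_global(trN, 1)
  expect_equal(unname(f1$rates), unname(fN$rates), tolerance = 1e-8)
})

test_that("double-exponential rates come back ordered and accurate", {
  tr <- make_transient(function(t) {
    3 * exp(-0.03 * t) + 3 * exp(-0.003 * t) + 1
  }, times = seq(0, 2000, by = 2))
  fit <- fit_exponential_global(tr, 2)
  expect_gt(fit$rates[["k1"]], fit$rates[["k2"]])
  expect_equal(unname(fit$rates[["k1"]]), 0.03, tolerance = 1e-3)
  expect_equal(unname(fit$rates[["k2"]]), 0.003, tolerance = 1e-3)
})

test_that("rate recovery holds across the usable rate range", {
  for (k in 10^seq(-4, 0)) {
    dur <- 10 / k
    times <- seq(0, dur, length.out = 301)
    tr <- make_transient(function(t) 4 * exp(-k * t) + 1, times = times)
    fit <- fit_exponential_global(tr, 1)
    expect_lt(abs(fit$rates[["k1"]] - k) / k, 1e-4)
  }
})

test_that("underdetermined or malformed inputs are rejected", {
  short <- tibble::tibble(time_s = 1:5, signal = exp(-(1:5)))
  expect_error(fit_exponential_global(short), class = "foldkit_input_error")
  expect_error(fit_exponential_global(make_transient(function(t) exp(-t)),
                                      n_exponentials = 3),
               class = "foldkit_input_error")
  nonmono <- tibble::tibble(time_s = c(0:8, 8), signal = rnorm(10))
  expect_error(fit_exponential_global(nonmono),
               class = "foldkit_input_error")
})

test_that("model selection keeps one exponential for one-phase data", {
  set.seed(11)
  correct <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    tr <- generate_transients(rates = 0.015, amplitudes = -5, offset = 6,
                              noise_fraction = 0.02, n_replicates = 1,
                              seed = 1000 + s)
    sel <- select_exponential_model(tr)
    correct <- correct + (sel$n_exponentials == 1L)
  }
  expect_gte(correct / n_seeds, 0.95)
})

test_that("model selection finds two phases when rates differ tenfold", {
  correct <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    tr <- generate_transients(model = "double_exp", rates = c(0.03, 0.003),
                              amplitudes = c(-3, -3), offset = 7,
                              noise_fraction = 0.01, duration = 2000,
                              sample_interval = 2, n_replicates = 1,
                              seed = 2000 + s)
    sel <- select_exponential_model(tr)
    correct <- correct + (sel$n_exponentials == 2L)
  }
  expect_gte(correct / n_seeds, 0.95)
})

test_that("constant signal is reported as having no decay component", {
  flat <- make_transient(function(t) rep(5, length(t)))
  expect_error(select_exponential_model(flat), class = "foldkit_fit_error")
})

test_that("tidy/glance/augment expose the fit in tabular form", {
  tr <- generate_transients(rates = 0.0149, noise_fraction = 0.02,
                            n_replicates = 2, seed = 3)
  fit <- fit_exponential_global(tr, 1)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error") %in% names(td)))
  expect_true("k1" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$n_transients, 2L)
  aug <- augment(fit)
  expect_true(all(c(".fitted", ".resid") %in% names(aug)))
  expect_equal(nrow(aug), nrow(tr))
})
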