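#' Summarize replicate measurements: mean, SD and s.e.m.
#'
#' The standard error of the mean is \eqn{\sigma/\sqrt{n}} with \eqn{\sigma}
#' the sample SD. When `batch` is supplied, values are first averaged within
#' each batch and the s.e.m. is computed across batch means — the convention
#' for kinetic parameters measured over independent liposome batches.
#'
#' @param values Numeric vector of measurements (rates, t50 values, ...).
#' @param batch Optional vector of batch identifiers, same length as
#'   `values`; s.e.m. is then taken across batches.
#' @return A one-row tibble with columns `mean`, `sd`, `sem`, `n`.
#' @examples
#' summarize_values(c(1, 2, 3))  # mean 2, sd 1, sem 1/sqrt(3)
#' @export
summarize_values <- function(values, batch = NULL) {
  if (length(values) == 0) abort_input("`values` must be non-empty")
  if (any(!is.finite(values))) abort_input("`values` must be finite")
  if (!is.null(batch)) {
    if (length(batch) != length(values)) {
      abort_input("`batch` must match `values` in length")
    }
    values <- vapply(split(values, batch), mean, numeric(1))
  }
  n <- length(values)
  s <- if (n > 1) stats::sd(values) else 0
  tibble(mean = mean(values), sd = s, sem = s / sqrt(n), n = n)
}

#' Fold change between two summarized quantities with propagated error
#'
#' Computes the ratio \eqn{R = X/Y} of two means and propagates their
#' standard errors in quadrature:
#' \deqn{\delta R = |R| \sqrt{(\delta X / X)^2 + (\delta Y / Y)^2}}
#' This is the standard comparison of, for example, an observed rate
#' constant or t50 measured with and without a catalyst.
#'
#' @param x,y Each a one-row data frame with columns `mean` and `sem`
#'   (as returned by [summarize_values()]), or a named numeric vector with
#'   elements `mean` and `sem`.
#' @return A one-row tibble with columns `ratio`, `ratio_error`,
#'   `numerator_mean`, `numerator_sem`, `denominator_mean`,
#'   `denominator_sem`.
#' @examples
#' fold_change(c(mean = 14.9, sem = 0.3), c(mean = 1.2, sem = 0.1))
#' @export
fold_change <- function(x, y) {
  x <- as_mean_sem(x, "x")
  y <- as_mean_sem(y, "y")
  if (x[["mean"]] == 0 || y[["mean"]] == 0) {
    abort_input("fold change undefined for a zero mean")
  }
  r <- x[["mean"]] / y[["mean"]]
  dr <- abs(r) * sqrt((x[["sem"]] / x[["mean"]])^2 +
                        (y[["sem"]] / y[["mean"]])^2)
  tibble(
    ratio = r,
    ratio_error = dr,
    numerator_mean = x[["mean"]],
    numerator_sem = x[["sem"]],
    denominator_mean = y[["mean"]],
    denominator_sem = y[["sem"]]
  )
}

as_mean_sem <- function(v, name) {
  if (is.data.frame(v)) {
    if (!all(c("mean", "sem") %in% names(v)) || nrow(v) != 1) {
      abort_input(sprintf(
        "`%s` must be a one-row data frame with columns `mean` and `sem`",
        name))
    }
    return(c(mean = v$mean[[1]], sem = v$sem[[1]]))
  }
  if (is.numeric(v) && all(c("mean", "sem") %in% names(v))) {
    return(v[c("mean", "sem")])
  }
  abort_input(sprintf(
    "`%s` must carry `mean` and `sem` (data frame row or named vector)",
    name))
}
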