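# ggplot2 displays for fitted objects.

#' Plot a global exponential fit over its transients
#'
#' @param object A `foldkit_expfit`.
#' @param ... Unused.
#' @return A ggplot: data points per transient with fitted curves overlaid.
#' @method autoplot foldkit_expfit
#' @export
autoplot.foldkit_expfit <- function(object, ...) {
  aug <- augment(object)
  aug$trace <- paste(aug$replicate, aug$batch, sep = "/")
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal,
                                     colour = .data$trace),
                        alpha = 0.4, size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted,
                                    group = .data$trace),
                       linewidth = 0.6) +
    ggplot2::labs(
      x = "Time (s)", y = "Fluorescence (a.u.)",
      title = sprintf("Global %d-exponential fit (shared %s)",
                      object$n_exponentials,
                      paste(sprintf("%s = %.3g /s", names(object$rates),
                                    object$rates), collapse = ", ")),
      colour = "Transient") +
    ggplot2::theme_minimal()
}

#' Plot a Hill-equation binding fit
#'
#' @param object A `foldkit_hillfit`.
#' @param ... Unused.
#' @return A ggplot: titration points and the fitted binding curve on a
#'   log concentration axis.
#' @method autoplot foldkit_hillfit
#' @export
autoplot.foldkit_hillfit <- function(object, ...) {
  p <- object$parameters
  est <- setNames(p$estimate, p$term)
  pos <- object$data$ligand_M[object$data$ligand_M > 0]
  grid <- exp(seq(log(min(pos)), log(max(pos)), length.out = 200))
  curve <- tibble(
    ligand_M = grid,
    signal = est[["S_U"]] + (est[["S_B"]] - est[["S_U"]]) *
      grid^est[["hill_n"]] /
      (est[["K_d_app"]]^est[["hill_n"]] + grid^est[["hill_n"]])
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$ligand_M, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Ligand (M)", y = "Signal (a.u.)",
      title = sprintf("Hill fit: K_d,app = %.3g M, n = %.2f",
                      est[["K_d_app"]], est[["hill_n"]])) +
    ggplot2::theme_minimal()
}

#' Plot local vs bulk membrane metrics
#'
#' @param object A `foldkit_membrane_profile`.
#' @param ... Unused.
#' @return A patch of two panels: thickness per selection, and order
#'   parameter per bond per selection, mean +/- SD across replicas.
#' @method autoplot foldkit_membrane_profile
#' @export
autoplot.foldkit_membrane_profile <- function(object, ...) {
  s <- object$summary
  s$panel <- ifelse(s$metric == "thickness", "Thickness (Å)",
                    "Order parameter S")
  s$xlab <- ifelse(is.na(s$bond), s$selection,
                   paste(s$selection, s$bond))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$xlab, y = .data$mean,
                                  fill = .data$selection)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Selection") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
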