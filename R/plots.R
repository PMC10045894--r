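#' Plot creep curves
#'
#' Creep length against time, one line per spheroid. Excluded curves are
#' drawn dashed.
#'
#' @param curves Long tibble of creep curves (`time_s`, `length_um`,
#'   `spheroid_id`, optionally `excluded`).
#' @return A ggplot object.
#' @export
plot_creep <- function(curves) {
  stopifnot(is.data.frame(curves))
  if (!"excluded" %in% names(curves)) curves$excluded <- FALSE
  ggplot2::ggplot(curves, ggplot2::aes(.data$time_s, .data$length_um,
                                       colour = .data$spheroid_id,
                                       linetype = .data$excluded)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = "Time (s)", y = "Creep length (µm)",
                  colour = "Spheroid") +
    ggplot2::theme_minimal()
}

#' @rdname fit_modified_maxwell
#' @param object A `creep_fit` object (for `autoplot`).
#' @export
autoplot.creep_fit <- function(object, ...) {
  aug <- augment(object)
  p <- object$params
  g <- ggplot2::ggplot(aug, ggplot2::aes(.data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$length_um), size = 0.8,
                        colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "black") +
    ggplot2::labs(x = "Time (s)", y = "Creep length (µm)") +
    ggplot2::theme_minimal()
  if (isTRUE(object$converged)) {
    # long-time linear flow whose intercept is the elastic deformation
    g <- g + ggplot2::geom_abline(intercept = p[["delta"]],
                                  slope = p[["l_dot_inf"]],
                                  linetype = "dashed", colour = "red3")
  }
  g
}

#' Plot the clogging sweep of the hydraulic network
#'
#' Pressure drop across an open (and a clogged) aspiration channel as a
#' function of how many pockets are already clogged.
#'
#' @param sweep Output of [sweep_clogging()].
#' @return A ggplot object.
#' @export
plot_network <- function(sweep) {
  stopifnot(is.data.frame(sweep))
  long <- tidyr::pivot_longer(sweep, c("open_drop_pa", "clogged_drop_pa"),
                              names_to = "branch", values_to = "drop_pa")
  long$branch <- ifelse(long$branch == "open_drop_pa", "open", "clogged")
  ggplot2::ggplot(dplyr::filter(long, is.finite(.data$drop_pa)),
                  ggplot2::aes(.data$n_clogged, .data$drop_pa,
                               colour = .data$branch)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Clogged pockets", y = "Channel pressure drop (Pa)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cohort summary
#'
#' Bar chart of mean elastic modulus or viscosity with SEM error bars, one
#' bar per group.
#'
#' @param summaries Row-bound [summarize_group()] tables.
#' @param what `"e"` (modulus, Pa) or `"eta"` (viscosity, kPa s).
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summaries, what = c("e", "eta")) {
  what <- match.arg(what)
  m <- if (what == "e") "mean_e_pa" else "mean_eta_kpa_s"
  s <- if (what == "e") "sem_e_pa" else "sem_eta_kpa_s"
  ylab <- if (what == "e") "Elastic modulus (Pa)" else "Viscosity (kPa s)"
  ggplot2::ggplot(summaries,
                  ggplot2::aes(.data$label, .data[[m]])) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[m]] - .data[[s]],
                                        ymax = .data[[m]] + .data[[s]]),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}
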