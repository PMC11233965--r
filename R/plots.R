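#' Plot an imprinting-simulation trajectory
#'
#' Preference curves across the continuum at a handful of time steps,
#' showing how the preference narrows onto the imprinted stimulus.
#'
#' @param object An `imprinting_sim`.
#' @param steps Time steps to draw (default six spread over the run).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.imprinting_sim <- function(object, steps = NULL, ...) {
  if (is.null(steps)) {
    steps <- unique(round(seq(0, object$params$n_steps, length.out = 6)))
  }
  dat <- tidy(object) |> dplyr::filter(.data$step %in% steps)
  ggplot2::ggplot(dat, ggplot2::aes(.data$position, .data$preference,
                                    color = factor(.data$step),
                                    group = .data$step)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(
      xintercept = stimulus_position(object$continuum, object$imprint),
      linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "continuum position", y = "normalized preference",
                  color = "time step",
                  title = paste("Imprinting on", object$imprint)) +
    ggplot2::theme_minimal()
}

#' Plot a generalization curve
#'
#' Mean familiar preference +/- SEM per test stimulus, with the chance
#' level, the rehearsal baseline when present, and optionally a model
#' prediction overlaid.
#'
#' @param object A `generalization_curve`.
#' @param predicted Optional predicted preference percent per stimulus (in
#'   row order), drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.generalization_curve <- function(object, predicted = NULL, ...) {
  dat <- tidy(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$position, .data$mean)) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted",
                        color = "red") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), width = 0.02) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "continuum position",
                  y = "familiar preference (%)") +
    ggplot2::theme_minimal()
  baseline <- attr(object, "rehearsal_baseline")
  if (!is.null(baseline) && is.finite(baseline)) {
    p <- p + ggplot2::geom_hline(yintercept = baseline, color = "red")
  }
  if (!is.null(predicted)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(position = dat$position, mean = predicted),
      linetype = "dashed", color = "red")
  }
  p
}

#' Plot color loci in a 2-D slice of avian tetrahedral space
#'
#' The x-y plane of the tetrahedral projection (the chromatic plane of the
#' three non-UV cones), with the four vertex projections marked.
#'
#' @param loci A tibble from [color_loci()] (columns `x`, `y`; `z` mapped
#'   to point color when present).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_tetra_loci <- function(loci, ...) {
  corners <- tetra_project(relative_catches(diag(4)[, 1L], diag(4)[, 2L],
                                            diag(4)[, 3L], diag(4)[, 4L]))
  corners$label <- c("VS", "S", "M", "L")
  p <- ggplot2::ggplot(loci, ggplot2::aes(.data$x, .data$y))
  p <- if ("z" %in% names(loci)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$z), alpha = 0.6)
  } else {
    p + ggplot2::geom_point(alpha = 0.6)
  }
  p +
    ggplot2::geom_point(data = corners, shape = 4, size = 3) +
    ggplot2::geom_text(data = corners, ggplot2::aes(label = .data$label),
                       nudge_y = 0.04, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", color = "z") +
    ggplot2::theme_minimal()
}
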