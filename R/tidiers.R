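#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an imprinting simulation into long format
#'
#' @param x An `imprinting_sim`.
#' @param ... Unused.
#' @return A tibble with one row per (step, stimulus): `step`, `name`,
#'   `position`, `preference`.
#' @export
tidy.imprinting_sim <- function(x, ...) {
  traj <- x$trajectory
  tibble::tibble(
    step = rep(0:(nrow(traj) - 1L), times = ncol(traj)),
    name = rep(colnames(traj), each = nrow(traj)),
    position = rep(x$continuum$position, each = nrow(traj)),
    preference = as.vector(traj)
  )
}

#' One-row summary of an imprinting simulation
#'
#' @param x An `imprinting_sim`.
#' @param ... Unused.
#' @return A tibble: `imprint`, `alpha`, `sigma`, `n_steps`,
#'   `final_peak` (argmax stimulus of the final row), `final_min`.
#' @export
glance.imprinting_sim <- function(x, ...) {
  final <- x$trajectory[nrow(x$trajectory), ]
  tibble::tibble(
    imprint = x$imprint,
    alpha = x$params$alpha,
    sigma = x$params$sigma,
    n_steps = x$params$n_steps,
    final_peak = names(final)[which.max(final)],
    final_min = min(final)
  )
}

#' Tidy a generalization curve (per-stimulus rows)
#'
#' @param x A `generalization_curve`.
#' @param ... Unused.
#' @return The underlying per-stimulus tibble.
#' @export
tidy.generalization_curve <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "generalization_curve")
  attr(out, "rehearsal_baseline") <- NULL
  attr(out, "gradient") <- NULL
  out
}

#' One-row summary of a generalization curve
#'
#' @param x A `generalization_curve`.
#' @param ... Unused.
#' @return A tibble: `n_stimuli`, `rehearsal_baseline`, `gradient_kind`,
#'   `n_significant` (Holm-adjusted p < 0.05).
#' @export
glance.generalization_curve <- function(x, ...) {
  grad <- attr(x, "gradient")
  tibble::tibble(
    n_stimuli = nrow(x),
    rehearsal_baseline = attr(x, "rehearsal_baseline"),
    gradient_kind = if (is.null(grad)) NA_character_ else grad$kind,
    n_significant = sum(x$p_holm < 0.05, na.rm = TRUE)
  )
}

#' Tidy a gradient fit (per-coefficient rows)
#'
#' @param x A `gradient_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`.
#' @export
tidy.gradient_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}
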