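#' Similarity under an unbiased generalization kernel
#'
#' Shepard's universal law: similarity between two stimuli decays with their
#' perceptual distance, irrespective of direction. Two kernels are offered:
#' exponential `exp(-d / scale)` (Shepard's original form, the default
#' downstream) and gaussian `exp(-d^2 / (2 * scale^2))`. Both equal 1 at
#' zero distance and decrease strictly with distance.
#'
#' @param d Non-negative perceptual distance(s).
#' @param kernel `"exponential"` or `"gaussian"`.
#' @param scale Positive decay scale (lambda for exponential, tau for
#'   gaussian) on the normalized continuum axis.
#' @return Similarity in (0, 1\].
#' @export
similarity <- function(d, kernel = c("exponential", "gaussian"), scale = 0.3) {
  kernel <- match.arg(kernel)
  if (any(d < 0)) rlang::abort("distance must be non-negative")
  if (scale <= 0) rlang::abort("`scale` must be positive")
  switch(kernel,
    exponential = exp(-d / scale),
    gaussian = exp(-d^2 / (2 * scale^2))
  )
}

#' Predicted generalization curve of the unbiased null model
#'
#' The null model carries no predisposition: the imprinted stimulus has value
#' 1 and a test stimulus at distance d has value `similarity(d)`, so under
#' the ratio choice rule the raw familiar preference for test stimulus j is
#' `100 / (1 + similarity(d_j))` percent. The raw curve is then rescaled
#' affinely about the 50% chance level so its extreme equals the observed
#' maximum preference. The result is symmetric around the imprinted stimulus
#' and monotone non-decreasing in distance — a progressively decreasing
#' generalization on both sides, which is exactly the shape the null model is
#' committed to.
#'
#' @param continuum A `stimulus_continuum`.
#' @param imprint Name or 0-based index of the imprinted stimulus.
#' @param kernel,scale Kernel specification, see [similarity()].
#' @param max_pref Observed maximum familiar preference (percent, in
#'   (50, 100\]) that the curve's extreme is scaled to.
#' @return A tibble with one row per stimulus: `name`, `position`,
#'   `distance`, `similarity`, `predicted` (percent).
#' @export
predict_unbiased_curve <- function(continuum, imprint,
                                   kernel = c("exponential", "gaussian"),
                                   scale = 0.3, max_pref = 73) {
  kernel <- match.arg(kernel)
  if (max_pref <= 50 || max_pref > 100) {
    rlang::abort("`max_pref` must lie in (50, 100]")
  }
  pos0 <- stimulus_position(continuum, imprint)
  d <- abs(continuum$position - pos0)
  s <- similarity(d, kernel, scale)
  raw <- 100 / (1 + s)
  dev <- max(abs(raw - 50))
  scaled <- if (dev == 0) rep(50, length(raw)) else
    50 + (raw - 50) * (max_pref - 50) / dev
  tibble::tibble(
    name = continuum$name,
    position = continuum$position,
    distance = d,
    similarity = s,
    predicted = scaled
  )
}

#' Grid-search the kernel scale of the unbiased model against observed means
#'
#' One-dimensional helper: evaluates [predict_unbiased_curve()] on a grid of
#' scales and returns the scale maximizing R-squared against the observed
#' per-stimulus mean preferences. The null model is a qualitative foil, so
#' nothing finer than a grid search is warranted.
#'
#' @param continuum,imprint,kernel,max_pref As in [predict_unbiased_curve()].
#' @param observed Observed mean preference (percent) per stimulus, in
#'   continuum order.
#' @param scales Positive grid of candidate scales.
#' @return A one-row tibble: `kernel`, `scale`, `r_squared`.
#' @export
fit_unbiased_scale <- function(continuum, imprint, observed,
                               kernel = c("exponential", "gaussian"),
                               scales = seq(0.05, 1, by = 0.05),
                               max_pref = 73) {
  kernel <- match.arg(kernel)
  r2 <- purrr::map_dbl(scales, function(sc) {
    pred <- predict_unbiased_curve(continuum, imprint, kernel, sc, max_pref)
    r_squared(pred$predicted, observed)
  })
  best <- which.max(r2)
  tibble::tibble(kernel = kernel, scale = scales[best], r_squared = r2[best])
}
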