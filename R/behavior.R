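#' Arena geometry and zone definition
#'
#' The rectangular home cage used as test apparatus: 90 x 60 cm with a
#' monitor on each short side. The regions within `zone_depth_cm` of each
#' monitor are the choice zones; the remainder is the center. The monitor
#' axis is the coordinate running between the two monitors (x by default).
#'
#' @param length_cm Arena length along the monitor axis (default 90).
#' @param width_cm Arena width (default 60).
#' @param zone_depth_cm Depth of each choice zone (default 20); must leave a
#'   center region (`2 * zone_depth_cm < length_cm`).
#' @param monitor_axis `"x"` or `"y"`.
#' @return A list of class `arena_config`.
#' @export
arena_config <- function(length_cm = 90, width_cm = 60, zone_depth_cm = 20,
                         monitor_axis = c("x", "y")) {
  monitor_axis <- match.arg(monitor_axis)
  if (2 * zone_depth_cm >= length_cm) {
    rlang::abort("zones must leave a center region (2*zone_depth < length)")
  }
  structure(
    list(length_cm = length_cm, width_cm = width_cm,
         zone_depth_cm = zone_depth_cm, monitor_axis = monitor_axis),
    class = "arena_config"
  )
}

#' Filter tracking frames by likelihood
#'
#' Markerless pose estimation attaches a per-frame tracking likelihood;
#' only frames at or above the threshold (0.9 by default, the threshold
#' inclusive) are analysed.
#'
#' @param frames A data frame with at least a `likelihood` column in \[0,1\].
#' @param min_likelihood Inclusive threshold (default 0.9).
#' @return The kept frames, with the retained fraction in attribute
#'   `retained_fraction` (also available via [retained_fraction()]).
#' @export
filter_frames <- function(frames, min_likelihood = 0.9) {
  if (nrow(frames) == 0) rlang::abort("no frames to filter")
  if (any(frames$likelihood < 0 | frames$likelihood > 1)) {
    rlang::abort("likelihoods must lie in [0, 1]")
  }
  kept <- dplyr::filter(frames, .data$likelihood >= min_likelihood)
  attr(kept, "retained_fraction") <- nrow(kept) / nrow(frames)
  kept
}

#' @rdname filter_frames
#' @param filtered A [filter_frames()] result.
#' @export
retained_fraction <- function(filtered) {
  attr(filtered, "retained_fraction")
}

#' Assign frames to familiar / center / unfamiliar zones
#'
#' A frame within `zone_depth_cm` of the wall showing the familiar stimulus
#' is in the familiar zone; within the same depth of the opposite wall, the
#' unfamiliar zone; otherwise the center. A coordinate exactly on the 20-cm
#' line belongs to the monitor zone (the zone definition is inclusive).
#'
#' @param frames Data frame with `x_cm` (and `y_cm`) columns.
#' @param arena An [arena_config()].
#' @param side_of_familiar `"left"` (coordinate 0 end) or `"right"`.
#' @return `frames` with a `zone` factor column
#'   (`familiar`/`center`/`unfamiliar`).
#' @export
assign_zone <- function(frames, arena = arena_config(),
                        side_of_familiar = c("left", "right")) {
  side_of_familiar <- match.arg(side_of_familiar)
  coord <- if (arena$monitor_axis == "x") frames$x_cm else frames$y_cm
  if (any(coord < 0 | coord > arena$length_cm)) {
    rlang::abort("coordinates outside arena bounds along the monitor axis")
  }
  d <- arena$zone_depth_cm
  low <- coord <= d
  high <- coord >= arena$length_cm - d
  zone <- dplyr::case_when(
    low ~ if (side_of_familiar == "left") "familiar" else "unfamiliar",
    high ~ if (side_of_familiar == "left") "unfamiliar" else "familiar",
    TRUE ~ "center"
  )
  frames$zone <- factor(zone, levels = c("familiar", "center", "unfamiliar"))
  frames
}

#' Familiar-preference index
#'
#' `100 * time_familiar / (time_familiar + time_unfamiliar)` percent:
#' 50 means no preference, above 50 preference for the familiar (imprinting)
#' stimulus, below 50 preference for the novel one. Trials with no time in
#' either choice zone carry no information and yield `NA` (excluded).
#'
#' @param time_familiar_s,time_unfamiliar_s Nonnegative dwell times
#'   (seconds). Vectorized.
#' @return Preference percent in \[0, 100\], `NA` where both times are zero.
#' @export
preference_index <- function(time_familiar_s, time_unfamiliar_s) {
  if (any(time_familiar_s < 0) || any(time_unfamiliar_s < 0)) {
    rlang::abort("zone times must be nonnegative")
  }
  total <- time_familiar_s + time_unfamiliar_s
  ifelse(total == 0, NA_real_, 100 * time_familiar_s / total)
}

#' Per-trial zone dwell times from tracking frames
#'
#' Filters frames by likelihood, assigns zones, and credits each retained
#' frame with one frame interval of dwell time (gaps left by discarded
#' frames are not interpolated). Frames must carry `trial_id`, `time_s`,
#' `x_cm`, `y_cm`, `likelihood`; trial metadata must carry `trial_id`,
#' `chick_id`, `phase`, `familiar`, `test`, `side_familiar`.
#'
#' @param frames Tracking frames for any number of trials.
#' @param trials Trial metadata table.
#' @param arena An [arena_config()].
#' @param fps Frames per second of the recording (sets the frame interval).
#' @param min_likelihood Tracking-likelihood threshold (default 0.9).
#' @return A tibble per trial: metadata plus `time_familiar_s`,
#'   `time_center_s`, `time_unfamiliar_s`, `preference` (percent, `NA` if
#'   excluded), and `retained_fraction`.
#' @export
trial_zone_times <- function(frames, trials, arena = arena_config(),
                             fps = 10, min_likelihood = 0.9) {
  if (fps <= 0) rlang::abort("`fps` must be positive")
  dt <- 1 / fps
  # keep only metadata from the trial table: recomputed quantities win
  trials <- dplyr::select(
    trials,
    -dplyr::any_of(c("time_familiar_s", "time_center_s",
                     "time_unfamiliar_s", "preference",
                     "retained_fraction")))
  kept <- filter_frames(frames, min_likelihood)
  frac <- retained_fraction(kept)
  per_trial <- kept |>
    dplyr::inner_join(trials, by = "trial_id") |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::group_modify(function(g, key) {
      z <- assign_zone(g, arena, g$side_familiar[1L])$zone
      tibble::tibble(
        time_familiar_s = sum(z == "familiar") * dt,
        time_center_s = sum(z == "center") * dt,
        time_unfamiliar_s = sum(z == "unfamiliar") * dt
      )
    }) |>
    dplyr::ungroup()
  out <- trials |>
    dplyr::inner_join(per_trial, by = "trial_id") |>
    dplyr::mutate(
      preference = preference_index(.data$time_familiar_s,
                                    .data$time_unfamiliar_s),
      retained_fraction = frac
    )
  tibble::as_tibble(out)
}

#' One-sample t-test against chance level
#'
#' Tests whether preference indices differ from the 50% chance level
#' (two-sided, via [stats::t.test()]).
#'
#' @param values Preference percentages (n >= 2, non-constant).
#' @param mu Null value (default 50).
#' @return A one-row tibble: `estimate`, `t`, `df`, `p_value`.
#' @export
one_sample_t <- function(values, mu = 50) {
  if (length(values) < 2) rlang::abort("need at least 2 values")
  if (stats::sd(values) == 0) {
    rlang::abort("values are constant: t-test undefined")
  }
  fit <- stats::t.test(values, mu = mu)
  tibble::tibble(
    estimate = unname(fit$estimate),
    t = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value
  )
}

#' Holm (step-down Bonferroni) adjustment of p values
#'
#' Wrapper over [stats::p.adjust()] with `method = "holm"`; adjusted values
#' are never smaller than the raw ones and are capped at 1.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted p values, in the original order.
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) {
    rlang::abort("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Best-fitting generalization gradient
#'
#' Least-squares polynomial fits of degree 0 (constant), 1 (linear) and
#' 2 (quadratic) of mean preference on continuum position; the winner is
#' chosen by a small-sample information criterion (AICc by default)
#' computed from the residual sums of squares, ties going to the simpler
#' model.
#'
#' @param positions Stimulus positions on the continuum axis.
#' @param means Mean preference percent per stimulus (>= 4 points so the
#'   quadratic is a candidate).
#' @param criterion `"AICc"`, `"AIC"`, or `"adjR2"`.
#' @return A list of class `gradient_fit`: `kind`
#'   (`constant`/`linear`/`quadratic`), `coefficients`, `fits` (the three
#'   `lm` objects), `criterion`, `scores`.
#' @export
best_fit_gradient <- function(positions, means,
                              criterion = c("AICc", "AIC", "adjR2")) {
  criterion <- match.arg(criterion)
  n <- length(means)
  if (n < 4) rlang::abort("need >= 4 points for the quadratic candidate")
  dat <- data.frame(x = positions, y = means)
  fits <- list(
    constant = stats::lm(y ~ 1, data = dat),
    linear = stats::lm(y ~ x, data = dat),
    quadratic = stats::lm(y ~ x + I(x^2), data = dat)
  )
  scores <- purrr::map_dbl(fits, function(f) {
    rss <- sum(stats::residuals(f)^2)
    p <- length(stats::coef(f))
    k <- p + 1 # +1 for the error variance
    switch(criterion,
      # clamp RSS away from zero so exact fits stay comparable
      AICc = n * log(max(rss, 1e-12) / n) + 2 * k +
        2 * k * (k + 1) / max(n - k - 1, 1e-9),
      AIC = n * log(max(rss, 1e-12) / n) + 2 * k,
      adjR2 = -summary(f)$adj.r.squared
    )
  })
  # which.min takes the first minimum; candidates are ordered by complexity
  kind <- names(scores)[which.min(scores)]
  structure(
    list(kind = kind, coefficients = stats::coef(fits[[kind]]),
         fits = fits, criterion = criterion, scores = scores),
    class = "gradient_fit"
  )
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat("<gradient_fit>", x$kind, "gradient selected by", x$criterion, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Summarize per-chick preferences into a generalization curve
#'
#' Aggregates familiar-preference observations (one or more trials per chick
#' and test stimulus) into the mean +/- SEM curve across chicks, with a
#' rehearsal baseline, per-stimulus one-sample t-tests against 50% with Holm
#' correction, and the best-fitting polynomial gradient.
#'
#' @param observations Data frame with columns `chick_id`, `test`,
#'   `preference` (percent) for test trials; trials may repeat within chick
#'   (averaged per chick first).
#' @param continuum A `stimulus_continuum` ordering the test stimuli.
#' @param rehearsal Optional numeric vector of rehearsal-trial preference
#'   indices (familiar stimulus alone vs blank monitor), pooled into the
#'   baseline mean.
#' @param gradient_criterion Model-selection rule for [best_fit_gradient()].
#' @return An object of class `generalization_curve`: a tibble per test
#'   stimulus (`name`, `position`, `mean`, `sem`, `n`, `t`, `df`, `p_value`,
#'   `p_holm`) with attributes `rehearsal_baseline` and `gradient`.
#' @export
summarize_curve <- function(observations, continuum, rehearsal = NULL,
                            gradient_criterion = "AICc") {
  obs <- observations |>
    dplyr::filter(!is.na(.data$preference)) |>
    dplyr::group_by(.data$chick_id, .data$test) |>
    dplyr::summarise(preference = mean(.data$preference), .groups = "drop")
  chance_test <- function(values) {
    if (length(values) < 2 || stats::sd(values) == 0) {
      return(tibble::tibble(t = NA_real_, p_value = NA_real_))
    }
    fit <- stats::t.test(values, mu = 50)
    tibble::tibble(t = unname(fit$statistic), p_value = fit$p.value)
  }
  per_stim <- obs |>
    dplyr::group_by(name = .data$test) |>
    dplyr::summarise(
      mean = mean(.data$preference),
      sem = stats::sd(.data$preference) / sqrt(dplyr::n()),
      n = dplyr::n(),
      df = dplyr::n() - 1,
      test = list(chance_test(.data$preference)),
      .groups = "drop"
    ) |>
    tidyr::unnest("test")
  if (any(per_stim$n < 2)) {
    rlang::abort("every test stimulus needs at least 2 chicks")
  }
  curve <- continuum |>
    dplyr::select("name", "position") |>
    dplyr::inner_join(per_stim, by = "name") |>
    dplyr::mutate(p_holm = holm_adjust(.data$p_value)) |>
    tibble::as_tibble()
  attr(curve, "rehearsal_baseline") <-
    if (is.null(rehearsal)) NA_real_ else mean(rehearsal, na.rm = TRUE)
  attr(curve, "gradient") <- if (nrow(curve) >= 4)
    best_fit_gradient(curve$position, curve$mean, gradient_criterion)
  class(curve) <- c("generalization_curve", class(curve))
  curve
}

#' Compare a generalization curve to model predictions
#'
#' R-squared of the per-stimulus predicted preferences against the observed
#' means (see [r_squared()]).
#'
#' @param curve A `generalization_curve`.
#' @param predicted Predicted preference percent per stimulus, in the
#'   curve's row order.
#' @return Scalar R-squared.
#' @export
compare_to_model <- function(curve, predicted) {
  r_squared(predicted, curve$mean)
}
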