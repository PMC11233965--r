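#' Parameters of the preference-update model
#'
#' @param alpha Positive update rate: the speed of learning (default 0.01).
#' @param sigma Positive width of the Gaussian update weight on the
#'   normalized \[0, 1\] stimulus axis (default 0.2).
#' @param n_steps Number of update iterations (default 400).
#' @param readout_short,readout_long Time steps at which generalization
#'   curves are read out; defaults 100 (about one day of analysed imprinting
#'   exposure) and 300 (about five days).
#' @return A list of class `update_params`.
#' @export
update_params <- function(alpha = 0.01, sigma = 0.2, n_steps = 400,
                          readout_short = 100, readout_long = 300) {
  if (alpha <= 0) rlang::abort("`alpha` must be positive")
  if (sigma <= 0) rlang::abort("`sigma` must be positive")
  n_steps <- as.integer(n_steps)
  readout_short <- as.integer(readout_short)
  readout_long <- as.integer(readout_long)
  if (n_steps < 0) rlang::abort("`n_steps` must be non-negative")
  if (readout_short < 0 || readout_short > readout_long ||
      readout_long > n_steps) {
    rlang::abort("need 0 <= readout_short <= readout_long <= n_steps")
  }
  structure(
    list(alpha = alpha, sigma = sigma, n_steps = n_steps,
         readout_short = readout_short, readout_long = readout_long),
    class = "update_params"
  )
}

#' Gaussian update weight around the presented stimulus
#'
#' The weight of the experience of seeing the imprinting stimulus: maximal
#' (exactly 1) at the presented stimulus, falling off as a narrow Gaussian
#' with width `sigma` along the continuum, so stimuli perceptually close to
#' the exemplar are updated too. The peak height is fixed at 1; any other
#' height would be absorbed into the update rate alpha.
#'
#' @param continuum A `stimulus_continuum`.
#' @param presented Name or 0-based index of the stimulus shown.
#' @param sigma Positive Gaussian width on the normalized axis.
#' @return Numeric weights in (0, 1\], one per stimulus.
#' @export
update_weight <- function(continuum, presented, sigma = 0.2) {
  if (sigma <= 0) rlang::abort("`sigma` must be positive")
  pos0 <- stimulus_position(continuum, presented)
  exp(-(continuum$position - pos0)^2 / (2 * sigma^2))
}

#' One multiplicative update of a preference curve
#'
#' `pref_i <- pref_i * (1 + alpha * w_i)`, then the whole curve is divided
#' by its maximum. Normalization to the maximum keeps the state bounded and
#' cancels out of every preference ratio, so the choice probabilities the
#' model predicts are unaffected by it.
#'
#' @param pref A `preference_curve`.
#' @param w Update weights, one per stimulus (see [update_weight()]).
#' @param alpha Non-negative update rate.
#' @return A normalized `preference_curve`.
#' @export
imprint_step <- function(pref, w, alpha) {
  if (length(w) != nrow(pref)) rlang::abort("weight length mismatch")
  if (alpha < 0) rlang::abort("`alpha` must be non-negative")
  if (any(pref$preference <= 0)) rlang::abort("preferences must be positive")
  values <- pref$preference * (1 + alpha * w)
  out <- pref
  out$preference <- values / max(values)
  attr(out, "normalized") <- TRUE
  out
}

#' Simulate imprinting on one stimulus
#'
#' Deterministically iterates [imprint_step()] with the same presented
#' stimulus for `n_steps` steps, storing the whole preference trajectory.
#' Because the update multiplier for each stimulus is constant over time,
#' preference ratios obey the closed form
#' `pref_i,T / pref_j,T = (pref_i,0 / pref_j,0) * ((1 + alpha w_i) / (1 + alpha w_j))^T`,
#' which the test suite uses as an independent oracle.
#'
#' @param initial A strictly positive `preference_curve` (the predisposition
#'   at hatching).
#' @param imprint Name or 0-based index of the imprinted stimulus.
#' @param params An [update_params()] list.
#' @return An object of class `imprinting_sim`: list with `trajectory`
#'   (matrix, rows = steps 0..n_steps, columns = stimuli), `continuum`,
#'   `imprint` (name), `params`.
#' @export
simulate_imprinting <- function(initial, imprint, params = update_params()) {
  continuum <- build_continuum(initial$name, positions = initial$position)
  imprint_name <- continuum$name[stimulus_row(continuum, imprint)]
  w <- update_weight(continuum, imprint_name, params$sigma)
  n <- nrow(initial)
  traj <- matrix(NA_real_, nrow = params$n_steps + 1L, ncol = n,
                 dimnames = list(NULL, initial$name))
  cur <- initial$preference / max(initial$preference)
  traj[1L, ] <- cur
  mult <- 1 + params$alpha * w
  if (params$n_steps > 0) {
    for (t in seq_len(params$n_steps)) {
      cur <- cur * mult
      cur <- cur / max(cur)
      traj[t + 1L, ] <- cur
    }
  }
  structure(
    list(trajectory = traj, continuum = continuum, imprint = imprint_name,
         params = params),
    class = "imprinting_sim"
  )
}

#' @export
print.imprinting_sim <- function(x, ...) {
  cat("<imprinting_sim> imprinted on", x$imprint, "|",
      x$params$n_steps, "steps, alpha =", x$params$alpha,
      ", sigma =", x$params$sigma, "\n")
  cat("final preferences:\n")
  print(round(x$trajectory[nrow(x$trajectory), ], 4))
  invisible(x)
}

#' Initial preference curve from predisposition-test choice proportions
#'
#' Inverts the ratio choice rule: a measured double-choice proportion c for
#' stimulus a over b implies `pref_a / pref_b = c / (1 - c)`. The anchor
#' stimulus is fixed at preference 1 and ratios are chained through the graph
#' of measured pairs; stimuli with no measurement are filled by linear
#' interpolation of preference along continuum position between the nearest
#' measured stimuli (constant extrapolation beyond the ends).
#'
#' @param choices A data frame with columns `stimulus_a`, `stimulus_b`,
#'   `mean_choice_a` (proportion in (0,1), the probability of choosing a).
#' @param continuum A `stimulus_continuum` containing all measured stimuli.
#' @param anchor Stimulus name given preference 1.
#' @return A normalized `preference_curve`.
#' @examples
#' cont <- build_continuum(c("Red1", "Red2", "Red3", "Orange",
#'                           "Yellow3", "Yellow2", "Yellow1"))
#' choices <- tibble::tibble(
#'   stimulus_a = c("Red1", "Red1"),
#'   stimulus_b = c("Orange", "Yellow1"),
#'   mean_choice_a = c(0.5, 0.649)
#' )
#' estimate_initial_prefs(choices, cont, anchor = "Red1")
#' @export
estimate_initial_prefs <- function(choices, continuum, anchor) {
  choices <- tibble::as_tibble(choices)
  stopifnot(all(c("stimulus_a", "stimulus_b", "mean_choice_a") %in%
                  names(choices)))
  if (any(choices$mean_choice_a <= 0 | choices$mean_choice_a >= 1)) {
    rlang::abort("choice proportions must lie strictly inside (0, 1)")
  }
  measured <- unique(c(choices$stimulus_a, choices$stimulus_b, anchor))
  stimulus_row(continuum, measured) # validates names
  pref <- stats::setNames(rep(NA_real_, length(measured)), measured)
  pref[anchor] <- 1
  # breadth-first chaining of preference ratios from the anchor
  repeat {
    progressed <- FALSE
    for (k in seq_len(nrow(choices))) {
      a <- choices$stimulus_a[k]
      b <- choices$stimulus_b[k]
      ratio <- choices$mean_choice_a[k] / (1 - choices$mean_choice_a[k])
      if (!is.na(pref[a]) && is.na(pref[b])) {
        pref[b] <- pref[a] / ratio
        progressed <- TRUE
      } else if (!is.na(pref[b]) && is.na(pref[a])) {
        pref[a] <- pref[b] * ratio
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  if (anyNA(pref)) {
    rlang::abort("measured pairs do not connect every stimulus to the anchor")
  }
  known_pos <- stimulus_position(continuum, names(pref))
  ord <- order(known_pos)
  filled <- stats::approx(known_pos[ord], pref[ord],
                          xout = continuum$position, rule = 2)$y
  preference_curve(continuum, filled)
}

#' Predicted generalization curve from a simulation read-out
#'
#' Converts the preference state at time step t into predicted familiar
#' preferences via the ratio choice rule
#' (`100 * pref_imprint / (pref_imprint + pref_j)` percent per test stimulus
#' j), then rescales affinely about the 50% chance anchor so the curve's
#' largest deviation from chance maps to the observed maximum. Predictions
#' below 50% (preference for the unfamiliar stimulus) keep their sign: the
#' rescaling stretches deviations, it never flips them.
#'
#' @param sim An `imprinting_sim`.
#' @param t Time step in 0..n_steps.
#' @param max_observed Observed maximum familiar preference percent in
#'   (50, 100\] — in practice the rehearsal-trial or test maximum.
#' @return A tibble per stimulus: `name`, `position`, `raw` and `predicted`
#'   (percent).
#' @export
predict_generalization <- function(sim, t, max_observed = 73) {
  if (t < 0 || t > sim$params$n_steps) rlang::abort("`t` out of range")
  if (max_observed <= 50 || max_observed > 100) {
    rlang::abort("`max_observed` must lie in (50, 100]")
  }
  state <- sim$trajectory[t + 1L, ]
  p_imp <- state[[sim$imprint]]
  raw <- 100 * p_imp / (p_imp + state)
  dev <- max(abs(raw - 50))
  scaled <- if (dev == 0) rep(50, length(raw)) else
    50 + (raw - 50) * (max_observed - 50) / dev
  tibble::tibble(
    name = sim$continuum$name,
    position = sim$continuum$position,
    raw = as.numeric(raw),
    predicted = as.numeric(scaled)
  )
}

#' Coefficient of determination
#'
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`. Can be negative when
#' the predictions do worse than the observed mean.
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 2);
#'   observations must not all be identical.
#' @return Scalar R-squared, at most 1.
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    rlang::abort("`predicted` and `observed` must have equal length")
  }
  if (length(observed) < 2) rlang::abort("need at least 2 observations")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) rlang::abort("observations are constant: R-squared undefined")
  1 - sum((observed - predicted)^2) / sst
}

#' Best read-out step for an observed generalization curve
#'
#' Scans a grid of time steps and returns the step whose predicted curve
#' (see [predict_generalization()]) maximizes R-squared against the observed
#' per-stimulus means; ties break toward the earliest step.
#'
#' @param sim An `imprinting_sim`.
#' @param observed Observed mean preference (percent) per stimulus, in
#'   continuum order.
#' @param t_grid Time steps to scan (default every step of the simulation).
#' @param max_observed Scaling target, see [predict_generalization()].
#' @return A one-row tibble: `t`, `r_squared`.
#' @export
fit_readout <- function(sim, observed, t_grid = NULL, max_observed = 73) {
  if (is.null(t_grid)) t_grid <- 0:sim$params$n_steps
  if (length(t_grid) == 0) rlang::abort("`t_grid` must be nonempty")
  t_grid <- sort(unique(as.integer(t_grid)))
  r2 <- purrr::map_dbl(t_grid, function(t) {
    r_squared(predict_generalization(sim, t, max_observed)$predicted, observed)
  })
  best <- which.max(r2) # which.max returns the first (smallest t) on ties
  tibble::tibble(t = t_grid[best], r_squared = r2[best])
}
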