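#' Specify a synthetic experimental design
#'
#' The three study designs the generators reproduce:
#' * `short_imprinting` — one imprinting day of 8 sessions x 10 trials
#'   (10 min stimulus each), then a test day of 8 sessions x (2 rehearsal +
#'   8 test) trials where each test stimulus appears exactly once per session;
#' * `long_imprinting` — the same with 5 imprinting days;
#' * `predisposition` — 6 consecutive 20-min double-choice trials between a
#'   stimulus pair, before any imprinting, sides counterbalanced (3 left,
#'   3 right), for 120 min of stimulus presentation in total.
#'
#' @param design One of `"short_imprinting"`, `"long_imprinting"`,
#'   `"predisposition"`.
#' @param n_chicks Number of chicks (>= 1).
#' @param continuum A `stimulus_continuum`; generalization designs need 8
#'   test stimuli.
#' @param imprint Imprinted stimulus name, or for `predisposition` a pair of
#'   stimulus names `c(a, b)` (the index measures preference for a over b).
#' @param seed Integer seed recorded in all outputs.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(design = c("short_imprinting", "long_imprinting",
                                   "predisposition"),
                        n_chicks = 48, continuum, imprint, seed = 1) {
  design <- match.arg(design)
  if (n_chicks < 1) rlang::abort("`n_chicks` must be >= 1")
  if (design == "predisposition") {
    if (length(imprint) != 2) {
      rlang::abort("predisposition designs need a stimulus pair")
    }
  } else {
    if (length(imprint) != 1) rlang::abort("need a single imprinted stimulus")
    if (nrow(continuum) != 8) {
      rlang::abort("generalization designs need a continuum of 8 test stimuli")
    }
  }
  stimulus_row(continuum, imprint) # validates names
  structure(
    list(design = design, n_chicks = as.integer(n_chicks),
         continuum = continuum, imprint = imprint, seed = as.integer(seed)),
    class = "design_spec"
  )
}

#' Ground truth of the behavioral generator
#'
#' The known state the generators sample from, so recovery can be scored.
#' Time allocation between the two choice zones follows a Beta distribution
#' whose mean is the ratio-rule choice probability and whose concentration
#' controls trial-to-trial variability (`Inf` = deterministic). A fixed
#' fraction of each trial is spent in the center region, and a fixed
#' fraction of frames receives a sub-threshold tracking likelihood to
#' exercise the frame filter.
#'
#' @param preferences A `preference_curve` (the true preference state).
#' @param concentration Beta concentration of the familiar-side share
#'   (default 10, giving trial-level SEMs comparable to real chicks);
#'   `Inf` for deterministic time allocation.
#' @param center_fraction Fraction of trial time spent in the center region
#'   (default 0.1; real chicks spend most time near the monitors).
#' @param subthreshold_fraction Fraction of frames with tracking likelihood
#'   below 0.9 (default 0.02, i.e. 98% of frames usable).
#' @param rehearsal_choice Expected familiar-zone share in rehearsal trials,
#'   where the familiar stimulus is shown alone (default 0.73).
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(preferences, concentration = 10,
                         center_fraction = 0.1,
                         subthreshold_fraction = 0.02,
                         rehearsal_choice = 0.73) {
  if (concentration <= 0) rlang::abort("`concentration` must be positive")
  if (center_fraction < 0 || center_fraction >= 1) {
    rlang::abort("`center_fraction` must lie in [0, 1)")
  }
  if (subthreshold_fraction < 0 || subthreshold_fraction > 1) {
    rlang::abort("`subthreshold_fraction` must lie in [0, 1]")
  }
  if (rehearsal_choice <= 0 || rehearsal_choice >= 1) {
    rlang::abort("`rehearsal_choice` must lie in (0, 1)")
  }
  structure(
    list(preferences = preferences, concentration = concentration,
         center_fraction = center_fraction,
         subthreshold_fraction = subthreshold_fraction,
         rehearsal_choice = rehearsal_choice),
    class = "ground_truth"
  )
}

#' Trial schedule of a synthetic design
#'
#' Expands a [design_spec()] into ordered per-trial records with empty zone
#' times. Trial counts follow the study designs exactly: 80 imprinting
#' trials per imprinting day, 16 rehearsal + 64 test trials on the test day
#' (each test stimulus once per session, order randomized per session under
#' the spec's seed), and 6 predisposition trials with sides counterbalanced.
#'
#' @param spec A [design_spec()].
#' @return A tibble of trial records: `trial_id`, `chick_id`, `day`,
#'   `session`, `trial`, `phase`, `familiar`, `test`, `side_familiar`,
#'   `duration_s`, `seed`.
#' @export
make_schedule <- function(spec) {
  withr::with_seed(spec$seed, make_schedule_impl(spec))
}

make_schedule_impl <- function(spec) {
  chicks <- sprintf("chick%03d", seq_len(spec$n_chicks))
  if (spec$design == "predisposition") {
    sched <- tidyr::expand_grid(chick_id = chicks, trial = 1:6) |>
      dplyr::mutate(
        day = 1L, session = 1L, phase = "predisposition",
        familiar = spec$imprint[1L], test = spec$imprint[2L],
        side_familiar = rep(c("left", "right"), 3)[.data$trial],
        duration_s = 1200
      )
  } else {
    n_days <- if (spec$design == "short_imprinting") 1L else 5L
    impr <- tidyr::expand_grid(chick_id = chicks, day = seq_len(n_days),
                               session = 1:8, trial = 1:10) |>
      dplyr::mutate(
        phase = "imprinting", familiar = spec$imprint, test = NA_character_,
        side_familiar = dplyr::if_else(.data$trial %% 2 == 1, "left", "right"),
        duration_s = 600
      )
    test_day <- n_days + 1L
    test <- tidyr::expand_grid(chick_id = chicks, session = 1:8) |>
      dplyr::group_by(.data$chick_id, .data$session) |>
      dplyr::reframe(
        trial = 1:10,
        phase = c("rehearsal", "rehearsal", rep("test", 8)),
        test = c(NA_character_, NA_character_,
                 sample(spec$continuum$name))
      ) |>
      dplyr::mutate(
        day = test_day, familiar = spec$imprint,
        side_familiar = dplyr::if_else(.data$trial %% 2 == 1, "left", "right"),
        duration_s = 600
      )
    sched <- dplyr::bind_rows(impr, test)
  }
  sched |>
    dplyr::arrange(.data$chick_id, .data$day, .data$session, .data$trial) |>
    dplyr::mutate(trial_id = sprintf("t%05d", dplyr::row_number()),
                  seed = spec$seed) |>
    dplyr::select("trial_id", "chick_id", "day", "session", "trial", "phase",
                  "familiar", "test", "side_familiar", "duration_s", "seed")
}

#' Fill a schedule with simulated zone times
#'
#' For each trial, the familiar-side share of stimulus-zone time is drawn
#' from a Beta distribution with mean equal to the ratio-rule choice
#' probability implied by the ground-truth preferences (or the rehearsal
#' share for single-stimulus trials) and the stated concentration, so the
#' expected preference index equals 100 x the true choice probability.
#' Center time is the stated fraction of trial duration.
#'
#' @param schedule A [make_schedule()] tibble (or any subset of it).
#' @param truth A [ground_truth()].
#' @param seed Integer seed (default the schedule's recorded seed).
#' @return The schedule with `time_familiar_s`, `time_center_s`,
#'   `time_unfamiliar_s` filled.
#' @export
simulate_trial_times <- function(schedule, truth, seed = schedule$seed[1L]) {
  pref <- stats::setNames(truth$preferences$preference,
                          truth$preferences$name)
  mu <- purrr::map_dbl(seq_len(nrow(schedule)), function(k) {
    phase <- schedule$phase[k]
    if (phase %in% c("test", "predisposition")) {
      a <- schedule$familiar[k]
      b <- schedule$test[k]
      if (is.na(pref[a]) || is.na(pref[b])) {
        rlang::abort("ground truth lacks a preference for a scheduled pair")
      }
      choice_probability(pref[[a]], pref[[b]])
    } else {
      truth$rehearsal_choice
    }
  })
  withr::with_seed(seed + 1L, {
    share <- if (is.finite(truth$concentration)) {
      stats::rbeta(length(mu), mu * truth$concentration,
                   (1 - mu) * truth$concentration)
    } else {
      mu
    }
    stim_time <- schedule$duration_s * (1 - truth$center_fraction)
    schedule |>
      dplyr::mutate(
        time_familiar_s = share * stim_time,
        time_center_s = .data$duration_s * truth$center_fraction,
        time_unfamiliar_s = (1 - share) * stim_time
      )
  })
}

# reflect a random walk into [lo, hi]
fold_walk <- function(x, lo, hi) {
  span <- hi - lo
  lo + abs(((x - lo) %% (2 * span)) - span)
}

#' Simulate tracking frames for trials with known zone times
#'
#' Produces per-frame centroid coordinates from a biased random walk inside
#' the arena: each trial's frames are divided among zone bouts
#' (familiar / center / unfamiliar blocks matching the trial's zone times to
#' within one frame interval), and within a bout the chick performs a
#' reflected Gaussian walk confined to that zone (with a small margin so no
#' frame sits exactly on a zone boundary). A stated fraction of frames
#' receives a tracking likelihood below 0.9, the rest at or above it.
#'
#' @param trials Trials with zone times (from [simulate_trial_times()]).
#' @param arena An [arena_config()].
#' @param fps Frames per second (default 10).
#' @param truth A [ground_truth()] (supplies `subthreshold_fraction`).
#' @param seed Integer seed (default the trials' recorded seed).
#' @param step_sd Walk step standard deviation in cm per frame (default 2).
#' @return A tibble of tracked frames: `trial_id`, `time_s`, `x_cm`, `y_cm`,
#'   `likelihood`.
#' @export
simulate_frames <- function(trials, arena = arena_config(), fps = 10,
                            truth = NULL, seed = trials$seed[1L],
                            step_sd = 2) {
  if (fps <= 0) rlang::abort("`fps` must be positive")
  sub_frac <- if (is.null(truth)) 0.02 else truth$subthreshold_fraction
  d <- arena$zone_depth_cm
  L <- arena$length_cm
  margin <- 0.5
  withr::with_seed(seed + 2L, {
    purrr::map_dfr(seq_len(nrow(trials)), function(k) {
      tr <- trials[k, ]
      counts <- c(familiar = round(tr$time_familiar_s * fps),
                  center = round(tr$time_center_s * fps),
                  unfamiliar = round(tr$time_unfamiliar_s * fps))
      n <- sum(counts)
      if (n == 0) return(NULL)
      # interleave bouts: f/c/u/c/f keeps the walk plausible without
      # changing zone totals
      half <- function(x) c(floor(x / 2), ceiling(x / 2))
      bouts <- tibble::tibble(
        zone = c("familiar", "center", "unfamiliar", "center", "familiar"),
        len = c(half(counts["familiar"])[1L], half(counts["center"])[1L],
                counts[["unfamiliar"]], half(counts["center"])[2L],
                half(counts["familiar"])[2L])
      ) |> dplyr::filter(.data$len > 0)
      fam_left <- tr$side_familiar == "left"
      zone_range <- function(zone) {
        switch(zone,
          familiar = if (fam_left) c(margin, d - margin)
                     else c(L - d + margin, L - margin),
          unfamiliar = if (fam_left) c(L - d + margin, L - margin)
                       else c(margin, d - margin),
          center = c(d + margin, L - d - margin)
        )
      }
      x <- purrr::map(seq_len(nrow(bouts)), function(b) {
        rng <- zone_range(bouts$zone[b])
        start <- mean(rng)
        fold_walk(start + cumsum(stats::rnorm(bouts$len[b], 0, step_sd)),
                  rng[1L], rng[2L])
      })
      x <- unlist(x, use.names = FALSE)
      y <- fold_walk(arena$width_cm / 2 +
                       cumsum(stats::rnorm(n, 0, step_sd)),
                     margin, arena$width_cm - margin)
      sub <- stats::runif(n) < sub_frac
      lik <- ifelse(sub, stats::runif(n, 0, 0.89),
                    stats::runif(n, 0.9, 1))
      tibble::tibble(
        trial_id = tr$trial_id,
        time_s = (seq_len(n) - 1L) / fps,
        x_cm = x, y_cm = y, likelihood = lik
      )
    })
  })
}

#' Generate a synthetic library of natural-like reflectance spectra
#'
#' Smooth nonnegative spectra on 300-700 nm built from a low-order positive
#' basis: most samples are broad Gaussian reflectance bumps at short-to-
#' medium wavelengths over a small flat baseline (unsaturated greens, browns
#' and greys, the bulk of natural objects), and a seeded `red_fraction` of
#' samples are sigmoidal long-pass spectra with reflectance concentrated
#' above ~580 nm (the phaeomelanin-like "red" minority). A synthetic
#' stand-in for large reflectance databases, with the red prevalence under
#' experimental control.
#'
#' @param n Number of spectra (>= 0).
#' @param red_fraction Probability that a sample is long-wavelength-
#'   reflecting (default 0.1).
#' @param seed Integer seed; the same seed reproduces the library exactly.
#' @param grid Wavelength grid (default every 2 nm over 300-700).
#' @return A named list of `spectrum` objects (`sample0001`, ...), with the
#'   true red/non-red flag in attribute `is_red`.
#' @export
generate_spectra_library <- function(n, red_fraction = 0.1, seed = 1,
                                     grid = seq(300, 700, by = 2)) {
  if (n < 0) rlang::abort("`n` must be >= 0")
  if (red_fraction < 0 || red_fraction > 1) {
    rlang::abort("`red_fraction` must lie in [0, 1]")
  }
  if (n == 0) return(structure(list(), is_red = logical(0)))
  withr::with_seed(seed, {
    is_red <- stats::runif(n) < red_fraction
    specs <- purrr::map(seq_len(n), function(k) {
      base <- stats::runif(1, 0.02, 0.08)
      if (is_red[k]) {
        mid <- stats::runif(1, 590, 620)
        wid <- stats::runif(1, 12, 25)
        amp <- stats::runif(1, 0.5, 0.9)
        v <- base + amp / (1 + exp(-(grid - mid) / wid))
      } else {
        ctr <- stats::runif(1, 330, 520)
        wid <- stats::runif(1, 40, 70)
        amp <- stats::runif(1, 0.4, 0.9)
        v <- base + amp * exp(-(grid - ctr)^2 / (2 * wid^2))
      }
      spectrum(grid, v)
    })
    names(specs) <- sprintf("sample%04d", seq_len(n))
    attr(specs, "is_red") <- is_red
    specs
  })
}

#' End-to-end parameter-recovery harness
#'
#' Simulates a full synthetic experiment and pushes it back through the
#' analysis chain, reporting how well known ground truth is recovered:
#' * `predisposition` designs: schedule -> simulated zone times ->
#'   preference indices -> per-chick means; reports the recovered pairwise
#'   choice probability against truth.
#' * generalization designs: preference state at the read-out step implied
#'   by `readout_t` -> simulated per-chick test-day indices ->
#'   [summarize_curve()] -> [fit_readout()]; reports the recovered read-out
#'   step against the generating one.
#'
#' @param spec A [design_spec()].
#' @param truth A [ground_truth()]. For generalization designs its
#'   preference curve is taken as the state at hatching; the imprinting
#'   dynamics then produce the state at `readout_t`.
#' @param params An [update_params()] (generalization designs only).
#' @param readout_t Generating read-out step (default
#'   `params$readout_long`).
#' @return A tibble report: `quantity`, `truth`, `recovered`, `abs_error`.
#' @export
recovery_harness <- function(spec, truth, params = update_params(),
                             readout_t = params$readout_long) {
  sched <- make_schedule(spec)
  if (spec$design == "predisposition") {
    timed <- simulate_trial_times(sched, truth, seed = spec$seed)
    per_chick <- timed |>
      dplyr::mutate(preference = preference_index(.data$time_familiar_s,
                                                  .data$time_unfamiliar_s)) |>
      dplyr::group_by(.data$chick_id) |>
      dplyr::summarise(preference = mean(.data$preference, na.rm = TRUE))
    pref <- stats::setNames(truth$preferences$preference,
                            truth$preferences$name)
    true_choice <- choice_probability(pref[[spec$imprint[1L]]],
                                      pref[[spec$imprint[2L]]])
    recovered <- mean(per_chick$preference) / 100
    return(tibble::tibble(
      quantity = paste0("choice_", spec$imprint[1L], "_vs_", spec$imprint[2L]),
      truth = true_choice, recovered = recovered,
      abs_error = abs(recovered - true_choice)
    ))
  }
  # generalization design: generate observed test-day behavior from the
  # dynamics at readout_t, then recover the read-out step
  sim <- simulate_imprinting(truth$preferences, spec$imprint, params)
  state <- sim$trajectory[readout_t + 1L, ]
  state_truth <- ground_truth(
    preference_curve(spec$continuum, state),
    concentration = truth$concentration,
    center_fraction = truth$center_fraction,
    subthreshold_fraction = truth$subthreshold_fraction,
    rehearsal_choice = truth$rehearsal_choice
  )
  test_day <- dplyr::filter(sched, .data$phase %in% c("test", "rehearsal"))
  timed <- simulate_trial_times(test_day, state_truth, seed = spec$seed)
  timed <- dplyr::mutate(timed,
    preference = preference_index(.data$time_familiar_s,
                                  .data$time_unfamiliar_s))
  curve <- summarize_curve(dplyr::filter(timed, .data$phase == "test"),
                           spec$continuum,
                           rehearsal = timed$preference[timed$phase ==
                                                          "rehearsal"])
  observed <- curve$mean[match(sim$continuum$name, curve$name)]
  max_obs <- min(max(max(observed), 50.5), 100)
  fit <- fit_readout(sim, observed, max_observed = max_obs)
  tibble::tibble(
    quantity = "readout_step",
    truth = readout_t, recovered = as.numeric(fit$t),
    abs_error = abs(fit$t - readout_t)
  )
}
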