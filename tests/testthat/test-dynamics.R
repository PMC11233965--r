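test_that("update weight peaks at 1 on the presented stimulus and is a
           symmetric Gaussian in position", {
  cont <- red_yellow()
  w <- update_weight(cont, "Orange", sigma = 0.2)
  expect_equal(w[4], 1)
  # one continuum step is 1/7; closed form at that distance
  expect_equal(w[3], exp(-(1 / 7)^2 / (2 * 0.2^2)))
  expect_equal(w[3], w[5])
  expect_equal(w[2], w[6])
  # a stimulus exactly sigma away gets weight exp(-1/2)
  fine <- build_continuum(c("a", "b", "c"), positions = c(0, 0.2, 1))
  expect_equal(update_weight(fine, "a", 0.2)[2], exp(-0.5))
  expect_error(update_weight(cont, "Lime"), "unknown")
  expect_error(update_weight(cont, "Orange", sigma = 0), "positive")
})

test_that("a single update multiplies by (1 + alpha w) and renormalizes", {
  cont <- build_continuum(c("A", "B"))
  pref <- preference_curve(cont, c(1, 1))
  out <- imprint_step(pref, c(1, 0.5), alpha = 0.01)
  expect_equal(out$preference[1] / out$preference[2], 1.01 / 1.005)
  expect_equal(max(out$preference), 1)

  # alpha = 0 leaves the (normalized) curve untouched
  pc <- preference_curve(red_yellow(), 8:1)
  same <- imprint_step(pc, rep(0.5, 8), alpha = 0)
  expect_equal(same$preference, pc$preference)

  # a uniform curve with a peaked weight gains its maximum at the peak
  uni <- preference_curve(red_yellow(), rep(1, 8))
  w <- update_weight(red_yellow(), "Red3", 0.2)
  up <- imprint_step(uni, w, 0.01)
  expect_equal(which.max(up$preference), 3L)
  expect_equal(max(up$preference), 1)

  expect_error(imprint_step(pc, rep(1, 3), 0.01), "mismatch")
})

test_that("simulated trajectories obey the closed-form ratio oracle to 1e-9", {
  init <- hatching_prefs()
  sim <- simulate_imprinting(init, "Red1", update_params())
  w <- update_weight(sim$continuum, "Red1", 0.2)
  traj <- sim$trajectory
  p0 <- init$preference
  for (T in c(1, 50, 100, 300, 400)) {
    for (i in 1:8) for (j in 1:8) {
      observed <- unname(traj[T + 1, i] / traj[T + 1, j])
      expected <- (p0[i] / p0[j]) *
        ((1 + 0.01 * w[i]) / (1 + 0.01 * w[j]))^T
      expect_equal(observed, expected, tolerance = 1e-9)
    }
  }
})

test_that("trajectories start at the normalized initial curve, keep row
           maxima at exactly 1, stay positive, and are constant at alpha 0", {
  init <- hatching_prefs()
  sim <- simulate_imprinting(init, "Red1")
  expect_equal(sim$trajectory[1, ], setNames(init$preference, init$name))
  expect_identical(unname(apply(sim$trajectory, 1, max)), rep(1, 401))
  expect_true(all(sim$trajectory > 0))

  frozen <- simulate_imprinting(init, "Red1",
                                update_params(alpha = 1e-12, n_steps = 50,
                                              readout_short = 10,
                                              readout_long = 50))
  expect_equal(frozen$trajectory[51, ], frozen$trajectory[1, ],
               tolerance = 1e-9)

  none <- simulate_imprinting(init, "Red1",
                              update_params(n_steps = 0, readout_short = 0,
                                            readout_long = 0))
  expect_error(none, NA)
})

test_that("the imprinted stimulus gains relative dominance monotonically", {
  init <- hatching_prefs()
  sim <- simulate_imprinting(init, "Yellow1")
  traj <- sim$trajectory
  imp <- which(colnames(traj) == "Yellow1")
  for (j in setdiff(1:8, imp)) {
    ratios <- traj[, imp] / traj[, j]
    expect_true(all(diff(ratios) > 0))
  }
})

test_that("initial preferences invert the choice rule and interpolate the
           unmeasured stimuli", {
  cont <- red_yellow()
  # equal choice means equal preference
  eq <- estimate_initial_prefs(
    tibble::tibble(stimulus_a = "Red1", stimulus_b = "Yellow1",
                   mean_choice_a = 0.5), cont, "Red1")
  expect_equal(eq$preference[1], eq$preference[8])

  # the measured 0.649 proportion implies a preference ratio near 1.849
  pc <- estimate_initial_prefs(
    tibble::tibble(stimulus_a = "Red1", stimulus_b = "Yellow1",
                   mean_choice_a = 0.649), cont, "Red1")
  expect_equal(pc$preference[1] / pc$preference[8], 0.649 / 0.351,
               tolerance = 1e-12)

  # anchored fill: Red1 = Orange = 1, Yellow1 = 0.5, intermediates between
  full <- hatching_prefs(cont)
  expect_equal(full$preference[full$name == "Red1"], 1)
  expect_equal(full$preference[full$name == "Orange"], 1)
  expect_equal(full$preference[full$name == "Yellow1"], 0.5)
  mid <- full$preference[5:7]
  expect_true(all(mid > 0.5 & mid < 1))
  expect_true(all(diff(full$preference) <= 0))

  expect_error(
    estimate_initial_prefs(
      tibble::tibble(stimulus_a = "Red2", stimulus_b = "Red3",
                     mean_choice_a = 0.6), cont, "Red1"),
    "connect")
  expect_error(
    estimate_initial_prefs(
      tibble::tibble(stimulus_a = "Red1", stimulus_b = "Yellow1",
                     mean_choice_a = 1), cont, "Red1"),
    "inside")
})

test_that("generalization read-outs apply the ratio rule then scale about
           the 50% chance anchor", {
  cont <- red_yellow()
  uni <- preference_curve(cont, rep(1, 8))
  sim <- simulate_imprinting(uni, "Red1")
  at0 <- predict_generalization(sim, 0, 73)
  expect_equal(at0$predicted, rep(50, 8))

  init <- hatching_prefs()
  sim2 <- simulate_imprinting(init, "Red1")
  raw0 <- predict_generalization(sim2, 0, 73)
  expect_equal(raw0$raw[raw0$name == "Red1"], 50)
  expect_equal(raw0$raw[raw0$name == "Yellow1"], 100 / 1.5,
               tolerance = 1e-12)
  # scaling maps the largest deviation from 50 to the observed maximum
  expect_equal(max(abs(predict_generalization(sim2, 100, 73)$predicted - 50)),
               23)
  expect_error(predict_generalization(sim2, 500, 73), "range")
  expect_error(predict_generalization(sim2, 100, 45), "50")
})

test_that("r_squared matches the textbook formula", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(2, 4, 9)
  expect_equal(r_squared(rep(mean(obs), 3), obs), 0)
  expect_equal(r_squared(c(1, 2, 4), c(1, 2, 3)), 0.5)
  expect_error(r_squared(1:3, 1:4), "length")
  expect_error(r_squared(c(1, 2), c(5, 5)), "constant")
})

test_that("fit_readout recovers a self-generated read-out with ties broken
           toward the earliest step", {
  init <- hatching_prefs()
  sim <- simulate_imprinting(init, "Red1")
  target <- predict_generalization(sim, 100, 73)$predicted
  fit <- fit_readout(sim, target, max_observed = 73)
  expect_equal(fit$t, 100)
  expect_equal(fit$r_squared, 1)

  single <- fit_readout(sim, target, t_grid = 250, max_observed = 73)
  expect_equal(single$t, 250)

  # constant observations break r_squared; use a near-flat curve instead
  # to exercise ties: identical grid entries must return the smallest t
  tie <- fit_readout(sim, target, t_grid = c(100, 100, 300),
                     max_observed = 73)
  expect_equal(tie$t, 100)
})

test_that("predisposed imprinting forms its preference faster and both
           trajectories end peaked on the imprinted stimulus", {
  init <- hatching_prefs()
  sim_red <- simulate_imprinting(init, "Red1")
  sim_yel <- simulate_imprinting(init, "Yellow1")

  # the affine scaling pins 50 and the extreme for every curve, so the
  # speed contrast is read from the raw (unscaled) model predictions
  range_at <- function(sim, t) {
    p <- predict_generalization(sim, t, 73)$raw
    max(p) - min(p)
  }
  expect_gt(range_at(sim_red, 100), range_at(sim_yel, 100))
  expect_equal(names(which.max(sim_red$trajectory[401, ])), "Red1")
  expect_equal(names(which.max(sim_yel$trajectory[401, ])), "Yellow1")
})
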