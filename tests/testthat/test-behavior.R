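test_that("frame filtering keeps the 0.9 boundary and reports the retained
           fraction", {
  frames <- tibble::tibble(likelihood = c(1, 1, 1))
  expect_equal(retained_fraction(filter_frames(frames)), 1)

  edge <- tibble::tibble(likelihood = c(0.9, 0.8999999, 0.95))
  kept <- filter_frames(edge)
  expect_equal(nrow(kept), 2)
  expect_true(0.9 %in% kept$likelihood)

  ten <- tibble::tibble(likelihood = c(rep(0.95, 8), 0.5, 0.2))
  expect_equal(retained_fraction(filter_frames(ten)), 0.8)
  expect_error(filter_frames(ten[0, ]), "no frames")
  expect_error(filter_frames(tibble::tibble(likelihood = 1.2)), "0, 1")
})

test_that("zone assignment partitions the arena with inclusive 20-cm
           boundaries", {
  arena <- arena_config()
  fr <- function(x) tibble::tibble(x_cm = x, y_cm = 30)
  z <- function(x, side) as.character(assign_zone(fr(x), arena, side)$zone)
  expect_equal(z(5, "left"), "familiar")
  expect_equal(z(45, "left"), "center")
  expect_equal(z(20, "left"), "familiar")    # boundary is monitor zone
  expect_equal(z(70, "left"), "unfamiliar")  # boundary on the far side
  expect_equal(z(5, "right"), "unfamiliar")
  expect_equal(z(85, "right"), "familiar")
  expect_error(assign_zone(fr(5), arena, "top"), "arg")
  expect_error(assign_zone(fr(95), arena, "left"), "bounds")

  # every in-bounds frame maps to exactly one zone
  sweep <- assign_zone(fr(seq(0, 90, by = 0.5)), arena, "left")
  expect_false(anyNA(sweep$zone))
  expect_error(arena_config(zone_depth_cm = 45), "center")
})

test_that("preference index is the familiar share of choice-zone time", {
  expect_equal(preference_index(60, 60), 50)
  expect_equal(preference_index(73, 27), 73)
  expect_true(is.na(preference_index(0, 0)))
  expect_error(preference_index(-1, 5), "nonnegative")
  # invariant to rescaling both times
  set.seed(3)
  tf <- runif(20, 0, 600)
  tu <- runif(20, 0, 600)
  expect_equal(preference_index(tf, tu), preference_index(7 * tf, 7 * tu))
  expect_true(all(preference_index(tf, tu) >= 0 &
                    preference_index(tf, tu) <= 100))
})

test_that("one-sample t against chance matches the textbook formula", {
  sym <- one_sample_t(c(45, 55, 45, 55))
  expect_equal(sym$t, 0)

  vals <- c(55, 60, 50, 65, 45)
  fit <- one_sample_t(vals)
  # independent hand computation
  t_hand <- (mean(vals) - 50) / (sd(vals) / sqrt(5))
  expect_equal(fit$t, t_hand)
  expect_equal(fit$t, sqrt(2), tolerance = 1e-4)
  expect_equal(fit$df, 4)
  expect_equal(fit$p_value, 2 * (1 - pt(t_hand, 4)))
  expect_equal(fit$p_value, 0.2302, tolerance = 1e-4)
  expect_error(one_sample_t(c(50, 50, 50)), "constant")
  expect_error(one_sample_t(55), "2 values")
})

test_that("Holm adjustment reproduces the step-down arithmetic", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  set.seed(7)
  p <- runif(10)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # independent step-down oracle
  ord <- order(p)
  hand <- cummax((10:1) * p[ord])
  expect_equal(adj[ord], pmin(hand, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("gradient model selection picks the lowest adequate polynomial", {
  x <- (0:7) / 7
  line <- best_fit_gradient(x, 2 * x + 50)
  expect_equal(line$kind, "linear")
  expect_equal(unname(line$coefficients), c(50, 2), tolerance = 1e-8)

  parab <- best_fit_gradient(x, 80 - 120 * (x - 0.5)^2)
  expect_equal(parab$kind, "quadratic")

  flat <- best_fit_gradient(x, rep(50, 8))
  expect_equal(flat$kind, "constant")
  expect_error(best_fit_gradient(x[1:3], rep(1, 3)), "4 points")
})

test_that("curve summaries aggregate chicks into mean, SEM and tests", {
  cont <- red_yellow()
  set.seed(13)
  obs <- tidyr::expand_grid(chick_id = sprintf("c%02d", 1:6),
                            test = cont$name) |>
    dplyr::mutate(preference = 55 + rnorm(dplyr::n(), 0, 8))
  curve <- summarize_curve(obs, cont, rehearsal = c(70, 76))
  expect_s3_class(curve, "generalization_curve")
  expect_equal(nrow(curve), 8)
  expect_equal(curve$name, cont$name)
  expect_equal(curve$n, rep(6, 8))
  expect_equal(attr(curve, "rehearsal_baseline"), 73)
  expect_true(all(curve$p_holm >= curve$p_value))

  # hand-check one stimulus against the SEM formula
  one <- obs$preference[obs$test == "Red2"]
  expect_equal(curve$mean[curve$name == "Red2"], mean(one))
  expect_equal(curve$sem[curve$name == "Red2"], sd(one) / sqrt(6))

  # two chicks at 40 and 60: mean 50, SEM 10
  mini <- tidyr::expand_grid(chick_id = c("a", "b"), test = cont$name)
  mini$preference <- ifelse(mini$chick_id == "a", 40, 60)
  mc <- summarize_curve(mini, cont)
  expect_equal(mc$mean, rep(50, 8))
  expect_equal(mc$sem, rep(10, 8))

  single <- dplyr::filter(obs, !(chick_id == "c01" & test == "Red1"))
  expect_error(summarize_curve(dplyr::filter(single, test == "Red1" |
                                               chick_id != "c02"),
                               cont), NA) # still >= 2 chicks everywhere
  lone <- dplyr::filter(obs, chick_id == "c01")
  expect_error(summarize_curve(lone, cont), "2 chicks")
})

test_that("model comparison delegates to R-squared on the observed means", {
  cont <- red_yellow()
  obs <- tidyr::expand_grid(chick_id = c("a", "b", "c"), test = cont$name)
  set.seed(17)
  obs$preference <- 50 + 20 * rep(cont$position, each = 3) + rnorm(24, 0, 2)
  curve <- summarize_curve(obs, cont)
  expect_equal(compare_to_model(curve, curve$mean), 1)
  expect_equal(compare_to_model(curve, rep(mean(curve$mean), 8)), 0)
})

test_that("frames flow through filtering, zoning and dwell accumulation to
           per-trial preference indices", {
  arena <- arena_config()
  trials <- tibble::tibble(
    trial_id = c("t1", "t2"), chick_id = "c1", phase = "test",
    familiar = "Red1", test = c("Orange", "Yellow1"),
    side_familiar = c("left", "right")
  )
  # t1: 6 familiar frames (x<=20, left), 2 center, 2 unfamiliar; one frame
  # sub-threshold in the familiar zone
  f1 <- tibble::tibble(
    trial_id = "t1",
    time_s = (0:9) / 10,
    x_cm = c(rep(5, 6), 45, 45, 80, 80),
    y_cm = 30,
    likelihood = c(0.5, rep(0.95, 9))
  )
  # t2: familiar on the right
  f2 <- tibble::tibble(
    trial_id = "t2", time_s = (0:3) / 10,
    x_cm = c(85, 85, 5, 45), y_cm = 30, likelihood = 0.95
  )
  res <- trial_zone_times(dplyr::bind_rows(f1, f2), trials, arena, fps = 10)
  expect_equal(res$time_familiar_s[res$trial_id == "t1"], 0.5)
  expect_equal(res$time_center_s[res$trial_id == "t1"], 0.2)
  expect_equal(res$time_unfamiliar_s[res$trial_id == "t1"], 0.2)
  expect_equal(res$preference[res$trial_id == "t1"], 100 * 5 / 7)
  expect_equal(res$preference[res$trial_id == "t2"], 100 * 2 / 3)
  expect_equal(unique(res$retained_fraction), 13 / 14)
})
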