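# Shared fixtures: the red-yellow 8-stimulus continuum and the
# predisposition-test choice proportions used to initialize the dynamics.

red_yellow <- function() {
  build_continuum(c("Red1", "Red2", "Red3", "Orange",
                    "Yellow4", "Yellow3", "Yellow2", "Yellow1"))
}

# Red1 ~ Orange at hatching; Red1 about twice as attractive as Yellow1
hatching_choices <- function() {
  tibble::tibble(
    stimulus_a = c("Red1", "Red1"),
    stimulus_b = c("Orange", "Yellow1"),
    mean_choice_a = c(0.5, 2 / 3)
  )
}

hatching_prefs <- function(continuum = red_yellow()) {
  estimate_initial_prefs(hatching_choices(), continuum, anchor = "Red1")
}
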