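#' Bundle the probabilities entering the ideal-observer computation
#'
#' @param p_color_given_target Probability that the imprinting target (the
#'   mother hen) displays the color.
#' @param p_color_given_not_target Probability that some other object in the
#'   environment displays the color.
#' @param p_target Prior probability that an observed object is the target,
#'   treated as a constant (default 0.5).
#' @return A list of class `color_evidence`.
#' @export
color_evidence <- function(p_color_given_target, p_color_given_not_target,
                           p_target = 0.5) {
  if (p_color_given_target < 0 || p_color_given_target > 1 ||
      p_color_given_not_target < 0 || p_color_given_not_target > 1) {
    rlang::abort("likelihoods must lie in [0, 1]")
  }
  if (p_target <= 0 || p_target >= 1) {
    rlang::abort("`p_target` must lie strictly inside (0, 1)")
  }
  if (p_color_given_target == 0 && p_color_given_not_target == 0) {
    rlang::abort("at least one likelihood must be positive")
  }
  structure(
    list(p_color_given_target = p_color_given_target,
         p_color_given_not_target = p_color_given_not_target,
         p_target = p_target),
    class = "color_evidence"
  )
}

#' Posterior probability that an object is the imprinting target given its color
#'
#' Bayes' theorem:
#' `P(t|c) = P(c|t) P(t) / (P(c|t) P(t) + P(c|not t) (1 - P(t)))`.
#' The interest an ideal observer should show in a colored object: it rises
#' with the probability that the target displays the color and falls with
#' the color's prevalence among other objects.
#'
#' @param e A [color_evidence()] object.
#' @return Posterior probability in \[0, 1\].
#' @export
posterior_target_given_color <- function(e) {
  stopifnot(inherits(e, "color_evidence"))
  num <- e$p_color_given_target * e$p_target
  den <- num + e$p_color_given_not_target * (1 - e$p_target)
  num / den
}

#' Likelihood ratio of a color indicating the target
#'
#' `P(color|target) / P(color|not target)`; strictly monotone with the
#' posterior at a fixed prior. Returns `Inf` when the color never occurs on
#' non-target objects but does on the target (exclusive evidence).
#'
#' @param e A [color_evidence()] object.
#' @return Non-negative scalar, possibly `Inf`.
#' @export
likelihood_ratio <- function(e) {
  stopifnot(inherits(e, "color_evidence"))
  if (e$p_color_given_not_target == 0) return(Inf)
  e$p_color_given_target / e$p_color_given_not_target
}

#' Categorize tetrahedral color loci by dominant cone class
#'
#' Coarse categorical binning of relative cone catches: a locus is labelled
#' by its dominant cone (`"vs"`, `"s"`, `"m"`, `"l"`) unless no catch
#' reaches `achromatic_below`, in which case the color is close to the
#' achromatic center and labelled `"achromatic"`. The `"l"` bin is the
#' long-wavelength-dominant ("red") category.
#'
#' @param catches A data frame with columns `u`, `s`, `m`, `l` (relative
#'   catches summing to 1 per row).
#' @param achromatic_below Loci whose maximum relative catch is below this
#'   value count as achromatic (default 0.35).
#' @return Character vector of bin labels, one per row.
#' @export
bin_dominant_cone <- function(catches, achromatic_below = 0.35) {
  m <- as.matrix(catches[, c("u", "s", "m", "l")])
  lab <- c("vs", "s", "m", "l")[max.col(m, ties.method = "first")]
  lab[apply(m, 1L, max) < achromatic_below] <- "achromatic"
  lab
}

#' Relative color frequencies from loci or category labels
#'
#' Counts per bin divided by the total, so frequencies sum to 1 — the
#' color-prevalence summary of a spectra library (how often each color
#' category occurs among flowers, leaves, soil, plumage, ...).
#'
#' @param loci Either a character vector of category labels, or a data frame
#'   of relative catches (columns `u`, `s`, `m`, `l`) binned with `binning`.
#' @param binning Binning function mapping a catches data frame to labels
#'   (default [bin_dominant_cone()]); ignored when `loci` are labels already.
#' @return A tibble of class `color_frequency_table` with columns `bin`,
#'   `frequency`.
#' @export
color_frequency_table <- function(loci, binning = bin_dominant_cone) {
  if (is.data.frame(loci)) {
    if (nrow(loci) == 0) rlang::abort("`loci` must be nonempty")
    loci <- binning(loci)
  }
  if (length(loci) == 0) rlang::abort("`loci` must be nonempty")
  counts <- table(loci)
  out <- tibble::tibble(
    bin = names(counts),
    frequency = as.numeric(counts) / length(loci)
  )
  class(out) <- c("color_frequency_table", class(out))
  out
}

#' Grid binning of tetrahedral loci
#'
#' Alternative to the categorical rule: cuts each Cartesian coordinate of
#' the tetrahedral space into `n_cells` equal intervals over
#' \[-0.75, 0.75\] and labels each locus by its cell.
#'
#' @param loci Data frame with columns `x`, `y`, `z`.
#' @param n_cells Number of cells per axis (default 4).
#' @return Character vector of cell labels.
#' @export
bin_tetra_grid <- function(loci, n_cells = 4) {
  breaks <- seq(-0.75, 0.75, length.out = n_cells + 1L)
  cell <- function(v) {
    idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    if (any(v < breaks[1L] | v > breaks[n_cells + 1L])) {
      rlang::abort("locus outside the tetrahedral grid")
    }
    idx
  }
  paste(cell(loci$x), cell(loci$y), cell(loci$z), sep = ".")
}

#' Color evidence from a target table and an environment table
#'
#' Reads off `P(color|target)` from the target's color-frequency table and
#' `P(color|not target)` from the environment's table at the named bin.
#'
#' @param target_table,environment_table `color_frequency_table`s.
#' @param bin Bin label present in both tables.
#' @param p_target Prior probability of the target (default 0.5).
#' @return A [color_evidence()] object.
#' @export
evidence_from_frequencies <- function(target_table, environment_table, bin,
                                      p_target = 0.5) {
  f_t <- target_table$frequency[match(bin, target_table$bin)]
  f_e <- environment_table$frequency[match(bin, environment_table$bin)]
  if (is.na(f_t) || is.na(f_e)) {
    rlang::abort(paste0("bin '", bin, "' missing from a frequency table"))
  }
  color_evidence(f_t, f_e, p_target)
}
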