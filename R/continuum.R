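#' Build an ordered stimulus continuum
#'
#' A continuum is an ordered set of color stimuli on a normalized perceptual
#' axis: the first stimulus sits at position 0, the last at 1, and distances
#' are symmetric (the distance from Red1 to Yellow1 equals the distance from
#' Yellow1 to Red1). When `positions` is omitted, stimuli are equally spaced,
#' the default because only the order of the stimuli, not their perceptual
#' spacing, is known.
#'
#' @param names Character vector of unique stimulus labels (length >= 2),
#'   in continuum order (e.g. `"Red1"` through `"Yellow1"`).
#' @param positions Optional numeric vector of strictly increasing positions,
#'   same length as `names`; rescaled to span \[0, 1\].
#' @param wavelength_nm Optional approximate dominant wavelengths (metadata).
#' @param rgb Optional data frame or matrix with columns r, g, b (display
#'   metadata only; never used in computation).
#' @return A tibble of class `stimulus_continuum` with columns `name`,
#'   `index` (0-based), `position`, and any metadata supplied.
#' @examples
#' build_continuum(c("Red1", "Red2", "Orange", "Yellow1"))
#' @export
build_continuum <- function(names, positions = NULL, wavelength_nm = NULL,
                            rgb = NULL) {
  names <- as.character(names)
  if (length(names) < 2L) {
    rlang::abort("a continuum needs at least 2 stimuli")
  }
  if (anyDuplicated(names)) {
    rlang::abort("stimulus names must be unique within a continuum")
  }
  n <- length(names)
  if (is.null(positions)) {
    positions <- seq(0, 1, length.out = n)
  } else {
    if (length(positions) != n) {
      rlang::abort("`positions` must match `names` in length")
    }
    if (any(diff(positions) <= 0)) {
      rlang::abort("`positions` must be strictly increasing")
    }
    positions <- (positions - positions[1L]) / (positions[n] - positions[1L])
  }
  out <- tibble::tibble(
    name = names,
    index = seq_len(n) - 1L,
    position = as.numeric(positions)
  )
  if (!is.null(wavelength_nm)) out$wavelength_nm <- as.numeric(wavelength_nm)
  if (!is.null(rgb)) {
    rgb <- as.data.frame(rgb)
    out$r <- rgb[[1L]]
    out$g <- rgb[[2L]]
    out$b <- rgb[[3L]]
  }
  class(out) <- c("stimulus_continuum", class(out))
  out
}

#' Read a continuum definition from a delimited text file
#'
#' Expects a header row and columns `name` plus optional `position`,
#' `wavelength_nm`, `r`, `g`, `b`.
#'
#' @param path Path to a comma- or tab-separated file.
#' @return A [build_continuum()] result.
#' @export
read_continuum <- function(path) {
  tab <- utils::read.delim(path, sep = guess_sep(path),
                           stringsAsFactors = FALSE)
  stopifnot("name" %in% names(tab))
  build_continuum(
    names = tab$name,
    positions = tab[["position"]],
    wavelength_nm = tab[["wavelength_nm"]],
    rgb = if (all(c("r", "g", "b") %in% names(tab))) tab[c("r", "g", "b")]
  )
}

guess_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Perceptual distance between two stimuli
#'
#' Distance along the normalized continuum axis: `|position_i - position_j|`.
#' Symmetric by construction and zero only for a stimulus against itself.
#'
#' @param continuum A `stimulus_continuum`.
#' @param i,j Stimulus names or 0-based indices.
#' @return Non-negative scalar distance.
#' @export
perceptual_distance <- function(continuum, i, j) {
  abs(stimulus_position(continuum, i) - stimulus_position(continuum, j))
}

# resolve a name or 0-based index to a position on the axis
stimulus_position <- function(continuum, id) {
  continuum$position[stimulus_row(continuum, id)]
}

stimulus_row <- function(continuum, id) {
  if (is.character(id)) {
    row <- match(id, continuum$name)
    if (anyNA(row)) {
      rlang::abort(paste0("unknown stimulus: ", id[is.na(row)][1L]))
    }
  } else {
    row <- as.integer(id) + 1L
    if (any(row < 1L) || any(row > nrow(continuum))) {
      rlang::abort("stimulus index out of range")
    }
  }
  row
}

#' Ratio choice rule
#'
#' The probability of approaching stimulus i when stimuli i and j are offered
#' together, choosing in proportion to their evaluated value:
#' `pref_i / (pref_i + pref_j)`. This single choice mechanism is shared by
#' the unbiased null model and the predisposition + update model, so the two
#' differ only in the preference structure they feed it.
#'
#' @param pref_i,pref_j Non-negative preference values, not both zero.
#'   Vectorized.
#' @return Choice probability in \[0, 1\].
#' @examples
#' choice_probability(2, 1) # 2/3
#' @export
choice_probability <- function(pref_i, pref_j) {
  if (any(pref_i < 0) || any(pref_j < 0)) {
    rlang::abort("preferences must be non-negative")
  }
  if (any(pref_i + pref_j == 0)) {
    rlang::abort("choice undefined when both preferences are zero")
  }
  pref_i / (pref_i + pref_j)
}

#' Construct a preference curve over a continuum
#'
#' One strictly positive preference value per stimulus; the model's state.
#' When `normalize = TRUE` (the default) the curve is divided by its maximum
#' so the most preferred stimulus has value 1.
#'
#' @param continuum A `stimulus_continuum`.
#' @param values Strictly positive numeric vector, one per stimulus.
#' @param normalize Divide by the maximum?
#' @return A tibble of class `preference_curve` with columns `name`,
#'   `position`, `preference` and attribute `normalized`.
#' @export
preference_curve <- function(continuum, values, normalize = TRUE) {
  values <- as.numeric(values)
  if (length(values) != nrow(continuum)) {
    rlang::abort("`values` must supply one preference per stimulus")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    rlang::abort("preferences must be strictly positive and finite")
  }
  if (normalize) values <- values / max(values)
  out <- tibble::tibble(
    name = continuum$name,
    position = continuum$position,
    preference = values
  )
  attr(out, "normalized") <- normalize
  class(out) <- c("preference_curve", class(out))
  out
}
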