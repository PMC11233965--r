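#' Construct a spectrum
#'
#' A wavelength-indexed nonnegative function: reflectance of a stimulus,
#' spectral sensitivity of a photoreceptor, or photon flux of an illuminant.
#'
#' @param wavelength_nm Strictly ascending wavelengths (nm), length >= 2.
#' @param value Nonnegative values, same length.
#' @return A tibble of class `spectrum` with columns `wavelength_nm`, `value`.
#' @export
spectrum <- function(wavelength_nm, value) {
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) < 2L) rlang::abort("need at least 2 samples")
  if (length(value) != length(wavelength_nm)) {
    rlang::abort("`wavelength_nm` and `value` must have equal length")
  }
  if (any(diff(wavelength_nm) <= 0)) {
    rlang::abort("wavelengths must be strictly ascending")
  }
  if (any(value < 0)) rlang::abort("spectral values must be nonnegative")
  out <- tibble::tibble(wavelength_nm = wavelength_nm, value = value)
  class(out) <- c("spectrum", class(out))
  out
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation; grid points outside the measured range get value 0
#' (no extrapolated reflectance).
#'
#' @param spec A `spectrum`.
#' @param grid Target wavelengths (nm).
#' @return A `spectrum` on `grid`.
#' @export
resample <- function(spec, grid = 300:700) {
  if (length(grid) == 0) rlang::abort("`grid` must be nonempty")
  v <- stats::approx(spec$wavelength_nm, spec$value, xout = grid,
                     yleft = 0, yright = 0)$y
  spectrum(grid, v)
}

#' Photoreceptor quantum catch
#'
#' The effective photon capture of one cone class: the integral over
#' 300-700 nm of stimulus reflectance x receptor sensitivity x illuminant
#' photon flux, approximated by the trapezoidal rule on a 1-nm grid. The
#' illuminant defaults to a constant 1 across wavelengths.
#'
#' @param reflectance,sensitivity `spectrum` objects.
#' @param illuminant A `spectrum`, or `NULL` for the unit illuminant.
#' @param grid Integration grid (nm), default `300:700`.
#' @return Nonnegative scalar catch. Linear in the reflectance.
#' @export
quantum_catch <- function(reflectance, sensitivity, illuminant = NULL,
                          grid = 300:700) {
  r <- resample(reflectance, grid)$value
  s <- resample(sensitivity, grid)$value
  i <- if (is.null(illuminant)) rep(1, length(grid)) else
    resample(illuminant, grid)$value
  pracma::trapz(as.numeric(grid), r * s * i)
}

#' Normalize four cone catches to relative catches
#'
#' Divides each of the four single-cone quantum catches by their sum,
#' yielding the relative \{vs s m l\} values (u = vs) that sum to 1; the
#' barycentric coordinates of the color in the avian cone space.
#'
#' @param qc_vs,qc_s,qc_m,qc_l Nonnegative catches (UV/violet-, short-,
#'   medium-, long-wavelength-sensitive cones), not all zero. Vectorized.
#' @return A tibble with columns `u`, `s`, `m`, `l` summing to 1 per row.
#' @export
relative_catches <- function(qc_vs, qc_s, qc_m, qc_l) {
  if (any(c(qc_vs, qc_s, qc_m, qc_l) < 0)) {
    rlang::abort("quantum catches must be nonnegative")
  }
  total <- qc_vs + qc_s + qc_m + qc_l
  if (any(total == 0)) rlang::abort("all four catches are zero")
  tibble::tibble(u = qc_vs / total, s = qc_s / total,
                 m = qc_m / total, l = qc_l / total)
}

#' Project relative cone catches into avian tetrahedral color space
#'
#' The standard Cartesian projection of the \{vs s m l\} simplex:
#' \deqn{x = \frac{1 - 2s - m - u}{2}\sqrt{\frac{3}{2}}, \quad
#'       y = \frac{-1 + 3m + u}{2\sqrt{2}}, \quad
#'       z = u - \frac{1}{4}}
#' A color stimulating only one cone class lands on the corresponding vertex
#' of a regular tetrahedron (each at distance 0.75 from the origin); equal
#' stimulation of all four cones — an achromatic color — lands at the origin
#' (0, 0, 0).
#'
#' @param rc A data frame of relative catches (columns `u`, `s`, `m`, `l`),
#'   e.g. from [relative_catches()].
#' @return A tibble with columns `x`, `y`, `z`, one row per input row.
#' @export
tetra_project <- function(rc) {
  tibble::tibble(
    x = ((1 - 2 * rc$s - rc$m - rc$u) / 2) * sqrt(3 / 2),
    y = (-1 + 3 * rc$m + rc$u) / (2 * sqrt(2)),
    z = rc$u - 1 / 4
  )
}

#' Read a spectra table from a delimited text file
#'
#' Expects a header row, a first column `wavelength_nm`, and one column per
#' sample; comma- or tab-separated, decimal point. This simple layout is the
#' package's ingestion contract: exports from reflectance libraries such as
#' FReD or the USGS spectral library should be converted to it (one
#' wavelength column, one column per measured sample) before loading.
#'
#' @param path Path to the file.
#' @return A named list of `spectrum` objects, one per sample column.
#' @export
load_spectra <- function(path) {
  tab <- utils::read.delim(path, sep = guess_sep(path), check.names = FALSE)
  if (names(tab)[1L] != "wavelength_nm") {
    rlang::abort("first column must be `wavelength_nm`")
  }
  wl <- tab[[1L]]
  if (any(diff(wl) <= 0)) rlang::abort("wavelengths must be strictly ascending")
  samples <- names(tab)[-1L]
  purrr::map(stats::setNames(samples, samples), function(id) {
    v <- tab[[id]]
    if (any(v < 0)) {
      rlang::abort(paste0("negative reflectance in column '", id, "', row ",
                          which(v < 0)[1L]))
    }
    spectrum(wl, v)
  })
}

#' Write a spectra table
#'
#' Inverse of [load_spectra()]: all spectra must share one wavelength grid.
#'
#' @param spectra Named list of `spectrum` objects.
#' @param path Output path (tab-separated).
#' @export
write_spectra <- function(spectra, path) {
  wl <- spectra[[1L]]$wavelength_nm
  ok <- purrr::map_lgl(spectra, ~ identical(.x$wavelength_nm, wl))
  if (!all(ok)) rlang::abort("all spectra must share one wavelength grid")
  tab <- c(list(wavelength_nm = wl), purrr::map(spectra, "value"))
  utils::write.table(as.data.frame(tab), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Synthetic receptor sensitivities of a UV-sensitive tetrachromat
#'
#' Smooth unimodal (log-normal-shaped) sensitivity curves peaking near 370,
#' 445, 508 and 565 nm — a synthetic stand-in emulating the shape of
#' published average ultraviolet-sensitive avian cone sensitivities, shipped
#' for testing and examples. It is not a published sensitivity dataset;
#' analyses of real reflectance data should load measured sensitivities via
#' [load_spectra()].
#'
#' @param peaks Peak wavelengths (nm) of the vs, s, m, l cones.
#' @param width Gaussian width (nm) of each curve on a log-wavelength-like
#'   scale (default 35).
#' @param grid Wavelength grid (default `300:700`).
#' @return A named list of four `spectrum` objects: `vs`, `s`, `m`, `l`.
#' @export
synthetic_receptor_set <- function(peaks = c(vs = 370, s = 445, m = 508,
                                             l = 565),
                                   width = 35, grid = 300:700) {
  purrr::map(as.list(peaks), function(p) {
    spectrum(grid, exp(-(grid - p)^2 / (2 * width^2)))
  })
}

#' Color loci of a set of reflectance spectra
#'
#' Full colorimetric chain for a spectra library: quantum catches of the
#' four cone classes, normalization to relative catches, and projection into
#' tetrahedral color space.
#'
#' @param spectra Named list of reflectance `spectrum` objects.
#' @param receptors Named list of sensitivity spectra `vs`, `s`, `m`, `l`
#'   (default the synthetic set from [synthetic_receptor_set()]).
#' @param illuminant Illuminant `spectrum`, or `NULL` for constant 1.
#' @param grid Integration grid (nm).
#' @return A tibble per sample: `sample`, catches `qc_vs`..`qc_l`, relative
#'   catches `u`, `s`, `m`, `l`, coordinates `x`, `y`, `z`.
#' @export
color_loci <- function(spectra, receptors = synthetic_receptor_set(),
                       illuminant = NULL, grid = 300:700) {
  stopifnot(all(c("vs", "s", "m", "l") %in% names(receptors)))
  qc <- purrr::map_dfr(spectra, function(sp) {
    tibble::tibble(
      qc_vs = quantum_catch(sp, receptors$vs, illuminant, grid),
      qc_s = quantum_catch(sp, receptors$s, illuminant, grid),
      qc_m = quantum_catch(sp, receptors$m, illuminant, grid),
      qc_l = quantum_catch(sp, receptors$l, illuminant, grid)
    )
  })
  rc <- relative_catches(qc$qc_vs, qc$qc_s, qc$qc_m, qc$qc_l)
  dplyr::bind_cols(
    tibble::tibble(sample = names(spectra)), qc, rc, tetra_project(rc)
  )
}
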