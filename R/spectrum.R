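#' Steady-state emission spectrum
#'
#' Container for one Laurdan emission scan at one temperature: a strictly
#' increasing wavelength grid (nm) with non-negative intensities in
#' arbitrary fluorescence units.
#'
#' @param wavelength Numeric, nm, strictly increasing.
#' @param intensity Numeric, same length, non-negative.
#' @param temperature Sample temperature, degrees C.
#' @param sample_id Sample label.
#' @param scan_index Integer scan number, or the string `"averaged"` for a
#'   scan-averaged spectrum.
#' @return An object of class `"emission_spectrum"`.
#' @export
emission_spectrum <- function(wavelength, intensity, temperature,
                              sample_id = "sample", scan_index = 1L) {
  if (length(wavelength) != length(intensity))
    stop_typed("laurdanGP_input_error",
               "wavelength and intensity must have the same length")
  if (length(wavelength) < 2L || any(diff(wavelength) <= 0))
    stop_typed("laurdanGP_input_error",
               "wavelengths must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop_typed("laurdanGP_input_error",
               "intensities must be finite and non-negative")
  if (!is_scalar_number(temperature))
    stop_typed("laurdanGP_input_error", "temperature must be a finite number")
  structure(list(wavelength = as.numeric(wavelength),
                 intensity = as.numeric(intensity),
                 temperature = temperature,
                 sample_id = sample_id,
                 scan_index = scan_index),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("Emission spectrum: %s, scan %s, %.1f degC, %d points (%g-%g nm)\n",
              x$sample_id, as.character(x$scan_index), x$temperature,
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Average repeated scans of one spectrum
#'
#' Pointwise arithmetic mean of the intensities of repeated scans acquired
#' at the same temperature on the same wavelength grid — the scan-averaging
#' step that precedes any GP calculation. A steady-state spectrum in this
#' package is the simple average of its scans (three, in the standard
#' acquisition).
#'
#' @param scans List of [emission_spectrum()] objects with identical
#'   wavelength grids and temperatures.
#' @return A single averaged `emission_spectrum` with
#'   `scan_index = "averaged"`.
#' @export
average_scans <- function(scans) {
  if (!is.list(scans) || length(scans) < 1L ||
      !all(vapply(scans, inherits, logical(1), "emission_spectrum")))
    stop_typed("laurdanGP_input_error",
               "average_scans expects a non-empty list of emission spectra")
  ref <- scans[[1L]]
  for (s in scans[-1L]) {
    if (length(s$wavelength) != length(ref$wavelength) ||
        any(s$wavelength != ref$wavelength))
      stop_typed("laurdanGP_alignment_error",
                 "scans have mismatched wavelength grids")
    if (s$temperature != ref$temperature)
      stop_typed("laurdanGP_alignment_error",
                 "scans have mismatched temperatures")
  }
  avg <- rowMeans(vapply(scans, `[[`, numeric(length(ref$wavelength)),
                         "intensity"))
  emission_spectrum(ref$wavelength, avg, ref$temperature,
                    sample_id = ref$sample_id, scan_index = "averaged")
}

#' Laurdan generalized polarization of a spectrum
#'
#' `GP = (I440 - I490) / (I440 + I490)`, the normalized contrast between
#' the gel-phase (440 nm) and fluid-phase (490 nm) emission intensities.
#' Higher values indicate tighter lipid packing. By default the two
#' wavelengths must be present on the grid exactly (they always are for
#' the standard 400-540 nm, 1 nm acquisition); set `interpolate = TRUE`
#' to read foreign grids by linear interpolation.
#'
#' @param spectrum An [emission_spectrum()].
#' @param interpolate Allow linear interpolation when 440/490 nm are not
#'   grid points (default `FALSE`).
#' @return GP value in `[-1, 1]`.
#' @export
compute_gp <- function(spectrum, interpolate = FALSE) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  i440 <- intensity_at(spectrum, 440, interpolate)
  i490 <- intensity_at(spectrum, 490, interpolate)
  tot <- i440 + i490
  if (tot <= 0)
    stop_typed("laurdanGP_undefined_gp_error",
               "GP undefined: I440 + I490 is not positive")
  (i440 - i490) / tot
}

intensity_at <- function(spectrum, wl, interpolate) {
  hit <- which(abs(spectrum$wavelength - wl) < 1e-9)
  if (length(hit) == 1L) return(spectrum$intensity[hit])
  if (!interpolate)
    stop_typed("laurdanGP_grid_error",
               sprintf("wavelength %g nm not on the grid (strict mode)", wl))
  if (wl < min(spectrum$wavelength) || wl > max(spectrum$wavelength))
    stop_typed("laurdanGP_grid_error",
               sprintf("wavelength %g nm outside the acquired range", wl))
  stats::approx(spectrum$wavelength, spectrum$intensity, xout = wl)$y
}
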