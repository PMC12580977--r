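#' Emission band shape
#'
#' Gaussian spectral band used by the spectrum generator. Laurdan emission
#' is modelled as a mixture of a gel-phase band centred at 440 nm and a
#' fluid-phase band centred at 490 nm.
#'
#' @param center Band centre, nm, within the acquired 400-540 nm window.
#' @param width Spectral standard deviation, nm, positive.
#' @return An object of class `"band_shape"`.
#' @export
band_shape <- function(center, width) {
  if (!is_scalar_number(center) || center < 400 || center > 540)
    stop_typed("laurdanGP_input_error", "band center must lie in [400, 540] nm")
  if (!is_scalar_number(width) || width <= 0)
    stop_typed("laurdanGP_input_error", "band width must be > 0")
  structure(list(center = center, width = width), class = "band_shape")
}

band_value <- function(wavelength, band) {
  exp(-(wavelength - band$center)^2 / (2 * band$width^2))
}

#' Synthesize one Laurdan emission spectrum
#'
#' Generates a two-band emission spectrum whose GP equals the noiseless
#' model prediction at the given temperature. The gel (440 nm) and fluid
#' (490 nm) band amplitudes are solved from a 2x2 linear system so that,
#' with cross-band overlap included, the noiseless intensities at exactly
#' 440 and 490 nm satisfy `compute_gp(spectrum) == ideal_gp(temperature,
#' model)` to numerical precision, while `I440 + I490` equals `scale`.
#' Gaussian intensity noise of standard deviation `model$noise_sd * scale`
#' is then added per wavelength and clipped at zero.
#'
#' @param model A [melt_model()].
#' @param temperature Temperature, degrees C.
#' @param wavelength Wavelength grid, nm; strictly increasing and must
#'   contain 440 and 490 exactly. Default `400:540` (1 nm steps).
#' @param scale Intensity scale: the noiseless `I440 + I490`, arbitrary
#'   units (default 1000).
#' @param band_gel,band_fluid [band_shape()]s of the two emission bands.
#'   The default 15 nm standard deviation keeps the mixture's argmax on the
#'   band centres for all packaged models.
#' @param seed Optional integer seed for the intensity noise; identical
#'   seed and inputs give an identical spectrum. Ignored when
#'   `model$noise_sd == 0`.
#' @param sample_id,scan_index Labels stored on the spectrum.
#' @return An [emission_spectrum()].
#' @examples
#' m <- update(condition_model("DMPC"), noise_sd = 0)
#' s <- synth_spectrum(m, temperature = 10)
#' s$wavelength[which.max(s$intensity)]  # 440: ordered-phase peak
#' @export
synth_spectrum <- function(model, temperature, wavelength = 400:540,
                           scale = 1000,
                           band_gel = band_shape(440, 15),
                           band_fluid = band_shape(490, 15),
                           seed = NULL, sample_id = "synthetic",
                           scan_index = 1L) {
  stopifnot(inherits(model, "melt_model"))
  if (any(diff(wavelength) <= 0))
    stop_typed("laurdanGP_input_error",
               "wavelength grid must be strictly increasing")
  if (!any(abs(wavelength - 440) < 1e-9) || !any(abs(wavelength - 490) < 1e-9))
    stop_typed("laurdanGP_grid_error",
               "wavelength grid must contain 440 and 490 nm exactly")

  gp <- ideal_gp(temperature, model)
  i440 <- scale * (1 + gp) / 2
  i490 <- scale * (1 - gp) / 2

  # Cross-band overlap matrix at the two GP wavelengths.
  G <- rbind(c(band_value(440, band_gel), band_value(440, band_fluid)),
             c(band_value(490, band_gel), band_value(490, band_fluid)))
  if (abs(det(G)) < 1e-10)
    stop_typed("laurdanGP_degenerate_band_error",
               "band shapes make the amplitude system singular")
  amps <- solve(G, c(i440, i490))

  inten <- pmax(0, amps[1L] * band_value(wavelength, band_gel) +
                   amps[2L] * band_value(wavelength, band_fluid))
  if (model$noise_sd > 0) {
    add_noise <- function() {
      pmax(0, inten + stats::rnorm(length(inten), sd = model$noise_sd * scale))
    }
    inten <- if (is.null(seed)) add_noise() else run_with_seed(seed, add_noise())
  }
  emission_spectrum(wavelength, inten, temperature,
                    sample_id = sample_id, scan_index = scan_index)
}

#' Synthesize a replicated temperature series of emission spectra
#'
#' Emulates the standard thermotropic acquisition: for each of
#' `replicates` independent samples and each temperature, `scans_per_spectrum`
#' raw scans are generated with independent noise. Each scan's noise stream
#' is seeded deterministically from `seed` and the (replicate, temperature,
#' scan) indices, so any subset of the series is reproducible in isolation
#' and the whole series is reproducible byte-for-byte.
#'
#' @param model A [melt_model()].
#' @param temperatures Strictly increasing temperature grid, degrees C.
#' @param scans_per_spectrum Raw scans per steady-state spectrum
#'   (default 3).
#' @param replicates Independent samples (default 3).
#' @param seed Integer base seed (default 1).
#' @param condition Optional label, e.g. `"DMPC/LUV"`, carried to curves.
#' @inheritParams synth_spectrum
#' @return An object of class `"spectra_series"`: a list with elements
#'   `spectra` (`spectra[[replicate]][[temp_index]]` is the list of raw
#'   scans), `temperatures`, `model`, `seed`, `condition`, and the
#'   generation settings.
#' @seealso [series_to_curve()] for the average - GP - curve pipeline.
#' @export
synth_series <- function(model, temperatures, scans_per_spectrum = 3,
                         replicates = 3, seed = 1,
                         wavelength = 400:540, scale = 1000,
                         band_gel = band_shape(440, 15),
                         band_fluid = band_shape(490, 15),
                         condition = NULL) {
  stopifnot(inherits(model, "melt_model"))
  if (length(temperatures) < 1L || any(diff(temperatures) <= 0))
    stop_typed("laurdanGP_input_error",
               "temperatures must be strictly increasing")
  if (scans_per_spectrum < 1L || replicates < 1L)
    stop_typed("laurdanGP_input_error",
               "scans_per_spectrum and replicates must be >= 1")

  spectra <- lapply(seq_len(replicates), function(r) {
    lapply(seq_along(temperatures), function(ti) {
      lapply(seq_len(scans_per_spectrum), function(s) {
        synth_spectrum(model, temperatures[ti], wavelength = wavelength,
                       scale = scale, band_gel = band_gel,
                       band_fluid = band_fluid,
                       seed = derive_seed(seed, r, ti, s),
                       sample_id = sprintf("rep%d", r), scan_index = s)
      })
    })
  })
  structure(list(spectra = spectra, temperatures = temperatures,
                 replicates = replicates,
                 scans_per_spectrum = scans_per_spectrum,
                 model = model, seed = seed, condition = condition,
                 wavelength = wavelength, scale = scale),
            class = "spectra_series")
}

#' @export
print.spectra_series <- function(x, ...) {
  cat(sprintf(
    "Spectra series%s: %d replicate(s) x %d temperature(s) x %d scan(s)\n",
    if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
    x$replicates, length(x$temperatures), x$scans_per_spectrum))
  cat(sprintf("  temperatures %g-%g degC, seed %s\n",
              min(x$temperatures), max(x$temperatures),
              as.character(x$seed)))
  invisible(x)
}

# Scan-average every (replicate, temperature) cell of a series.
average_series <- function(series) {
  stopifnot(inherits(series, "spectra_series"))
  lapply(series$spectra, function(rep) lapply(rep, average_scans))
}

#' Run a simulated series through the GP pipeline
#'
#' Convenience wrapper applying the prescribed analysis order to a
#' [synth_series()] result: average the scans of each steady-state
#' spectrum, compute GP per spectrum, then aggregate replicates into a
#' [gp_curve()] (mean and standard deviation across replicates).
#'
#' @param series A `spectra_series`.
#' @param interpolate Passed to [compute_gp()].
#' @return A [gp_curve()].
#' @export
series_to_curve <- function(series, interpolate = FALSE) {
  build_curve(average_series(series), condition = series$condition,
              interpolate = interpolate)
}
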