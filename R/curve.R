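#' GP-versus-temperature curve
#'
#' @param temperature Strictly increasing temperatures, degrees C.
#' @param gp GP values in `[-1, 1]`, same length.
#' @param gp_sd Optional per-temperature standard deviation across
#'   replicates (absent for a single replicate).
#' @param condition Optional `(lipid, scaffold)` label.
#' @return A `data.frame` of class `"gp_curve"` with columns `temperature`,
#'   `gp` and (if supplied) `gp_sd`; the condition label is stored as an
#'   attribute.
#' @export
gp_curve <- function(temperature, gp, gp_sd = NULL, condition = NULL) {
  if (length(temperature) != length(gp))
    stop_typed("laurdanGP_input_error",
               "temperature and gp must have the same length")
  if (length(temperature) > 1L && any(diff(temperature) <= 0))
    stop_typed("laurdanGP_input_error",
               "temperatures must be strictly increasing")
  if (any(!is.finite(gp)) || any(gp < -1 - 1e-12) || any(gp > 1 + 1e-12))
    stop_typed("laurdanGP_input_error", "gp values must lie in [-1, 1]")
  df <- data.frame(temperature = as.numeric(temperature), gp = as.numeric(gp))
  if (!is.null(gp_sd)) {
    if (length(gp_sd) != length(gp))
      stop_typed("laurdanGP_input_error", "gp_sd length mismatch")
    df$gp_sd <- as.numeric(gp_sd)
  }
  structure(df, class = c("gp_curve", "data.frame"), condition = condition)
}

#' @export
print.gp_curve <- function(x, ...) {
  cond <- attr(x, "condition")
  cat(sprintf("GP curve%s: %d temperatures, %g-%g degC\n",
              if (is.null(cond)) "" else paste0(" [", cond, "]"),
              nrow(x), min(x$temperature), max(x$temperature)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
plot.gp_curve <- function(x, ..., xlab = "Temperature (°C)",
                          ylab = "GP", pch = 19) {
  graphics::plot(x$temperature, x$gp, xlab = xlab, ylab = ylab, pch = pch, ...)
  if (!is.null(x$gp_sd) && any(x$gp_sd > 0)) {
    graphics::arrows(x$temperature, x$gp - x$gp_sd,
                     x$temperature, x$gp + x$gp_sd,
                     angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}

#' Aggregate replicate spectra into a GP curve
#'
#' Computes GP per averaged spectrum and replicate, then summarizes across
#' replicates: `gp` is the mean and `gp_sd` the sample standard deviation
#' (n - 1 denominator) of the replicate GP values at each temperature;
#' `gp_sd` is absent for a single replicate. All replicates must share the
#' temperature list.
#'
#' @param averaged A replicate-indexed list; each element is a list of
#'   scan-averaged [emission_spectrum()] objects ordered by temperature
#'   (as produced by averaging each cell of a [synth_series()] or a read
#'   spectra file).
#' @param condition Optional condition label.
#' @param interpolate Passed to [compute_gp()].
#' @return A [gp_curve()].
#' @export
build_curve <- function(averaged, condition = NULL, interpolate = FALSE) {
  if (!is.list(averaged) || length(averaged) < 1L)
    stop_typed("laurdanGP_input_error",
               "build_curve expects a non-empty replicate list")
  temps <- vapply(averaged[[1L]], `[[`, numeric(1), "temperature")
  for (rep in averaged[-1L]) {
    t2 <- vapply(rep, `[[`, numeric(1), "temperature")
    if (length(t2) != length(temps) || any(t2 != temps))
      stop_typed("laurdanGP_alignment_error",
                 "replicates have mismatched temperature lists")
  }
  gp_mat <- vapply(averaged, function(rep)
    vapply(rep, compute_gp, numeric(1), interpolate = interpolate),
    numeric(length(temps)))
  gp_mat <- matrix(gp_mat, nrow = length(temps))
  gp_mean <- rowMeans(gp_mat)
  gp_sd <- if (ncol(gp_mat) > 1L) apply(gp_mat, 1L, stats::sd) else NULL
  gp_curve(temps, gp_mean, gp_sd = gp_sd, condition = condition)
}

as_gp_curve <- function(x) {
  if (inherits(x, "gp_curve")) return(x)
  if (is.data.frame(x) && all(c("temperature", "gp") %in% names(x)))
    return(gp_curve(x$temperature, x$gp, gp_sd = x$gp_sd,
                    condition = attr(x, "condition")))
  stop_typed("laurdanGP_input_error",
             "expected a gp_curve or a data.frame with temperature and gp")
}

#' Moving-average smoothing of a GP curve
#'
#' Optional centred moving-average filter for noisy measured curves; not
#' applied by default anywhere in the pipeline (the standard analysis
#' differentiates the raw replicate-averaged curve).
#'
#' @param curve A [gp_curve()].
#' @param window Odd window length in points (default 3).
#' @return A smoothed [gp_curve()] (endpoints kept unsmoothed).
#' @export
smooth_gp <- function(curve, window = 3L) {
  curve <- as_gp_curve(curve)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop_typed("laurdanGP_input_error", "window must be odd and >= 3")
  if (nrow(curve) < window) return(curve)
  sm <- stats::filter(curve$gp, rep(1 / window, window), sides = 2)
  gp <- ifelse(is.na(sm), curve$gp, as.numeric(sm))
  gp_curve(curve$temperature, pmin(1, pmax(-1, gp)), gp_sd = curve$gp_sd,
           condition = attr(curve, "condition"))
}
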