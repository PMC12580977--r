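#' Negative temperature derivative of a GP curve
#'
#' Central finite differences of `-dGP/dT` on the curve's own grid. For
#' interior point `i` the uneven-spacing stencil
#' `-(gp[i+1] - gp[i-1]) / (T[i+1] - T[i-1])` is used (exact for affine
#' GP(T) and, on uniform grids, for quadratics); the endpoints use
#' one-sided differences and are flagged so downstream peak searches can
#' exclude them. The sign convention makes a melting transition a positive
#' peak.
#'
#' @param curve A [gp_curve()] (or data.frame with `temperature`, `gp`)
#'   with at least 3 points.
#' @return A `data.frame` of class `"gp_derivative"` with columns
#'   `temperature` and `neg_dgp_dt`; attribute `endpoint` is a logical
#'   vector marking the one-sided endpoint values.
#' @export
neg_derivative <- function(curve) {
  curve <- as_gp_curve(curve)
  n <- nrow(curve)
  if (n < 3L)
    stop_typed("laurdanGP_insufficient_data_error",
               "central differences need at least 3 temperature points")
  tt <- curve$temperature
  gp <- curve$gp
  d <- numeric(n)
  i <- 2:(n - 1L)
  d[i] <- -(gp[i + 1L] - gp[i - 1L]) / (tt[i + 1L] - tt[i - 1L])
  d[1L] <- -(gp[2L] - gp[1L]) / (tt[2L] - tt[1L])
  d[n] <- -(gp[n] - gp[n - 1L]) / (tt[n] - tt[n - 1L])
  endpoint <- c(TRUE, rep(FALSE, n - 2L), TRUE)
  structure(data.frame(temperature = tt, neg_dgp_dt = d),
            class = c("gp_derivative", "data.frame"),
            endpoint = endpoint, condition = attr(curve, "condition"))
}

trapezoid <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)

#' Extract transition parameters from a GP thermogram
#'
#' Locates the phase transition in the negative derivative `-dGP/dT`:
#' \describe{
#'   \item{`t_m`}{transition temperature — the grid temperature of the
#'     derivative maximum (ties broken toward the lowest temperature;
#'     optional three-point parabolic refinement via `refine_peak`).}
#'   \item{`fwhm`}{cooperativity — full width at half the peak height,
#'     with each half-maximum crossing located by linear interpolation
#'     (smaller = more cooperative).}
#'   \item{`area`}{enthalpy proxy — trapezoidal integral of the derivative
#'     over the full grid, in GP units; for a drift-free two-state model on
#'     a grid spanning the transition it approaches
#'     `gp_gel - gp_fluid`.}
#' }
#' One-sided endpoint derivative values are excluded from the peak search
#' by default. A peak sitting at the edge of the searched range yields a
#' `"boundary-peak"` warning recorded in the result; a half-maximum never
#' crossed on one side raises a typed error carrying the partial result; a
#' flat derivative raises a no-transition error.
#'
#' @param x A [gp_curve()] or a [neg_derivative()] result.
#' @param include_endpoints Include the one-sided endpoint values in the
#'   peak search (default `FALSE`).
#' @param refine_peak Refine `t_m` by fitting a parabola through the peak
#'   and its neighbours (default `FALSE`: grid argmax).
#' @param smooth_window Optional odd integer; if given, the GP curve is
#'   passed through [smooth_gp()] before differentiation (logged in the
#'   result's `warnings`).
#' @param flat_tol Peak heights at or below this are treated as "no
#'   transition" (default `1e-8` GP per degree C).
#' @return An object of class `"transition_result"`: list with `t_m`,
#'   `fwhm`, `area`, `peak_height`, `derivative`, `warnings`, `condition`.
#' @examples
#' m <- update(condition_model("DPPC"), noise_sd = 0)
#' cur <- gp_curve(26:56, ideal_gp(26:56, m))
#' find_transition(cur)
#' @export
find_transition <- function(x, include_endpoints = FALSE, refine_peak = FALSE,
                            smooth_window = NULL, flat_tol = 1e-8) {
  warnings <- character(0)
  if (inherits(x, "gp_derivative")) {
    deriv <- x
  } else {
    curve <- as_gp_curve(x)
    if (!is.null(smooth_window)) {
      curve <- smooth_gp(curve, smooth_window)
      warnings <- c(warnings, sprintf("smoothed: window %d", smooth_window))
    }
    deriv <- neg_derivative(curve)
  }
  if (nrow(deriv) < 3L)
    stop_typed("laurdanGP_insufficient_data_error",
               "need at least 3 derivative points")
  tt <- deriv$temperature
  y <- deriv$neg_dgp_dt
  endpoint <- attr(deriv, "endpoint") %||% rep(FALSE, length(y))

  search <- if (include_endpoints) seq_along(y) else which(!endpoint)
  peak_rel <- which.max(y[search])  # which.max: first maximum = lowest T
  peak <- search[peak_rel]
  height <- y[peak]
  if (!is.finite(height) || height <= flat_tol)
    stop_typed("laurdanGP_no_transition_error",
               "no transition: derivative has no positive peak")
  if (peak == search[1L] || peak == search[length(search)])
    warnings <- c(warnings, "boundary-peak: derivative maximum at the edge of the searched range")

  t_m <- tt[peak]
  if (refine_peak && peak > 1L && peak < length(y)) {
    # Parabola through (t, y) at peak-1, peak, peak+1; vertex location.
    t3 <- tt[(peak - 1L):(peak + 1L)]
    y3 <- y[(peak - 1L):(peak + 1L)]
    den <- (t3[1] - t3[2]) * (t3[1] - t3[3]) * (t3[2] - t3[3])
    a <- (t3[3] * (y3[2] - y3[1]) + t3[2] * (y3[1] - y3[3]) +
            t3[1] * (y3[3] - y3[2])) / den
    b <- (t3[3]^2 * (y3[1] - y3[2]) + t3[2]^2 * (y3[3] - y3[1]) +
            t3[1]^2 * (y3[2] - y3[3])) / den
    if (a < 0) t_m <- -b / (2 * a)
  }

  half <- height / 2
  cross_left <- half_crossing(tt, y, peak, -1L)
  cross_right <- half_crossing(tt, y, peak, +1L)
  partial <- list(t_m = t_m, peak_height = height,
                  area = trapezoid(tt, y), derivative = deriv)
  if (is.na(cross_left) || is.na(cross_right)) {
    side <- if (is.na(cross_left)) "low-temperature" else "high-temperature"
    stop_typed("laurdanGP_fwhm_error",
               sprintf("half-maximum never crossed on the %s side of the peak",
                       side),
               partial = partial)
  }
  structure(list(t_m = t_m, fwhm = cross_right - cross_left,
                 area = trapezoid(tt, y), peak_height = height,
                 derivative = deriv, warnings = warnings,
                 condition = attr(deriv, "condition")),
            class = "transition_result")
}

# Walk outward from the peak in direction `step` until the derivative drops
# through half of the peak height; locate the crossing by linear
# interpolation. Returns NA if the half level is never reached.
half_crossing <- function(tt, y, peak, step) {
  half <- y[peak] / 2
  i <- peak
  repeat {
    j <- i + step
    if (j < 1L || j > length(y)) return(NA_real_)
    if (y[j] <= half) {
      if (y[i] == y[j]) return(tt[j])
      return(tt[i] + (half - y[i]) * (tt[j] - tt[i]) / (y[j] - y[i]))
    }
    i <- j
  }
}

#' @export
print.transition_result <- function(x, ...) {
  cond <- x$condition
  cat(sprintf("Transition%s\n",
              if (is.null(cond)) "" else paste0(" [", cond, "]")))
  cat(sprintf("  T_M          %8.3f degC\n", x$t_m))
  cat(sprintf("  FWHM         %8.3f degC  (cooperativity; smaller = sharper)\n",
              x$fwhm))
  cat(sprintf("  area         %8.4f GP units (enthalpy proxy)\n", x$area))
  cat(sprintf("  peak height  %8.4f GP/degC\n", x$peak_height))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
plot.transition_result <- function(x, ..., xlab = "Temperature (°C)",
                                   ylab = "-dGP/dT") {
  d <- x$derivative
  graphics::plot(d$temperature, d$neg_dgp_dt, type = "l",
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = x$t_m, lty = 2)
  invisible(x)
}

#' Transition-temperature difference between two conditions
#'
#' `t_m(curve_a) - t_m(curve_b)`; e.g. nanodisc minus LUV gives the
#' size-dependent melting-temperature shift. Antisymmetric in its
#' arguments; propagates any [find_transition()] errors.
#'
#' @param curve_a,curve_b [gp_curve()]s.
#' @param ... Passed to [find_transition()].
#' @return Temperature difference, degrees C.
#' @export
delta_tm <- function(curve_a, curve_b, ...) {
  find_transition(curve_a, ...)$t_m - find_transition(curve_b, ...)$t_m
}
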