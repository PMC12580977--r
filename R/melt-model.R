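#' Two-state melting model for Laurdan GP thermograms
#'
#' Constructs the parametric model used throughout the package to describe
#' (and simulate) the temperature dependence of Laurdan generalized
#' polarization (GP) across a gel to liquid-crystalline phase transition.
#' The bilayer is treated as a two-state system: at temperature `T` a
#' fraction [gel_fraction()] of the lipid is in the ordered (gel) phase and
#' the observed GP is the occupancy-weighted mixture of a gel plateau and a
#' fluid plateau, each optionally drifting linearly with temperature.
#'
#' @param gp_gel GP plateau in the ordered (gel) phase, dimensionless,
#'   in `[-1, 1]`. Must exceed `gp_fluid`.
#' @param gp_fluid GP plateau in the disordered (fluid) phase, in `[-1, 1]`.
#' @param t_m Main transition (melting) temperature, degrees C.
#' @param width_k Transition width parameter, degrees C; larger values give
#'   a broader, less cooperative transition. Must be positive. The full
#'   width at half maximum of the `-dGP/dT` peak is
#'   `2 * log(3 + 2 * sqrt(2)) * width_k` (about `3.5255 * width_k`).
#' @param slope_gel,slope_fluid Linear GP drift per degree C of each plateau
#'   below/above the transition (default 0).
#' @param noise_sd Per-wavelength intensity noise standard deviation used by
#'   the spectrum generator, expressed as a fraction of the intensity scale;
#'   must be non-negative. Ignored by the noiseless analytic forms.
#'
#' @return An object of class `"melt_model"`: a validated named list of the
#'   parameters above.
#' @seealso [gel_fraction()], [ideal_gp()], [synth_spectrum()],
#'   [fit_two_state()]
#' @examples
#' m <- melt_model(gp_gel = 0.55, gp_fluid = -0.2, t_m = 24, width_k = 0.4)
#' ideal_gp(c(10, 24, 40), m)
#' @export
melt_model <- function(gp_gel, gp_fluid, t_m, width_k,
                       slope_gel = 0, slope_fluid = 0, noise_sd = 0) {
  m <- structure(
    list(gp_gel = gp_gel, gp_fluid = gp_fluid, t_m = t_m, width_k = width_k,
         slope_gel = slope_gel, slope_fluid = slope_fluid,
         noise_sd = noise_sd),
    class = "melt_model")
  validate_melt_model(m)
}

validate_melt_model <- function(m) {
  for (f in c("gp_gel", "gp_fluid", "t_m", "width_k",
              "slope_gel", "slope_fluid", "noise_sd")) {
    if (!is_scalar_number(m[[f]]))
      stop_typed("laurdanGP_input_error",
                 sprintf("melt_model field '%s' must be a finite number", f))
  }
  if (m$gp_gel <= m$gp_fluid)
    stop_typed("laurdanGP_input_error",
               "melt_model requires gp_gel > gp_fluid")
  if (abs(m$gp_gel) > 1 || abs(m$gp_fluid) > 1)
    stop_typed("laurdanGP_input_error",
               "GP plateaus must lie in [-1, 1]")
  if (m$width_k <= 0)
    stop_typed("laurdanGP_input_error", "width_k must be > 0")
  if (m$noise_sd < 0)
    stop_typed("laurdanGP_input_error", "noise_sd must be >= 0")
  m
}

#' @export
print.melt_model <- function(x, ...) {
  cat("Two-state melting model\n")
  cat(sprintf("  T_M      %7.2f degC\n", x$t_m))
  cat(sprintf("  width_k  %7.3f degC  (FWHM of -dGP/dT peak: %.3f degC)\n",
              x$width_k, 2 * log(3 + 2 * sqrt(2)) * x$width_k))
  cat(sprintf("  GP plateaus  gel %+.3f  fluid %+.3f\n", x$gp_gel, x$gp_fluid))
  if (x$slope_gel != 0 || x$slope_fluid != 0)
    cat(sprintf("  drifts  gel %+.4f  fluid %+.4f per degC\n",
                x$slope_gel, x$slope_fluid))
  if (x$noise_sd > 0)
    cat(sprintf("  intensity noise sd  %.4f (fraction of scale)\n", x$noise_sd))
  invisible(x)
}

#' Update fields of a melt model
#'
#' Replaces one or more parameters of a [melt_model()] and revalidates.
#' Commonly used to switch off the generator noise
#' (`update(m, noise_sd = 0)`).
#'
#' @param object A `melt_model`.
#' @param ... Named fields to replace.
#' @return The modified, revalidated `melt_model`.
#' @export
update.melt_model <- function(object, ...) {
  repl <- list(...)
  bad <- setdiff(names(repl), names(unclass(object)))
  if (length(bad))
    stop_typed("laurdanGP_input_error",
               paste("unknown melt_model field(s):", paste(bad, collapse = ", ")))
  m <- utils::modifyList(unclass(object), repl)
  class(m) <- "melt_model"
  validate_melt_model(m)
}

#' Gel-phase occupancy of a two-state bilayer
#'
#' Logistic occupancy of the ordered phase,
#' `f(T) = 1 / (1 + exp((T - t_m) / width_k))`: 1 far below the transition,
#' 1/2 at `t_m`, 0 far above, strictly decreasing in `T`.
#'
#' @param temperature Temperature(s), degrees C (vectorized).
#' @param model A [melt_model()].
#' @return Gel fraction(s) in `[0, 1]`.
#' @export
gel_fraction <- function(temperature, model) {
  stopifnot(inherits(model, "melt_model"))
  1 / (1 + exp((temperature - model$t_m) / model$width_k))
}

# Unclamped two-state GP in terms of scalar parameters; this is the mean
# function handed to the nonlinear least-squares fit, where clamping would
# destroy gradient information.
two_state_gp <- function(temperature, gp_gel, gp_fluid, t_m, width_k,
                         slope_gel = 0, slope_fluid = 0) {
  f <- 1 / (1 + exp((temperature - t_m) / width_k))
  dT <- temperature - t_m
  (gp_gel + slope_gel * dT) * f + (gp_fluid + slope_fluid * dT) * (1 - f)
}

#' Noiseless GP predicted by a two-state melting model
#'
#' Occupancy-weighted mixture of the two plateau lines,
#' `GP(T) = (gp_gel + slope_gel (T - t_m)) f + (gp_fluid + slope_fluid
#' (T - t_m)) (1 - f)` with `f = ` [gel_fraction()]. With zero drifts,
#' `GP(t_m)` is the midpoint of the plateaus. The result is clamped to
#' `[-1, 1]`, the physical range of a two-wavelength intensity contrast.
#'
#' @inheritParams gel_fraction
#' @return GP value(s) in `[-1, 1]`.
#' @export
ideal_gp <- function(temperature, model) {
  stopifnot(inherits(model, "melt_model"))
  gp <- two_state_gp(temperature, model$gp_gel, model$gp_fluid,
                     model$t_m, model$width_k,
                     model$slope_gel, model$slope_fluid)
  pmin(1, pmax(-1, gp))
}
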