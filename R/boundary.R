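#' Nanodisc boundary-lipid geometry
#'
#' Geometry of the fixed-width perturbed annulus at a nanodisc rim: lipids
#' within `boundary_width` of the scaffold are "perturbed", the interior is
#' "unperturbed". Two variants of the unperturbed fraction are provided:
#' `"radius-ratio"`, `(r - w) / r` with `r = diameter / 2`, and
#' `"area-ratio"`, `((r - w) / r)^2` (the interior-disc to whole-disc area
#' ratio). The package default is the radius-ratio variant with
#' `w = 1.25` nm, the single configuration that reproduces the canonical
#' 77 / 83 / 90 / 95 % unperturbed-lipid figures at 11 / 15 / 25 / 50 nm;
#' the verbal two-lipid-layer annulus (area-ratio, `w = 1.5` nm) is one
#' switch away. See the methods vignette for the discrepancy between the
#' two formulations.
#'
#' @param diameter Nanodisc bilayer diameter, nm, positive.
#' @param boundary_width Perturbed annulus width `w`, nm, non-negative and
#'   at most the radius (default 1.25).
#' @param variant `"radius-ratio"` (default) or `"area-ratio"`.
#' @return An object of class `"disc_geometry"`.
#' @export
disc_geometry <- function(diameter, boundary_width = 1.25,
                          variant = c("radius-ratio", "area-ratio")) {
  variant <- match.arg(variant)
  if (!is_scalar_number(diameter) || diameter <= 0)
    stop_typed("laurdanGP_input_error", "diameter must be > 0")
  if (!is_scalar_number(boundary_width) || boundary_width < 0)
    stop_typed("laurdanGP_input_error", "boundary_width must be >= 0")
  if (boundary_width > diameter / 2)
    stop_typed("laurdanGP_domain_error",
               "boundary_width exceeds the disc radius")
  structure(list(diameter = diameter, boundary_width = boundary_width,
                 variant = variant),
            class = "disc_geometry")
}

#' @export
print.disc_geometry <- function(x, ...) {
  cat(sprintf("Nanodisc geometry: d = %g nm, boundary w = %g nm (%s)\n",
              x$diameter, x$boundary_width, x$variant))
  cat(sprintf("  unperturbed %.1f%%, perturbed %.1f%%\n",
              100 * unperturbed_fraction(x), 100 * perturbed_fraction(x)))
  invisible(x)
}

#' Unperturbed lipid fraction of a nanodisc
#'
#' @param geometry A [disc_geometry()].
#' @return Fraction in `[0, 1]` of lipids outside the perturbed rim
#'   annulus. Strictly increasing in diameter at fixed width, strictly
#'   decreasing in width at fixed diameter; tends to 1 as the diameter
#'   grows.
#' @examples
#' unperturbed_fraction(disc_geometry(50))  # 0.95
#' unperturbed_fraction(disc_geometry(11))  # 0.7727...
#' @export
unperturbed_fraction <- function(geometry) {
  stopifnot(inherits(geometry, "disc_geometry"))
  r <- geometry$diameter / 2
  ratio <- (r - geometry$boundary_width) / r
  if (geometry$variant == "area-ratio") ratio^2 else ratio
}

#' Perturbed (rim) lipid fraction of a nanodisc
#'
#' Exact complement of [unperturbed_fraction()].
#'
#' @inheritParams unperturbed_fraction
#' @return Fraction in `[0, 1]`.
#' @export
perturbed_fraction <- function(geometry) 1 - unperturbed_fraction(geometry)

#' Predicted transition area for a nanodisc
#'
#' Two-population scaling of the enthalpy proxy: only unperturbed lipids
#' contribute to the melting transition, so the predicted `-dGP/dT` area
#' for a disc is the unperturbed-bilayer reference area times the
#' unperturbed fraction. Monotone increasing in diameter.
#'
#' @inheritParams unperturbed_fraction
#' @param reference_area Transition area of the unperturbed bilayer (LUV
#'   reference), GP units, non-negative.
#' @return Predicted area, GP units.
#' @export
predict_relative_area <- function(geometry, reference_area) {
  if (!is_scalar_number(reference_area) || reference_area < 0)
    stop_typed("laurdanGP_input_error", "reference_area must be >= 0")
  reference_area * unperturbed_fraction(geometry)
}

#' Boundary-model predictions for a set of diameters
#'
#' @param diameters Numeric vector of disc diameters, nm (default the four
#'   packaged scaffold sizes 11, 15, 25, 50).
#' @param boundary_width,variant Passed to [disc_geometry()].
#' @return A `data.frame` with columns `diameter`, `variant`,
#'   `boundary_width`, `unperturbed_pct`, `perturbed_pct`.
#' @examples
#' boundary_table()
#' @export
boundary_table <- function(diameters = unname(scaffold_diameters()),
                           boundary_width = 1.25,
                           variant = "radius-ratio") {
  frac <- vapply(diameters, function(d)
    unperturbed_fraction(disc_geometry(d, boundary_width, variant)),
    numeric(1))
  data.frame(diameter = diameters, variant = variant,
             boundary_width = boundary_width,
             unperturbed_pct = 100 * frac,
             perturbed_pct = 100 * (1 - frac))
}
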