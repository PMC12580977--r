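#' Packaged lipid/scaffold condition table
#'
#' Default two-state model parameters for every (lipid, scaffold) condition
#' the package simulates. Scaffolds are the `"LUV"` reference (~100 nm
#' large unilamellar vesicle) and circularized nanodiscs `"spMSP1D1"`
#' (11 nm), `"spNW15"` (15 nm), `"spNW25"` (25 nm) and `"spNW50"` (50 nm).
#'
#' The anchored values are the literature main-transition temperatures for
#' the LUV reference (DMPC 24, DPPC 41, DSPC 54, POPC -2 degrees C) and the
#' transition-temperature offsets of the 11 nm disc relative to LUVs
#' (+5 DMPC, +2 DPPC, 0 DSPC). The 15 nm disc carries the same offset as
#' the 11 nm disc (their transition temperatures are experimentally
#' indistinguishable), the 50 nm disc none (indistinguishable from LUVs),
#' and the 25 nm disc an intermediate value. Transition widths `width_k`
#' decrease strictly from the 11 nm to the 50 nm disc and all exceed the
#' LUV width, encoding the size-dependent cooperativity trend. Plateau
#' levels, widths for intermediate sizes and the noise level are generator
#' defaults, all overridable. POPC melts below the usual assay range and is
#' modelled with a broad transition at -2 degrees C; soy polar extract has
#' no defined transition and gets a phenomenological plateau-offset model
#' with a very broad pseudo-transition.
#'
#' @param overrides Optional `data.frame` with columns among those of the
#'   returned table plus `lipid` and `scaffold`; matching rows replace the
#'   packaged defaults, non-matching rows are appended.
#' @return A `data.frame` with one row per condition and columns `lipid`,
#'   `scaffold`, `gp_gel`, `gp_fluid`, `t_m`, `width_k`, `slope_gel`,
#'   `slope_fluid`, `noise_sd`.
#' @seealso [condition_model()], [scaffold_diameters()]
#' @export
lipid_conditions <- function(overrides = NULL) {
  scaffolds <- c("LUV", "spMSP1D1", "spNW15", "spNW25", "spNW50")
  base <- data.frame(
    lipid    = c("DMPC", "DPPC", "DSPC", "POPC", "SoyPolar"),
    t_m      = c(24, 41, 54, -2, 20),
    gp_gel   = c(0.55, 0.60, 0.62, 0.45, 0.10),
    gp_fluid = c(-0.20, -0.15, -0.12, -0.25, -0.45),
    stringsAsFactors = FALSE)

  # T_M offset (degC) of each scaffold relative to the LUV reference.
  tm_offset <- rbind(
    DMPC     = c(0, 5, 5, 2, 0),
    DPPC     = c(0, 2, 2, 1, 0),
    DSPC     = c(0, 0, 0, 0, 0),
    POPC     = c(0, 0, 0, 0, 0),
    SoyPolar = c(0, 0, 0, 0, 0))
  width <- rbind(
    DMPC     = c(0.4, 3.0, 2.6, 1.8, 1.0),
    DPPC     = c(0.4, 3.0, 2.6, 1.8, 1.0),
    DSPC     = c(0.4, 3.0, 2.6, 1.8, 1.0),
    POPC     = c(2.0, 4.0, 3.6, 3.0, 2.4),
    SoyPolar = c(12, 14.0, 13.5, 13.0, 12.5))
  # Plateau offsets (phenomenological; only soy polar extract deviates --
  # all disc sizes are more ordered than the LUV across the assayed range).
  gel_offset <- rbind(
    DMPC = 0 * tm_offset["DMPC", ], DPPC = 0 * tm_offset["DPPC", ],
    DSPC = 0 * tm_offset["DSPC", ], POPC = 0 * tm_offset["POPC", ],
    SoyPolar = c(0, 0.22, 0.20, 0.16, 0.12))
  fluid_offset <- rbind(
    DMPC = 0 * tm_offset["DMPC", ], DPPC = 0 * tm_offset["DPPC", ],
    DSPC = 0 * tm_offset["DSPC", ], POPC = 0 * tm_offset["POPC", ],
    SoyPolar = c(0, 0.30, 0.30, 0.38, 0.25))

  rows <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
    l <- base$lipid[i]
    data.frame(
      lipid = l, scaffold = scaffolds,
      gp_gel = base$gp_gel[i] + gel_offset[l, ],
      gp_fluid = base$gp_fluid[i] + fluid_offset[l, ],
      t_m = base$t_m[i] + tm_offset[l, ],
      width_k = width[l, ],
      slope_gel = 0, slope_fluid = 0, noise_sd = 0.01,
      stringsAsFactors = FALSE, row.names = NULL)
  }))

  if (!is.null(overrides)) rows <- apply_condition_overrides(rows, overrides)
  rows
}

apply_condition_overrides <- function(tab, overrides) {
  overrides <- as.data.frame(overrides, stringsAsFactors = FALSE)
  if (!all(c("lipid", "scaffold") %in% names(overrides)))
    stop_typed("laurdanGP_config_error",
               "condition overrides need 'lipid' and 'scaffold' columns")
  bad <- setdiff(names(overrides), names(tab))
  if (length(bad))
    stop_typed("laurdanGP_config_error",
               paste("unknown condition column(s):", paste(bad, collapse = ", ")))
  for (i in seq_len(nrow(overrides))) {
    hit <- tab$lipid == overrides$lipid[i] & tab$scaffold == overrides$scaffold[i]
    vals <- overrides[i, setdiff(names(overrides), c("lipid", "scaffold")),
                      drop = FALSE]
    if (any(hit)) {
      for (cn in names(vals)) tab[hit, cn] <- vals[[cn]]
    } else {
      new <- tab[1, ]
      new$lipid <- overrides$lipid[i]
      new$scaffold <- overrides$scaffold[i]
      for (cn in names(vals)) new[[cn]] <- vals[[cn]]
      tab <- rbind(tab, new)
    }
  }
  row.names(tab) <- NULL
  tab
}

#' Look up the melt model for one condition
#'
#' @param lipid Lipid name, e.g. `"DMPC"`.
#' @param scaffold Scaffold name, one of `"LUV"`, `"spMSP1D1"`, `"spNW15"`,
#'   `"spNW25"`, `"spNW50"`.
#' @param conditions Condition table, by default [lipid_conditions()].
#' @return A [melt_model()].
#' @examples
#' condition_model("DPPC", "spMSP1D1")
#' @export
condition_model <- function(lipid, scaffold = "LUV",
                            conditions = lipid_conditions()) {
  hit <- conditions$lipid == lipid & conditions$scaffold == scaffold
  if (sum(hit) == 0L)
    stop_typed("laurdanGP_config_error",
               sprintf("no condition for lipid '%s', scaffold '%s'",
                       lipid, scaffold))
  if (sum(hit) > 1L)
    stop_typed("laurdanGP_config_error",
               sprintf("condition (%s, %s) is ambiguous: %d rows",
                       lipid, scaffold, sum(hit)))
  r <- conditions[hit, ]
  melt_model(gp_gel = r$gp_gel, gp_fluid = r$gp_fluid, t_m = r$t_m,
             width_k = r$width_k, slope_gel = r$slope_gel,
             slope_fluid = r$slope_fluid, noise_sd = r$noise_sd)
}

#' Nominal nanodisc diameters
#'
#' @return Named numeric vector of nominal bilayer diameters (nm) for the
#'   circularized scaffolds.
#' @export
scaffold_diameters <- function() {
  c(spMSP1D1 = 11, spNW15 = 15, spNW25 = 25, spNW50 = 50)
}

#' Default acquisition temperature grid for a lipid
#'
#' 1 degree C steps bracketing the transition for the saturated lipids;
#' 2 degree C steps over the instrument range for POPC and soy polar
#' extract, whose transitions are not sharp (or not reachable) in range.
#'
#' @param lipid Lipid name.
#' @return Numeric vector of temperatures, degrees C, strictly increasing.
#' @export
default_temperature_grid <- function(lipid) {
  switch(lipid,
    DMPC = seq(10, 40, by = 1),
    DPPC = seq(26, 56, by = 1),
    DSPC = seq(39, 69, by = 1),
    POPC = seq(4, 40, by = 2),
    SoyPolar = seq(4, 40, by = 2),
    stop_typed("laurdanGP_config_error",
               sprintf("no default temperature grid for lipid '%s'", lipid)))
}
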