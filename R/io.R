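# File formats: the package's spectra CSV dialect and TSV outputs.
# Every file written starts with '#'-prefixed provenance lines (tool
# version, resolved-config hash, seed); readers skip them.

provenance_header <- function(seed = NULL, config = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("laurdanGP")),
                  error = function(e) "dev")
  cfg <- jsonlite::toJSON(config %||% list(), auto_unbox = TRUE)
  c(sprintf("# laurdanGP %s", ver),
    sprintf("# seed: %s", if (is.null(seed)) "none" else as.character(seed)),
    sprintf("# config-hash: %s", hash_string(as.character(cfg))))
}

spectra_columns <- c("sample_id", "replicate", "temperature_C",
                     "scan_index", "wavelength_nm", "intensity")

#' Write a spectra series to the package CSV dialect
#'
#' One row per (scan, wavelength), columns `sample_id`, `replicate`,
#' `temperature_C`, `scan_index`, `wavelength_nm`, `intensity`, preceded by
#' `#` provenance lines. A JSON sidecar (`<path>.json`) records the
#' generating melt model and seed when the series came from
#' [synth_series()], enabling parameter-recovery round trips.
#'
#' @param series A `spectra_series`.
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar (default `TRUE` when the series
#'   carries a generating model).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(series, path, sidecar = !is.null(series$model)) {
  stopifnot(inherits(series, "spectra_series"))
  rows <- list()
  k <- 0L
  for (r in seq_along(series$spectra)) {
    for (ti in seq_along(series$spectra[[r]])) {
      for (sc in series$spectra[[r]][[ti]]) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          sample_id = sc$sample_id, replicate = r,
          temperature_C = sc$temperature,
          scan_index = as.character(sc$scan_index),
          wavelength_nm = sc$wavelength, intensity = sc$intensity,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  writeLines(provenance_header(seed = series$seed), path)
  suppressWarnings(utils::write.table(df, path, sep = ",", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  if (sidecar && !is.null(series$model)) {
    jsonlite::write_json(
      list(model = unclass(series$model), seed = series$seed,
           temperatures = series$temperatures,
           replicates = series$replicates,
           scans_per_spectrum = series$scans_per_spectrum,
           condition = series$condition, scale = series$scale),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a spectra CSV file into a validated series
#'
#' Parses the package's spectra dialect (see [write_spectra()]) and groups
#' rows into [emission_spectrum()] objects indexed by replicate,
#' temperature and scan. Validation failures (missing columns, negative or
#' non-numeric intensities, duplicated or non-increasing wavelengths
#' within a scan) raise typed parse errors naming the offending data row.
#' An empty file with a valid header yields an empty series with a
#' warning.
#'
#' @param path CSV path.
#' @return A `spectra_series` (with `model = NULL`).
#' @export
read_spectra <- function(path) {
  if (!file.exists(path))
    stop_typed("laurdanGP_parse_error", paste("no such file:", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(spectra_columns, names(df))
  if (length(miss))
    stop_typed("laurdanGP_parse_error",
               paste("spectra file missing column(s):",
                     paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) {
    warning("empty spectra file: ", path)
    return(structure(list(spectra = list(), temperatures = numeric(0),
                          replicates = 0L, scans_per_spectrum = 0L,
                          model = NULL, seed = NULL, condition = NULL),
                     class = "spectra_series"))
  }
  if (!is.numeric(df$intensity) || any(!is.finite(df$intensity)))
    stop_typed("laurdanGP_parse_error",
               sprintf("non-numeric intensity at data row %d",
                       which(!is.finite(suppressWarnings(
                         as.numeric(df$intensity))))[1L]))
  if (any(df$intensity < 0))
    stop_typed("laurdanGP_parse_error",
               sprintf("negative intensity at data row %d",
                       which(df$intensity < 0)[1L]))

  df$.row <- seq_len(nrow(df))
  key <- interaction(df$replicate, df$temperature_C, df$scan_index,
                     drop = TRUE, lex.order = TRUE)
  groups <- split(df, key)
  for (g in groups) {
    dw <- diff(g$wavelength_nm)
    if (any(dw == 0))
      stop_typed("laurdanGP_parse_error",
                 sprintf("duplicated wavelength at data row %d",
                         g$.row[which(dw == 0)[1L] + 1L]))
    if (any(dw < 0))
      stop_typed("laurdanGP_parse_error",
                 sprintf("wavelengths not increasing at data row %d",
                         g$.row[which(dw < 0)[1L] + 1L]))
  }

  reps <- sort(unique(df$replicate))
  temps <- sort(unique(df$temperature_C))
  spectra <- lapply(reps, function(r) {
    lapply(temps, function(tc) {
      sub <- df[df$replicate == r & df$temperature_C == tc, ]
      lapply(split(sub, sub$scan_index), function(g) {
        emission_spectrum(g$wavelength_nm, g$intensity, tc,
                          sample_id = g$sample_id[1L],
                          scan_index = g$scan_index[1L])
      })
    })
  })
  n_scans <- length(spectra[[1L]][[1L]])
  structure(list(spectra = spectra, temperatures = temps,
                 replicates = length(reps), scans_per_spectrum = n_scans,
                 model = NULL, seed = NULL, condition = NULL),
            class = "spectra_series")
}

#' Write / read a GP curve as TSV
#'
#' Columns `temperature`, `gp`, `gp_sd` (NA when absent), `condition`,
#' preceded by `#` provenance lines.
#'
#' @param curve A [gp_curve()].
#' @param path File path.
#' @param seed,config Optional provenance fields recorded in the header.
#' @return `write_gp_curve()` returns `path` invisibly; `read_gp_curve()`
#'   the [gp_curve()].
#' @export
write_gp_curve <- function(curve, path, seed = NULL, config = NULL) {
  curve <- as_gp_curve(curve)
  df <- data.frame(temperature = curve$temperature, gp = curve$gp,
                   gp_sd = if (is.null(curve$gp_sd)) NA_real_ else curve$gp_sd,
                   condition = attr(curve, "condition") %||% NA_character_)
  writeLines(provenance_header(seed = seed, config = config), path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_gp_curve
#' @export
read_gp_curve <- function(path) {
  if (!file.exists(path))
    stop_typed("laurdanGP_parse_error", paste("no such file:", path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("temperature", "gp") %in% names(df)))
    stop_typed("laurdanGP_parse_error",
               "curve file needs 'temperature' and 'gp' columns")
  sdcol <- if ("gp_sd" %in% names(df) && !all(is.na(df$gp_sd))) df$gp_sd
  cond <- if ("condition" %in% names(df) && !all(is.na(df$condition)))
    df$condition[1L]
  gp_curve(df$temperature, df$gp, gp_sd = sdcol, condition = cond)
}

#' Write a transitions report as TSV
#'
#' One row per analysed condition: `condition`, `t_m`, `fwhm`, `area`,
#' `peak_height`, `warnings` (semicolon-joined).
#'
#' @param results A single `transition_result` or a list of them.
#' @param path File path.
#' @param seed,config Optional provenance fields.
#' @return `path`, invisibly.
#' @export
write_transitions <- function(results, path, seed = NULL, config = NULL) {
  if (inherits(results, "transition_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(tr) {
    data.frame(condition = tr$condition %||% NA_character_,
               t_m = tr$t_m, fwhm = tr$fwhm, area = tr$area,
               peak_height = tr$peak_height,
               warnings = paste(tr$warnings, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  writeLines(provenance_header(seed = seed, config = config), path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  invisible(path)
}
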