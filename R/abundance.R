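#' Grouped relative-abundance normalization of lipid-species intensities
#'
#' Normalizes a lipid-species intensity table within each
#' `(sample, ion_mode)` group by that group's maximum intensity, the
#' standard presentation for direct-infusion lipidomics where
#' positive-mode species (PC) and negative-mode species (PA, PE, PI, PG,
#' and lysophospholipids) are not directly comparable. The reference
#' species of each group (the most intense, e.g. PC 36:4 in positive mode
#' or PI 34:2 in negative mode) gets relative intensity exactly 1; the
#' reference is computed as the group argmax rather than hard-coded, so
#' the rule generalizes to other mixtures. Within-group intensity ordering
#' is preserved; cross-group ratios are not meaningful after
#' normalization.
#'
#' @param table `data.frame` with columns `species` (e.g. `"PC 36:4"`),
#'   `class` (e.g. `"PC"`), `ion_mode` (`"positive"` or `"negative"`),
#'   `intensity` (raw, non-negative) and `sample`.
#' @param references Optional strict-mode check: named character vector
#'   mapping an ion mode to the species expected to be the group maximum,
#'   e.g. `c(positive = "PC 36:4", negative = "PI 34:2")`; a mismatch
#'   raises a normalization error.
#' @return The table with `intensity` replaced by the group-relative
#'   intensity (the operation is idempotent).
#' @examples
#' tab <- data.frame(
#'   species = c("PC 36:4", "PC 34:1", "PI 34:2", "PG 36:2"),
#'   class = c("PC", "PC", "PI", "PG"),
#'   ion_mode = c("positive", "positive", "negative", "negative"),
#'   intensity = c(100, 40, 80, 20), sample = "mix")
#' normalize_by_group_max(tab)
#' @export
normalize_by_group_max <- function(table, references = NULL) {
  table <- validate_species_table(table)
  key <- interaction(table$sample, table$ion_mode, drop = TRUE)
  for (g in levels(key)) {
    idx <- which(key == g)
    mx <- max(table$intensity[idx])
    if (mx <= 0)
      stop_typed("laurdanGP_normalization_error",
                 sprintf("group '%s' has no positive intensity", g))
    if (!is.null(references)) {
      mode <- table$ion_mode[idx[1L]]
      if (!is.na(expected <- references[mode])) {
        top <- table$species[idx[which.max(table$intensity[idx])]]
        if (top != expected)
          stop_typed("laurdanGP_normalization_error",
                     sprintf("group '%s': expected reference '%s' but '%s' is most intense",
                             g, expected, top))
      }
    }
    table$intensity[idx] <- table$intensity[idx] / mx
  }
  table
}

validate_species_table <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  need <- c("species", "class", "ion_mode", "intensity", "sample")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop_typed("laurdanGP_parse_error",
               paste("species table missing column(s):",
                     paste(miss, collapse = ", ")))
  if (!is.numeric(table$intensity) || any(!is.finite(table$intensity)) ||
      any(table$intensity < 0))
    stop_typed("laurdanGP_input_error",
               "intensities must be finite and non-negative")
  if (any(is.na(table$ion_mode) | table$ion_mode == ""))
    stop_typed("laurdanGP_input_error", "every row needs an ion_mode group")
  table
}

#' Compare relative abundances between two normalized tables
#'
#' Computes, per species, the difference in group-relative intensity
#' between two tables (e.g. nanodisc-extracted lipids versus the starting
#' mixture); both tables are normalized with [normalize_by_group_max()]
#' first. Species absent from one table get relative intensity 0 there —
#' which is how, for instance, lysophospholipid depletion in assembled
#' nanodiscs shows up.
#'
#' @param table_a,table_b Species intensity tables (raw or normalized).
#' @return A `data.frame` with `species`, `class`, `ion_mode`,
#'   `relative_a`, `relative_b`, `difference` (`a - b`), sorted by
#'   decreasing absolute difference.
#' @export
abundance_difference <- function(table_a, table_b) {
  a <- normalize_by_group_max(table_a)
  b <- normalize_by_group_max(table_b)
  key <- function(t) paste(t$species, t$ion_mode, sep = "\r")
  all_keys <- union(key(a), key(b))
  pick <- function(t, k, col) {
    i <- match(k, key(t))
    ifelse(is.na(i), NA, t[[col]][i])
  }
  species <- ifelse(is.na(pick(a, all_keys, "species")),
                    pick(b, all_keys, "species"), pick(a, all_keys, "species"))
  cls <- ifelse(is.na(pick(a, all_keys, "class")),
                pick(b, all_keys, "class"), pick(a, all_keys, "class"))
  mode <- ifelse(is.na(pick(a, all_keys, "ion_mode")),
                 pick(b, all_keys, "ion_mode"), pick(a, all_keys, "ion_mode"))
  ra <- pick(a, all_keys, "intensity"); ra[is.na(ra)] <- 0
  rb <- pick(b, all_keys, "intensity"); rb[is.na(rb)] <- 0
  out <- data.frame(species = species, class = cls, ion_mode = mode,
                    relative_a = ra, relative_b = rb, difference = ra - rb,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$difference)), , drop = FALSE]
}

#' Read / write a lipid-species intensity table (TSV)
#'
#' Tab-separated with header `species`, `class`, `ion_mode`, `intensity`,
#' `sample`; lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return `read_species_table()` returns the validated `data.frame`.
#' @export
read_species_table <- function(path) {
  if (!file.exists(path))
    stop_typed("laurdanGP_parse_error", paste("no such file:", path))
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  validate_species_table(tab)
}

#' @rdname read_species_table
#' @param table Table to write.
#' @export
write_species_table <- function(table, path) {
  writeLines(provenance_header(), path)
  suppressWarnings(utils::write.table(
    table, path, sep = "\t", row.names = FALSE, quote = FALSE,
    append = TRUE))
  invisible(path)
}
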