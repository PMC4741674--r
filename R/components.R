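#' Canonicalize an array-component name
#'
#' Array component names appear with inconsistent whitespace around hyphens
#' (e.g. `"BG-B2-Sp - 05"` vs `"BG-B2-Sp-05"`). Matching between typing
#' methods and profile matrices is exact and case-sensitive after removing
#' all whitespace, so spacing variants of the same component collapse to one
#' key while genuinely different names never silently co-join.
#'
#' @param name character vector of component names.
#' @return character vector with all whitespace removed.
#' @export
canonical_component_name <- function(name) {
  gsub("[[:space:]]+", "", name)
}

#' Parse a glycan array component name into structured covariates
#'
#' Component names encode the blood-group determinant (A, B, H), the carrier
#' chain type (1-6), the conjugation linker (Oct or Sp), and the average
#' glycan density (glycans per carrier protein molecule; the number at the
#' end of the name). Densities below 8 are classed as low, 8 and above as
#' high. Parsing is total: names that do not follow a recognized pattern
#' yield `determinant = "other"` with the remaining fields `NA`.
#'
#' Recognized determinant prefixes: `BG-A*` / `BG-B*` / `BG-H*` (including
#' trisaccharide and pentasaccharide variants such as `BG-A_tri_-19`),
#' `Globo A` / `Globo B`, `2'F-A` / `2'F-B` ("2'F" in any of its unicode
#' spellings), and `A-LeB` (an A determinant on a Lewis-B core).
#'
#' @param name a single component name (non-empty string).
#' @return a list with elements `name` (canonical form), `determinant`
#'   (`"A"`, `"B"`, `"H"` or `"other"`), `chain_type` (integer 1-6 or `NA`),
#'   `linker` (`"Oct"`, `"Sp"` or `"other"`), `density` (number or `NA`) and
#'   `density_class` (`"low"`, `"high"` or `NA`).
#' @examples
#' parse_component_name("BG-A3-Oct-14")
#' parse_component_name("BG-B2-Sp - 05")
#' parse_component_name("Forssman-di")
#' @export
parse_component_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  key <- canonical_component_name(name)

  determinant <- "other"
  chain_type <- NA_integer_

  m <- regmatches(key, regexec("^BG-([ABH])([1-6])?", key))[[1]]
  if (length(m)) {
    determinant <- m[2]
    if (nzchar(m[3])) chain_type <- as.integer(m[3])
  } else if (grepl("^Globo[AB]", key)) {
    determinant <- substring(key, 6, 6)
  } else if (grepl("^2.?F-[AB]", key)) {
    # "2'F" (2'-fluoro analogue); apostrophe varies across sources
    det_m <- regmatches(key, regexec("^2.?F-([AB])", key))[[1]]
    determinant <- det_m[2]
    type_m <- regmatches(key, regexec("type([1-6])", key))[[1]]
    if (length(type_m)) chain_type <- as.integer(type_m[2])
  } else if (grepl("^A-LeB", key)) {
    determinant <- "A"
  }

  linker <- if (grepl("-Oct", key)) "Oct" else if (grepl("-Sp", key)) "Sp" else "other"
  if (determinant == "other") linker <- NA_character_

  density <- NA_real_
  if (determinant != "other") {
    d <- regmatches(key, regexec("-([0-9]+)$", key))[[1]]
    if (length(d)) density <- as.numeric(d[2])
  }
  density_class <- if (is.na(density)) NA_character_ else if (density < 8) "low" else "high"

  list(
    name = key, determinant = determinant, chain_type = chain_type,
    linker = linker, density = density, density_class = density_class
  )
}

#' Parse many component names into a component table
#'
#' @param names character vector of component names.
#' @return a data.frame with one row per name and columns `name`,
#'   `determinant`, `chain_type`, `linker`, `density`, `density_class`.
#' @export
parse_component_names <- function(names) {
  rows <- lapply(names, parse_component_name)
  data.frame(
    name = vapply(rows, `[[`, "", "name"),
    determinant = vapply(rows, `[[`, "", "determinant"),
    chain_type = vapply(rows, `[[`, NA_integer_, "chain_type"),
    linker = vapply(rows, `[[`, NA_character_, "linker"),
    density = vapply(rows, `[[`, NA_real_, "density"),
    density_class = vapply(rows, `[[`, NA_character_, "density_class"),
    stringsAsFactors = FALSE
  )
}

#' Default array component panel
#'
#' A compact panel covering the ten components of the two-stage flow-chart
#' method (four A-determinant and four B-determinant IgG glycans, plus the
#' single IgM component per determinant), the A and B trisaccharides, an H
#' determinant and the Forssman disaccharide, spanning high and low glycan
#' densities and both Oct and Sp linkers.
#'
#' @return data.frame as from [parse_component_names()].
#' @export
default_component_panel <- function() {
  parse_component_names(c(
    "BG-A2-Sp-17", "BG-A2-Oct-16", "BG-A3-Oct-14", "Globo A-09",
    "BG-A1-Oct-12",
    "BG-B2-Sp-05", "BG-B2-Sp-20", "BG-B2-Oct-17", "BG-B3-Oct-17",
    "Globo B-12", "BG-B1-Sp-16",
    "BG-A_tri_-19", "BG-B_tri_-13",
    "BG-H1-Oct-05", "Forssman-di"
  ))
}
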