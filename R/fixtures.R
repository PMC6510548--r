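# Packaged fixture tables and their accessors.
#
# All tables ship as plain-text CSV under inst/extdata and are smooth
# synthetic reconstructions of the standard literature curves (see
# scripts/make_fixtures.R for provenance notes):
#   water_absorption.csv  - pure sea-water absorption a_w(lambda) [m-1]
#   bricaud_ap.csv        - chlorophyll-specific absorption A(lambda),
#                           E(lambda) for a_p = A * Chla^E
#   solar_irradiance.csv  - extraterrestrial solar irradiance [W m-2 nm-1]
#   gas_transmittance.csv - vertical-column band transmittances for O2,
#                           water vapor and ozone

.fixture_cache <- new.env(parent = emptyenv())

fixture_table <- function(name) {
  if (!is.null(.fixture_cache[[name]])) return(.fixture_cache[[name]])
  path <- system.file("extdata", paste0(name, ".csv"), package = "fluorrt")
  if (!nzchar(path)) {
    # fall back for un-installed source trees (tests via pkgload)
    path <- file.path("inst", "extdata", paste0(name, ".csv"))
  }
  if (!file.exists(path)) stop("fixture table not found: ", name)
  tab <- utils::read.csv(path)
  .fixture_cache[[name]] <- tab
  tab
}

#' List the packaged fixture tables
#'
#' @return data.frame with name, rows, wavelength range and column names of
#'   every packaged table.
#' @export
list_fixtures <- function() {
  names <- c("water_absorption", "bricaud_ap", "solar_irradiance",
             "gas_transmittance")
  do.call(rbind, lapply(names, function(n) {
    tab <- fixture_table(n)
    data.frame(name = n, rows = nrow(tab),
               wavelength_min = min(tab$wavelength),
               wavelength_max = max(tab$wavelength),
               columns = paste(names(tab), collapse = ","))
  }))
}

#' Extraterrestrial solar spectral irradiance
#'
#' Linear interpolation of the packaged smoothed solar spectrum.
#'
#' @param wavelength wavelengths [nm], within 350-800
#' @return irradiance [W m-2 nm-1]
#' @export
solar_irradiance <- function(wavelength) {
  tab <- fixture_table("solar_irradiance")
  interp_strict(tab$wavelength, tab$irradiance, wavelength,
                "solar irradiance table")
}
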