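#' Species cards and Cmol conversions
#'
#' A species card records the molar mass and carbon content of a measured
#' species so that mass-based rates (g per g biomass per hour) can be expressed
#' on a carbon-mole (Cmol) basis, the common currency for yields and the
#' carbon balance. Biomass itself is registered with its Cmol mass (g dry cell
#' weight per mole of biomass carbon) as the molar mass and one carbon atom,
#' so the same conversion applies.
#'
#' @param name species identifier (lower case by convention)
#' @param molar_mass molar mass in g/mol, must be positive
#' @param carbon_atoms integer count of carbon atoms per molecule, >= 0
#' @return a `species_card` object
#' @export
species_card <- function(name, molar_mass, carbon_atoms) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || molar_mass <= 0)
    stop_chemoflux("molar_mass must be a single positive number", "chemoflux_species_error")
  if (!is.numeric(carbon_atoms) || length(carbon_atoms) != 1L || carbon_atoms < 0)
    stop_chemoflux("carbon_atoms must be a single non-negative number", "chemoflux_species_error")
  structure(list(name = name, molar_mass = molar_mass, carbon_atoms = carbon_atoms),
            class = "species_card")
}

#' Default species registry
#'
#' Cards for the species tracked in the two-carbon-source chemostat medium
#' (glucose and monosodium glutamate), the secretion products quantified in the
#' broth (trehalose and the amino acids valine, glycine and alanine), CO2, and
#' biomass. Biomass uses a configurable Cmol mass; the default 24.6 g/Cmol is
#' the generic CH1.8O0.5N0.2 composition.
#'
#' @param biomass_cmol_mass g dry cell weight per Cmol of biomass (default 24.6)
#' @return named list of [species_card()] objects
#' @export
default_species_registry <- function(biomass_cmol_mass = 24.6) {
  cards <- list(
    species_card("glucose",   180.16, 6),
    species_card("msg",       169.11, 5),  # monosodium glutamate, C5H8NNaO4
    species_card("glutamate", 147.13, 5),
    species_card("trehalose", 342.30, 12),
    species_card("valine",    117.15, 5),
    species_card("glycine",    75.07, 2),
    species_card("alanine",    89.09, 3),
    species_card("co2",        44.01, 1),
    species_card("biomass", biomass_cmol_mass, 1)
  )
  stats::setNames(cards, vapply(cards, `[[`, "", "name"))
}

lookup_card <- function(registry, species) {
  card <- registry[[species]]
  if (is.null(card))
    stop_chemoflux(sprintf("species '%s' is not in the registry", species),
                   "chemoflux_registry_error")
  card
}

#' Convert a mass-based rate to a Cmol basis
#'
#' Multiplies by carbon atoms per molecule and divides by the molar mass, so
#' e.g. 1 g glucose corresponds to 6/180.16 = 0.0333 Cmol.
#'
#' @param mass_rate rate in g per (arbitrary basis) per hour
#' @param card a [species_card()], or a registry plus `species` name
#' @param registry optional named list of cards used when `card` is a name
#' @return rate in Cmol per (same basis) per hour
#' @export
to_cmol <- function(mass_rate, card, registry = NULL) {
  if (is.character(card)) card <- lookup_card(registry, card)
  stopifnot(inherits(card, "species_card"))
  mass_rate / card$molar_mass * card$carbon_atoms
}

#' Convert a mass-based specific rate to mmol/gDW/h
#'
#' Adapter between the bioprocess rate panel (g/g/h) and the flux-analysis
#' convention (mmol per g dry weight per hour) used for exchange constraints.
#'
#' @inheritParams to_cmol
#' @return rate in mmol/gDW/h
#' @export
to_mmol <- function(mass_rate, card, registry = NULL) {
  if (is.character(card)) card <- lookup_card(registry, card)
  stopifnot(inherits(card, "species_card"))
  mass_rate / card$molar_mass * 1000
}
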