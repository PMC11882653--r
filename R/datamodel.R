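# Domain types for the minicuvette drying-run protocol.
#
# A "drying run" is one thallus measured as a series of light-response curves
# while it dries from full hydration to dormancy; thallus mass is recorded
# before and after every curve so each curve can be assigned a water content.
# Units are fixed package-wide: masses mg, areas cm2, PPFD umol photons m-2
# s-1, assimilation nmol CO2 g-1 DM s-1 (net photosynthesis positive,
# respiration negative). No unit autodetection is attempted: silent unit
# errors are the main hazard with this kind of data.

#' Construct a thallus sample record
#'
#' @param sample_id Unique identifier for the thallus.
#' @param species_code Species label (any string; the seven study codes in
#'   [species_codes()] are used by the bundled calibration).
#' @param site Collection-site label.
#' @param dry_mass_mg Oven-dry mass, mg (> 0).
#' @param area_cm2 Planform thallus area, cm2 (> 0).
#' @param full_wet_mass_mg Mass of the fully hydrated, gently shaken thallus,
#'   mg (>= dry mass); internal plus external water.
#' @return An object of class `thallus_sample`.
#' @export
thallus_sample <- function(sample_id, species_code, site,
                           dry_mass_mg, area_cm2, full_wet_mass_mg) {
  x <- structure(list(sample_id = as.character(sample_id),
                      species_code = as.character(species_code),
                      site = as.character(site),
                      dry_mass_mg = as.numeric(dry_mass_mg),
                      area_cm2 = as.numeric(area_cm2),
                      full_wet_mass_mg = as.numeric(full_wet_mass_mg)),
                 class = "thallus_sample")
  validate_thallus_sample(x)
}

validate_thallus_sample <- function(x) {
  if (!nzchar(x$sample_id)) validation_error("sample_id must be non-empty")
  for (f in c("dry_mass_mg", "area_cm2", "full_wet_mass_mg"))
    if (!is_scalar_number(x[[f]]))
      validation_error(sprintf("sample %s: %s must be a finite number", x$sample_id, f))
  if (x$dry_mass_mg <= 0)
    validation_error(sprintf("sample %s: dry_mass_mg must be > 0", x$sample_id))
  if (x$area_cm2 <= 0)
    validation_error(sprintf("sample %s: area_cm2 must be > 0", x$sample_id))
  if (x$full_wet_mass_mg < x$dry_mass_mg)
    validation_error(sprintf(
      "sample %s: full_wet_mass_mg (%g) < dry_mass_mg (%g)",
      x$sample_id, x$full_wet_mass_mg, x$dry_mass_mg))
  x
}

#' Construct one light-response curve
#'
#' @param curve_index Ordinal position within the drying run (1 = wettest).
#' @param ppfd Strictly increasing irradiance steps, first element 0.
#' @param assim CO2 assimilation per step, nmol g-1 DM s-1 (NP positive,
#'   dark respiration negative).
#' @param mass_before_mg,mass_after_mg Thallus mass bracketing the curve, mg.
#' @return An object of class `light_curve`.
#' @export
light_curve <- function(curve_index, ppfd, assim, mass_before_mg, mass_after_mg) {
  x <- structure(list(curve_index = as.integer(curve_index),
                      ppfd = as.numeric(ppfd),
                      assim = as.numeric(assim),
                      mass_before_mg = as.numeric(mass_before_mg),
                      mass_after_mg = as.numeric(mass_after_mg)),
                 class = "light_curve")
  validate_light_curve(x)
}

validate_light_curve <- function(x, id = "") {
  tag <- if (nzchar(id)) sprintf(" (sample %s, curve %d)", id, x$curve_index)
         else sprintf(" (curve %d)", x$curve_index)
  if (length(x$ppfd) != length(x$assim))
    validation_error(paste0("ppfd and assim lengths differ", tag))
  if (length(x$ppfd) < 2L)
    validation_error(paste0("a light curve needs at least 2 PPFD steps", tag))
  if (x$ppfd[1L] != 0)
    validation_error(paste0("first PPFD step must be 0 (dark respiration)", tag))
  if (any(diff(x$ppfd) <= 0))
    validation_error(paste0("PPFD steps must be strictly increasing", tag))
  if (anyNA(x$assim) || any(!is.finite(x$assim)))
    validation_error(paste0("assimilation values must be finite", tag))
  if (!is_scalar_number(x$mass_before_mg) || !is_scalar_number(x$mass_after_mg))
    validation_error(paste0("curve masses must be finite numbers", tag))
  if (x$mass_before_mg < x$mass_after_mg)
    validation_error(paste0("mass_before_mg < mass_after_mg: sample must dry, not gain water", tag))
  x
}

#' Construct a drying run
#'
#' @param sample A [thallus_sample()].
#' @param curves List of [light_curve()]s ordered wettest to driest.
#' @param temperature_c Cuvette temperature, degrees C.
#' @param rh_percent Relative humidity, %.
#' @return An object of class `drying_run`.
#' @export
drying_run <- function(sample, curves, temperature_c = 18, rh_percent = 90) {
  x <- structure(list(sample = sample, curves = curves,
                      temperature_c = as.numeric(temperature_c),
                      rh_percent = as.numeric(rh_percent)),
                 class = "drying_run")
  validate_drying_run(x)
}

validate_drying_run <- function(x) {
  validate_thallus_sample(x$sample)
  if (length(x$curves) < 3L)
    validation_error(sprintf("sample %s: a drying run needs >= 3 light curves",
                             x$sample$sample_id))
  for (cv in x$curves) validate_light_curve(cv, x$sample$sample_id)
  mid <- vapply(x$curves, function(cv) (cv$mass_before_mg + cv$mass_after_mg) / 2,
                numeric(1))
  if (any(diff(mid) > 1e-9))
    validation_error(sprintf(
      "sample %s: curve water contents must be non-increasing along the run",
      x$sample$sample_id))
  if (any(vapply(x$curves, function(cv) cv$mass_after_mg, numeric(1)) <
          x$sample$dry_mass_mg - 1e-9))
    validation_error(sprintf("sample %s: curve mass below dry mass", x$sample$sample_id))
  x
}

#' @export
print.thallus_sample <- function(x, ...) {
  cat(sprintf("<thallus_sample> %s (%s, %s): DM %.1f mg, area %.2f cm2, wet %.1f mg\n",
              x$sample_id, x$species_code, x$site, x$dry_mass_mg, x$area_cm2,
              x$full_wet_mass_mg))
  invisible(x)
}

#' @export
print.drying_run <- function(x, ...) {
  cat(sprintf("<drying_run> sample %s (%s): %d curves, %g C, %g%% RH\n",
              x$sample$sample_id, x$sample$species_code, length(x$curves),
              x$temperature_c, x$rh_percent))
  invisible(x)
}

#' The seven study species, ordered by increasing rainforest association
#'
#' Rank 1 is the most weakly associated species, rank 7 the most strongly
#' associated (the published left-to-right ordering).
#'
#' @return Character vector of 7 species codes, names give the rank.
#' @export
species_codes <- function() {
  c("L_pulmonaria", "R_calicaris", "S_limbata", "S_sylvatica",
    "R_virens", "H_laevigata", "P_atlantica")
}

#' Habitat-association rank table
#'
#' @param species_code Character vector of species codes.
#' @param rank Integer ranks; must be a permutation of 1..n.
#' @return data.frame with columns `species_code`, `rank`.
#' @export
habitat_ranks <- function(species_code = species_codes(),
                          rank = seq_along(species_code)) {
  if (length(species_code) != length(rank))
    validation_error("species_code and rank lengths differ")
  rank <- as.integer(rank)
  if (!setequal(rank, seq_along(rank)))
    validation_error("ranks must be a permutation of 1..n")
  if (anyDuplicated(species_code))
    validation_error("duplicate species_code in rank table")
  data.frame(species_code = as.character(species_code), rank = rank,
             stringsAsFactors = FALSE)
}

#' Construct a pigment measurement
#'
#' Absorbances of a DMSO chlorophyll extract at 665 and 649 nm.
#'
#' @param sample_id Sample identifier.
#' @param a665,a649 Absorbances (>= 0, finite).
#' @param extract_volume_ml Extract volume, ml (> 0).
#' @param dm_mg Extracted dry mass, mg (> 0).
#' @return An object of class `pigment_measurement`.
#' @export
pigment_measurement <- function(sample_id, a665, a649, extract_volume_ml, dm_mg) {
  x <- structure(list(sample_id = as.character(sample_id),
                      a665 = as.numeric(a665), a649 = as.numeric(a649),
                      extract_volume_ml = as.numeric(extract_volume_ml),
                      dm_mg = as.numeric(dm_mg)),
                 class = "pigment_measurement")
  if (!is_scalar_number(x$a665) || !is_scalar_number(x$a649) ||
      x$a665 < 0 || x$a649 < 0)
    validation_error(sprintf("pigment %s: absorbances must be finite and >= 0", x$sample_id))
  if (!is_scalar_number(x$extract_volume_ml) || x$extract_volume_ml <= 0)
    validation_error(sprintf("pigment %s: extract_volume_ml must be > 0", x$sample_id))
  if (!is_scalar_number(x$dm_mg) || x$dm_mg <= 0)
    validation_error(sprintf("pigment %s: dm_mg must be > 0", x$sample_id))
  x
}
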