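#' @keywords internal
"_PACKAGE"

# Canonical basal resource codes: algae, living plants, bacteria, fungi,
# leaf litter, deadwood, soil organic matter.
RESOURCE_IDS <- c("A", "P", "B", "F", "L", "W", "S")

RESOURCE_LABELS <- c(
  A = "algae", P = "plants", B = "bacteria", F = "fungi",
  L = "litter", W = "deadwood", S = "soil_organic_matter"
)

HABITAT_LAYERS <- c("soil", "litter", "ground", "aboveground")

FOREST_TYPES <- c("taiga", "mixed_broadleaved", "beech", "monsoon", "rainforest")

#' Analysis configuration
#'
#' Builds the configuration object that parameterises food-web
#' reconstruction, energy-flux estimation and the downstream summaries.
#' Defaults encode the standard reconstruction constants: an optimum
#' predator-prey mass ratio of 100, a standard deviation of 1 on the log10
#' body-mass scale, trophic enrichment factors of 3.4 permil (delta 15N) and
#' 0.4 permil (delta 13C), the delta-15N anchors used by the isotope diet
#' refinements, diet-specific assimilation efficiencies for the seven basal
#' resources, the 50--99 percent efficiency bounds for animal prey, and the
#' energy density of fresh biomass (7e6 J per kg) used to express fluxes as
#' fresh-biomass consumption.
#'
#' @param ppmr_optimum optimum predator-prey fresh body-mass ratio.
#' @param sigma_log_mass standard deviation of individual body mass on the
#'   log10 scale, shared by all guilds unless a guild overrides it.
#' @param tef_d15N,tef_d13C trophic enrichment factors, permil per trophic
#'   step.
#' @param isotope_bandwidth Gaussian kernel bandwidth (permil) for the
#'   isotopic-distance link weight; defaults to one delta-15N enrichment
#'   step.
#' @param algivory_d15N_zero,algivory_d15N_full delta-15N values (permil) at
#'   which the inferred algal diet fraction reaches 0 and 1.
#' @param earthworm_d15N_litter,earthworm_d15N_soil delta-15N values
#'   (permil) anchoring the epigeic (pure litter) and endogeic (pure soil)
#'   ends of the earthworm detrital-diet split.
#' @param omnivory_parameter either the string \code{"as-given"} (use trait
#'   table preferences unchanged) or a number in [0, 1] rescaling every
#'   guild's auxiliary resource preferences relative to its main resource.
#' @param efficiency_table named numeric vector of assimilation efficiencies
#'   for the resource codes A, P, B, F, L, W, S.
#' @param animal_efficiency_bounds length-2 numeric, efficiency bounds for
#'   animal prey.
#' @param animal_N_range length-2 numeric, prey nitrogen content (mass
#'   percent) mapped linearly onto \code{animal_efficiency_bounds}.
#' @param energy_density J per kg fresh biomass.
#' @param seconds_per_year year length in seconds (365 days).
#' @param metabolic_coefficients named list, one entry per phylogenetic
#'   group, each \code{list(ln_b0, a, E)}: intercept (ln J/h), mass exponent
#'   and activation energy (eV) of the metabolic allometry.
#' @param boltzmann_k Boltzmann constant, eV per K.
#' @param rng_seed optional integer seed recorded with run manifests.
#'
#' @return an object of class \code{fw_config} (a named list).
#' @export
#' @examples
#' cfg <- fw_config()
#' cfg$ppmr_optimum
#' cfg$efficiency_table[["B"]]
fw_config <- function(ppmr_optimum = 100,
                      sigma_log_mass = 1,
                      tef_d15N = 3.4,
                      tef_d13C = 0.4,
                      isotope_bandwidth = 3.4,
                      algivory_d15N_zero = 2.0,
                      algivory_d15N_full = -1.4,
                      earthworm_d15N_litter = 1.2,
                      earthworm_d15N_soil = 5.5,
                      omnivory_parameter = "as-given",
                      efficiency_table = c(A = 0.36, P = 0.21, B = 0.96,
                                           F = 0.36, L = 0.18, W = 0.18,
                                           S = 0.13),
                      animal_efficiency_bounds = c(0.50, 0.99),
                      animal_N_range = c(5, 12),
                      energy_density = 7e6,
                      seconds_per_year = 31536000,
                      metabolic_coefficients = default_metabolic_coefficients(),
                      boltzmann_k = 8.617e-5,
                      rng_seed = NULL) {
  eff <- efficiency_table
  if (is.null(names(eff)) || !all(RESOURCE_IDS %in% names(eff))) {
    stop("efficiency_table must be named with all of: ",
         paste(RESOURCE_IDS, collapse = ", "))
  }
  eff <- eff[RESOURCE_IDS]
  if (any(!is.finite(eff)) || any(eff <= 0) || any(eff > 1)) {
    stop("resource assimilation efficiencies must lie in (0, 1]")
  }
  if (!identical(omnivory_parameter, "as-given")) {
    stopifnot(is.numeric(omnivory_parameter), length(omnivory_parameter) == 1,
              omnivory_parameter >= 0, omnivory_parameter <= 1)
  }
  scalars <- c(ppmr_optimum, sigma_log_mass, tef_d15N, tef_d13C,
               isotope_bandwidth, algivory_d15N_zero, algivory_d15N_full,
               earthworm_d15N_litter, earthworm_d15N_soil,
               animal_efficiency_bounds, animal_N_range,
               energy_density, seconds_per_year, boltzmann_k)
  if (any(!is.finite(scalars))) stop("configuration scalars must be finite")
  stopifnot(ppmr_optimum > 0, sigma_log_mass > 0, isotope_bandwidth > 0,
            animal_efficiency_bounds[1] > 0,
            animal_efficiency_bounds[2] <= 1,
            animal_efficiency_bounds[1] <= animal_efficiency_bounds[2])

  cfg <- list(
    ppmr_optimum = ppmr_optimum,
    sigma_log_mass = sigma_log_mass,
    tef_d15N = tef_d15N,
    tef_d13C = tef_d13C,
    isotope_bandwidth = isotope_bandwidth,
    algivory_d15N_zero = algivory_d15N_zero,
    algivory_d15N_full = algivory_d15N_full,
    earthworm_d15N_litter = earthworm_d15N_litter,
    earthworm_d15N_soil = earthworm_d15N_soil,
    omnivory_parameter = omnivory_parameter,
    efficiency_table = eff,
    animal_efficiency_bounds = animal_efficiency_bounds,
    animal_N_range = animal_N_range,
    energy_density = energy_density,
    seconds_per_year = seconds_per_year,
    metabolic_coefficients = metabolic_coefficients,
    boltzmann_k = boltzmann_k,
    rng_seed = rng_seed
  )
  class(cfg) <- "fw_config"
  cfg
}

#' Default metabolic-allometry coefficient table
#'
#' Per-phylogenetic-group coefficients of the temperature-corrected
#' metabolic allometry \code{X = exp(ln_b0 + a * ln(mass) - E / (k * T))}
#' (J per hour; mass in mg fresh weight, T in Kelvin). The shipped values
#' are editable placeholders in a plausible range for soil invertebrates;
#' site analyses should substitute coefficients fitted for their taxa (see
#' the \code{coefficients.yaml} template under \code{inst/extdata}).
#'
#' @return named list of \code{list(ln_b0, a, E)} per group, including a
#'   \code{"default"} entry used when a guild's group is not listed.
#' @export
default_metabolic_coefficients <- function() {
  list(
    default     = list(ln_b0 = 23.0, a = 0.70, E = 0.69),
    insect      = list(ln_b0 = 22.2, a = 0.76, E = 0.67),
    arachnid    = list(ln_b0 = 22.0, a = 0.57, E = 0.65),
    myriapod    = list(ln_b0 = 22.8, a = 0.60, E = 0.69),
    crustacean  = list(ln_b0 = 21.0, a = 0.72, E = 0.63),
    oligochaete = list(ln_b0 = 23.0, a = 0.80, E = 0.69),
    nematode    = list(ln_b0 = 23.5, a = 0.84, E = 0.73)
  )
}

#' Read a configuration from YAML
#'
#' @param path YAML file; keys mirror [fw_config()] arguments. Absent keys
#'   keep their defaults.
#' @return an \code{fw_config} object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(fw_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$efficiency_table)) {
    raw$efficiency_table <- unlist(raw$efficiency_table)
  }
  if (!is.null(raw$animal_efficiency_bounds)) {
    raw$animal_efficiency_bounds <- as.numeric(unlist(raw$animal_efficiency_bounds))
  }
  if (!is.null(raw$animal_N_range)) {
    raw$animal_N_range <- as.numeric(unlist(raw$animal_N_range))
  }
  do.call(fw_config, raw)
}

#' Write a configuration to YAML
#'
#' @param config an \code{fw_config} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fw_config"))
  out <- unclass(config)
  out$efficiency_table <- as.list(out$efficiency_table)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.fw_config <- function(x, ...) {
  cat("<fw_config>\n")
  cat("  PPMR optimum:", x$ppmr_optimum,
      " sigma(log10 mass):", x$sigma_log_mass, "\n")
  cat("  TEF d15N/d13C:", x$tef_d15N, "/", x$tef_d13C,
      "permil; isotope bandwidth:", x$isotope_bandwidth, "permil\n")
  cat("  resource efficiencies:",
      paste(names(x$efficiency_table), x$efficiency_table,
            sep = "=", collapse = " "), "\n")
  cat("  omnivory parameter:",
      if (identical(x$omnivory_parameter, "as-given")) "as-given"
      else x$omnivory_parameter, "\n")
  invisible(x)
}
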