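# Metabolic allometry, temperature correction and assimilation efficiencies.

#' Convert body length to fresh body mass
#'
#' Evaluates a taxon-specific length-mass power regression on the log10
#' scale: \code{log10(mass mg) = a_len + b_len * log10(length mm)}.
#'
#' @param length_mm body length, mm (> 0).
#' @param coeffs either a \code{list(a_len, b_len)} or a named list of such
#'   entries keyed by taxon, in which case \code{taxon} selects the entry.
#' @param taxon taxon key when \code{coeffs} is a table.
#' @return fresh body mass, mg.
#' @export
#' @examples
#' length_to_mass(2, list(a_len = 0, b_len = 3)) # 8 mg
length_to_mass <- function(length_mm, coeffs, taxon = NULL) {
  if (!is.null(taxon)) {
    if (is.null(coeffs[[taxon]])) {
      stop("no length-mass coefficients for taxon: ", taxon)
    }
    coeffs <- coeffs[[taxon]]
  }
  if (is.null(coeffs$a_len) || is.null(coeffs$b_len)) {
    stop("length-mass coefficients need fields a_len and b_len")
  }
  stopifnot(all(length_mm > 0))
  10^(coeffs$a_len + coeffs$b_len * log10(length_mm))
}

#' Individual metabolic rate with Arrhenius temperature correction
#'
#' \code{X = exp(ln_b0 + a * ln(mass) - E / (k * T_K))} in J per hour,
#' returned in mW (1 J/h = 1/3.6 mW). \code{T_K = T_C + 273.15}.
#'
#' @param mass_mg fresh body mass, mg (> 0).
#' @param temperature_C environmental temperature, deg C.
#' @param coeffs \code{list(ln_b0, a, E)}: intercept (ln J/h), mass
#'   exponent, activation energy (eV).
#' @param boltzmann_k Boltzmann constant, eV/K.
#' @return metabolic rate, mW per individual.
#' @export
individual_metabolic_rate <- function(mass_mg, temperature_C, coeffs,
                                      boltzmann_k = 8.617e-5) {
  stopifnot(all(mass_mg > 0), all(temperature_C > -273.15))
  T_K <- temperature_C + 273.15
  rate_J_h <- exp(coeffs$ln_b0 + coeffs$a * log(mass_mg) -
                    coeffs$E / (boltzmann_k * T_K))
  rate_J_h / 3.6
}

#' Community-level metabolic demand of a guild
#'
#' Scales the individual rate to the guild's standing population:
#' \code{X = (biomass g m-2 * 1000 / mass mg) * individual rate mW}.
#'
#' @param biomass_g total fresh biomass, g per square metre.
#' @param mass_mg mean individual fresh body mass, mg (> 0).
#' @param temperature_C environmental temperature, deg C.
#' @param coeffs metabolic coefficients, as in
#'   [individual_metabolic_rate()].
#' @param boltzmann_k Boltzmann constant, eV/K.
#' @return metabolic demand, mW per square metre.
#' @export
node_metabolic_demand <- function(biomass_g, mass_mg, temperature_C, coeffs,
                                  boltzmann_k = 8.617e-5) {
  if (any(mass_mg <= 0)) stop("mean body mass must be positive")
  n_ind <- biomass_g * 1000 / mass_mg
  n_ind * individual_metabolic_rate(mass_mg, temperature_C, coeffs,
                                    boltzmann_k)
}

#' Diet-specific assimilation efficiency of a prey or resource node
#'
#' Basal resources take their configured efficiencies (defaults: bacteria
#' 0.96, fungi 0.36, plants 0.21, litter 0.18, soil organic matter 0.13).
#' Animal prey efficiency increases with tissue nitrogen content, linear in
#' N percent over \code{config$animal_N_range} and clipped to
#' \code{config$animal_efficiency_bounds} (0.50--0.99 by default); prey with
#' unknown N content get the midpoint of the bounds.
#'
#' @param node_type \code{"resource"} or \code{"guild"}.
#' @param resource_id resource code (A, P, B, F, L, W, S) when a resource.
#' @param N_pct prey nitrogen content, mass percent, when an animal.
#' @param config an [fw_config()].
#' @return efficiency in (0, 1].
#' @export
#' @examples
#' assimilation_efficiency("resource", resource_id = "B") # 0.96
#' assimilation_efficiency("guild", N_pct = 12)           # 0.99
assimilation_efficiency <- function(node_type, resource_id = NULL,
                                    N_pct = NULL, config = fw_config()) {
  if (node_type == "resource") {
    if (is.null(resource_id) || !resource_id %in% RESOURCE_IDS) {
      stop("resource_id must be one of ", paste(RESOURCE_IDS, collapse = ", "))
    }
    return(unname(config$efficiency_table[[resource_id]]))
  }
  bounds <- config$animal_efficiency_bounds
  if (is.null(N_pct) || is.na(N_pct)) {
    return(mean(bounds))
  }
  nr <- config$animal_N_range
  frac <- (N_pct - nr[1]) / (nr[2] - nr[1])
  unname(bounds[1] + max(0, min(1, frac)) * (bounds[2] - bounds[1]))
}

#' Efficiency vector for every node of a food web
#'
#' @param web a \code{food_web}.
#' @param config an [fw_config()].
#' @return named numeric vector over all nodes (resources and guilds).
#' @export
node_efficiencies <- function(web, config = fw_config()) {
  stopifnot(inherits(web, "food_web"))
  vapply(seq_len(nrow(web$nodes)), function(i) {
    nd <- web$nodes[i, ]
    if (nd$type == "resource") {
      assimilation_efficiency("resource", resource_id = nd$node_id,
                              config = config)
    } else {
      assimilation_efficiency("guild", N_pct = nd$N_pct, config = config)
    }
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(web$nodes$node_id)
}
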