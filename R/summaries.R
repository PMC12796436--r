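# Headline summaries of a solved web: trophic functions, body-mass
# spectrum, unit conversions and NPP shares.

TROPHIC_FUNCTIONS <- c(
  predation = "animal",
  algivory = "A", herbivory = "P", bacterivory = "B", fungivory = "F",
  litter_consumption = "L", wood_consumption = "W", soil_consumption = "S"
)

# Body-mass bins: equal intervals of log10(32) = 1.50515 decades on the
# fresh-mass scale starting at 0.05 ug. The nominal labels (0.05-1.6 ug,
# 1.6-50 ug, 0.05-1.6 mg, 1.6-50 mg, 0.05-1.6 g) round the exact geometric
# edges 0.05 * 32^k ug.
MASS_BIN_EDGES_UG <- 0.05 * 32^(0:5)
MASS_BIN_LABELS <- c("microfauna", "large_microfauna_microarthropods",
                     "small_macrofauna", "macrofauna", "large_macrofauna")

#' Trophic-function summary of a solved web
#'
#' Each trophic function sums the energy fluxes outgoing from one source
#' class: herbivory (living plants), algivory (algae), bacterivory,
#' fungivory, litter consumption, deadwood consumption, soil consumption,
#' and predation (outgoing fluxes from all animal nodes). Functions are
#' also scaled to the total energy flux as percentages; together they
#' partition it exactly.
#'
#' @param solution a \code{flux_solution}.
#' @param web the \code{food_web} it solves.
#' @return object of class \code{trophic_function_summary}: data frame with
#'   columns \code{fn}, \code{flux_mW}, \code{percent}, plus attribute
#'   \code{total_flux}.
#' @export
trophic_functions <- function(solution, web) {
  stopifnot(inherits(solution, "flux_solution"), inherits(web, "food_web"))
  if (solution$total_flux <= 0) {
    stop("total flux is zero: trophic-function percentages are undefined")
  }
  L <- solution$L
  out_by_node <- rowSums(L)
  flux <- vapply(TROPHIC_FUNCTIONS, function(src) {
    if (src == "animal") {
      sum(out_by_node[setdiff(rownames(L), web$resources)])
    } else if (src %in% rownames(L)) {
      out_by_node[[src]]
    } else {
      0
    }
  }, numeric(1))
  df <- data.frame(fn = names(TROPHIC_FUNCTIONS), flux_mW = unname(flux),
                   percent = unname(flux) / solution$total_flux * 100,
                   stringsAsFactors = FALSE)
  structure(df, class = c("trophic_function_summary", "data.frame"),
            total_flux = solution$total_flux)
}

#' Fungivory-to-bacterivory flux ratio
#'
#' @param summary a \code{trophic_function_summary}.
#' @return the ratio of absolute fluxes, or \code{NA} (with attribute
#'   \code{undefined = TRUE}) when bacterivory is zero.
#' @export
fb_ratio <- function(summary) {
  f <- summary$flux_mW[summary$fn == "fungivory"]
  b <- summary$flux_mW[summary$fn == "bacterivory"]
  if (b <= 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  f / b
}

#' Assign fresh body masses (ug) to the five body-mass classes
#'
#' Half-open bins [lo, hi); masses outside the spectrum range are clamped
#' into the end bins with a warning.
#'
#' @param mass_ug fresh body masses, ug.
#' @return integer bin index 1..5.
#' @export
#' @examples
#' mass_bin(10)   # 2: large microfauna / microarthropods
#' mass_bin(1.6)  # 2: half-open edges
mass_bin <- function(mass_ug) {
  stopifnot(all(mass_ug > 0))
  out_of_range <- mass_ug < MASS_BIN_EDGES_UG[1] |
    mass_ug >= MASS_BIN_EDGES_UG[6]
  if (any(out_of_range)) {
    warning(sum(out_of_range), " mass(es) outside the spectrum range ",
            "clamped into the end bins", call. = FALSE)
  }
  idx <- findInterval(mass_ug, MASS_BIN_EDGES_UG)
  pmin(pmax(idx, 1L), 5L)
}

#' Body-mass spectrum of a solved web
#'
#' Sums guild biomass and intake flux within the five log-linear body-mass
#' classes (microfauna up to large macrofauna) and fits the spectrum
#' slopes.
#'
#' @param web a \code{food_web}.
#' @param solution optional \code{flux_solution}; when given, per-bin
#'   intake-flux sums and the flux slope are included.
#' @return object of class \code{body_mass_spectrum}: data frame with
#'   columns \code{bin}, \code{label}, \code{lo_ug}, \code{hi_ug},
#'   \code{mid_log10_ug}, \code{biomass}, \code{flux_mW}; attributes
#'   \code{slope_biomass} and \code{slope_flux} (per decade, bins 1-4).
#' @export
bin_spectrum <- function(web, solution = NULL) {
  stopifnot(inherits(web, "food_web"))
  guilds <- web$nodes[web$nodes$type == "guild", ]
  bins <- mass_bin(guilds$mass_mg * 1000)   # mg -> ug
  biomass <- vapply(1:5, function(b) sum(guilds$biomass[bins == b]),
                    numeric(1))
  flux <- rep(NA_real_, 5)
  if (!is.null(solution)) {
    Fv <- solution$F[guilds$node_id]
    flux <- vapply(1:5, function(b) sum(Fv[bins == b]), numeric(1))
  }
  df <- data.frame(
    bin = 1:5, label = MASS_BIN_LABELS,
    lo_ug = MASS_BIN_EDGES_UG[1:5], hi_ug = MASS_BIN_EDGES_UG[2:6],
    mid_log10_ug = (log10(MASS_BIN_EDGES_UG[1:5]) +
                      log10(MASS_BIN_EDGES_UG[2:6])) / 2,
    biomass = biomass, flux_mW = flux,
    stringsAsFactors = FALSE
  )
  spec <- structure(df, class = c("body_mass_spectrum", "data.frame"))
  attr(spec, "slope_biomass") <- tryCatch(
    spectrum_slope(spec, "biomass"), error = function(e) NA_real_)
  attr(spec, "slope_flux") <- if (is.null(solution)) NA_real_ else tryCatch(
    spectrum_slope(spec, "flux"), error = function(e) NA_real_)
  spec
}

#' Body-mass-spectrum slope
#'
#' Ordinary least squares of log10(per-bin sum) on the log10 geometric bin
#' midpoint mass, over bins 1-4 only: the largest class (large macrofauna)
#' is excluded as prone to undersampling. Zero bins are dropped with a
#' warning; fewer than 3 usable bins is an error.
#'
#' @param spectrum a \code{body_mass_spectrum}.
#' @param quantity \code{"biomass"} or \code{"flux"}.
#' @return slope per decade of body mass.
#' @export
spectrum_slope <- function(spectrum, quantity = c("biomass", "flux")) {
  quantity <- match.arg(quantity)
  y <- if (quantity == "biomass") spectrum$biomass else spectrum$flux_mW
  x <- spectrum$mid_log10_ug
  keep <- seq_len(4)
  usable <- keep[!is.na(y[keep]) & y[keep] > 0]
  if (length(usable) < length(keep)) {
    warning("dropping ", length(keep) - length(usable),
            " empty bin(s) from the spectrum fit", call. = FALSE)
  }
  if (length(usable) < 3) {
    stop("fewer than 3 nonzero bins among classes 1-4: slope not estimable")
  }
  fit <- stats::lm(log10(y[usable]) ~ x[usable])
  unname(stats::coef(fit)[2])
}

#' Convert an energy flux to a fresh-biomass equivalent
#'
#' Expresses a flux in the fresh biomass whose energy content it matches
#' over one year, using the energy density of fresh biomass (default 7e6 J
#' per kg) and a 365-day year.
#'
#' @param flux_mW energy flux, mW per square metre (>= 0).
#' @param config an [fw_config()] supplying \code{energy_density} and
#'   \code{seconds_per_year}.
#' @return fresh biomass, g per square metre per year.
#' @export
#' @examples
#' flux_to_fresh_biomass(1090)  # ~4910.6 g m-2 y-1
flux_to_fresh_biomass <- function(flux_mW, config = fw_config()) {
  stopifnot(all(flux_mW >= 0))
  flux_mW * 1e-3 * config$seconds_per_year / config$energy_density * 1e3
}

#' Share of net primary production consumed by the community
#'
#' @param total_flux_mW community total energy flux, mW per square metre.
#' @param npp_g net primary production, g fresh biomass per square metre
#'   per year (> 0).
#' @param config an [fw_config()].
#' @return percentage of NPP.
#' @export
#' @examples
#' round(npp_share(1090, 6050))  # 81
npp_share <- function(total_flux_mW, npp_g, config = fw_config()) {
  stopifnot(npp_g > 0)
  flux_to_fresh_biomass(total_flux_mW, config) / npp_g * 100
}

#' Annual mean of a monthly relative-biomass series
#'
#' Utility for assessing snapshot-sampling bias: given macrofauna biomass
#' per month expressed as a percentage of a reference month (= 100), the
#' annual mean percentage summarises how representative the reference
#' month is.
#'
#' @param monthly_percent numeric vector of 1-12 monthly percentages.
#' @return arithmetic mean, percent of the reference month.
#' @export
annual_mean_relative_biomass <- function(monthly_percent) {
  stopifnot(length(monthly_percent) >= 1, length(monthly_percent) <= 12,
            all(is.finite(monthly_percent)))
  mean(monthly_percent)
}
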