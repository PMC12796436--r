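# Weighted trophic-network reconstruction.
#
# Link plausibility is the entrywise product of six factor matrices, each
# scaled to [0, 1]: feeding preference, body-mass-ratio niche overlap,
# microhabitat overlap, prey biomass, prey protection, and isotopic
# distance. Columns (consumer diets) are normalised to sum to 1.

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Predator-prey body-mass-ratio link weight
#'
#' Overlap coefficient of the prey's log10 body-mass distribution
#' \code{Normal(mu_prey, sigma^2)} with the predator's optimum-prey
#' distribution \code{Normal(mu_pred - log10(R*), sigma^2)}, where \code{R*}
#' is the optimum predator-prey mass ratio. For two equal-variance normals
#' at distance \code{d} the overlap is \code{2 * pnorm(-d / (2 * sigma))}:
#' 1 when the prey sits exactly \code{R*} times below the predator, falling
#' off symmetrically with the log-ratio mismatch.
#'
#' @param mu_pred,mu_prey log10 fresh body masses (any common unit).
#' @param sigma standard deviation of log10 body mass (> 0).
#' @param ppmr_optimum optimum predator-prey mass ratio (default 100).
#' @return weight in [0, 1].
#' @export
#' @examples
#' ppmr_weight(2, 0)  # prey exactly 100x lighter -> 1
ppmr_weight <- function(mu_pred, mu_prey, sigma = 1, ppmr_optimum = 100) {
  stopifnot(all(is.finite(mu_pred)), all(is.finite(mu_prey)), sigma > 0)
  d <- abs(mu_prey - (mu_pred - log10(ppmr_optimum)))
  2 * stats::pnorm(-d / (2 * sigma))
}

#' Microhabitat (vertical niche) overlap
#'
#' Sum over microhabitat layers of the elementwise minimum of the two
#' weight vectors (soil, litter, ground, aboveground), each summing to 1.
#'
#' @param h_pred,h_prey habitat weight vectors.
#' @return overlap in [0, 1].
#' @export
habitat_overlap <- function(h_pred, h_prey) {
  h_pred <- as.numeric(h_pred); h_prey <- as.numeric(h_prey)
  stopifnot(length(h_pred) == length(h_prey),
            abs(sum(h_pred) - 1) < 1e-9, abs(sum(h_prey) - 1) < 1e-9)
  sum(pmin(h_pred, h_prey))
}

#' Isotopic-distance link weight
#'
#' The prey signature is shifted by the trophic enrichment factors (+3.4
#' permil d15N, +0.4 permil d13C by default); the weight is a Gaussian
#' kernel of the Euclidean distance D between the shifted prey and the
#' predator in (d15N, d13C) space: \code{exp(-D^2 / (2 b^2))} with
#' bandwidth b. Any missing isotope value yields the neutral weight 1.
#'
#' @param pred_d15N,pred_d13C predator signature, permil.
#' @param prey_d15N,prey_d13C prey signature, permil.
#' @param config an [fw_config()] supplying TEFs and the bandwidth.
#' @param warn warn when falling back to the neutral weight.
#' @return weight in (0, 1].
#' @export
isotope_weight <- function(pred_d15N, pred_d13C, prey_d15N, prey_d13C,
                           config = fw_config(), warn = FALSE) {
  vals <- c(pred_d15N, pred_d13C, prey_d15N, prey_d13C)
  if (anyNA(vals)) {
    if (warn) warning("missing isotope value: neutral link weight used",
                      call. = FALSE)
    return(1)
  }
  dn <- pred_d15N - (prey_d15N + config$tef_d15N)
  dc <- pred_d13C - (prey_d13C + config$tef_d13C)
  D2 <- dn^2 + dc^2
  exp(-D2 / (2 * config$isotope_bandwidth^2))
}

#' Algal diet fraction inferred from d15N
#'
#' Algivores carry distinctly low d15N; the algal fraction is scaled
#' linearly from 0 at the algivory threshold (2 permil) to 1 at the
#' observed minimum (-1.4 permil), clamped to [0, 1].
#'
#' @param d15N litter-calibrated d15N, permil.
#' @param config an [fw_config()].
#' @return algal diet fraction in [0, 1].
#' @export
#' @examples
#' refine_algivory(-1.4)  # 1
#' refine_algivory(0.3)   # 0.5
refine_algivory <- function(d15N, config = fw_config()) {
  stopifnot(!is.na(d15N))
  hi <- config$algivory_d15N_zero
  lo <- config$algivory_d15N_full
  clamp01((hi - d15N) / (hi - lo))
}

#' Earthworm soil-vs-litter diet split inferred from d15N
#'
#' Endogeic (soil-feeding) earthworms are d15N-enriched relative to epigeic
#' (litter-feeding) ones; the soil fraction scales linearly from 0 at 1.2
#' permil to 1 at 5.5 permil.
#'
#' @param d15N litter-calibrated d15N, permil.
#' @param is_earthworm guard flag; the refinement applies to earthworms
#'   only.
#' @param config an [fw_config()].
#' @return list with \code{soil} and \code{litter} fractions (summing to 1)
#'   to be applied within the earthworm's detrital preference mass.
#' @export
refine_earthworm_soil <- function(d15N, is_earthworm = TRUE,
                                  config = fw_config()) {
  if (!isTRUE(is_earthworm)) {
    stop("soil-vs-litter refinement applies to earthworm guilds only")
  }
  stopifnot(!is.na(d15N))
  lo <- config$earthworm_d15N_litter
  hi <- config$earthworm_d15N_soil
  soil <- clamp01((d15N - lo) / (hi - lo))
  list(soil = soil, litter = 1 - soil)
}

#' Omnivore predation fraction inferred from d15N
#'
#' Auxiliary feeding on other invertebrates scales linearly between the
#' minimum and maximum d15N observed in the local food web.
#'
#' @param d15N guild d15N, permil.
#' @param web_min,web_max d15N range over the web's guilds.
#' @return predation fraction in [0, 1]; a degenerate web (max == min)
#'   yields 0.5 with a warning.
#' @export
refine_omnivore_predation <- function(d15N, web_min, web_max) {
  stopifnot(!is.na(d15N))
  if (web_max <= web_min) {
    warning("degenerate d15N range in web; predation fraction set to 0.5",
            call. = FALSE)
    return(0.5)
  }
  clamp01((d15N - web_min) / (web_max - web_min))
}

#' Apply the isotope-based diet refinements to a bundle
#'
#' Rewrites guild feeding preferences in place: (1) algal diet fraction for
#' every guild with a d15N value, remaining preferences rescaled to the
#' complement; (2) the detrital (litter + soil organic matter) preference
#' mass of earthworms split by the endogeic-epigeic d15N scaling; (3) the
#' animal-prey preference of omnivores set to the web-scaled predation
#' fraction with basal preferences rescaled to the complement. Guilds
#' without d15N are left untouched.
#'
#' @param bundle an \code{fw_bundle} (see [merge_tables()]).
#' @param config an [fw_config()].
#' @return the bundle with refined preferences.
#' @export
refine_preferences <- function(bundle, config = fw_config()) {
  stopifnot(inherits(bundle, "fw_bundle"))
  g <- bundle$guilds
  has_n <- !is.na(g$d15N)
  pref_mat <- as.matrix(g[, PREF_COLS])
  basal_cols <- paste0("pref_", RESOURCE_IDS)

  # (1) algivory
  for (i in which(has_n)) {
    frac <- refine_algivory(g$d15N[i], config)
    rest <- setdiff(PREF_COLS, "pref_A")
    rest_sum <- sum(pref_mat[i, rest])
    if (rest_sum > 0) {
      pref_mat[i, rest] <- pref_mat[i, rest] * (1 - frac) / rest_sum
    }
    pref_mat[i, "pref_A"] <- frac
  }

  # (2) earthworm litter-vs-soil split within the detrital mass
  for (i in which(has_n & g$is_earthworm)) {
    split <- refine_earthworm_soil(g$d15N[i], TRUE, config)
    det <- pref_mat[i, "pref_L"] + pref_mat[i, "pref_S"]
    pref_mat[i, "pref_S"] <- split$soil * det
    pref_mat[i, "pref_L"] <- split$litter * det
  }

  # (3) omnivore auxiliary predation, scaled to the web's d15N range
  if (any(has_n & g$is_omnivore)) {
    rng <- range(g$d15N[has_n])
    for (i in which(has_n & g$is_omnivore)) {
      p <- refine_omnivore_predation(g$d15N[i], rng[1], rng[2])
      basal_sum <- sum(pref_mat[i, basal_cols])
      if (basal_sum > 0) {
        pref_mat[i, basal_cols] <- pref_mat[i, basal_cols] * (1 - p) / basal_sum
      }
      pref_mat[i, "pref_animal"] <- p
    }
  }

  g[, PREF_COLS] <- pref_mat
  bundle$guilds <- g
  bundle
}

#' Rescale auxiliary resource preferences (omnivory sweep)
#'
#' For every guild, the main resource is the one with the largest
#' preference; all other nonzero preferences are set to \code{omega} times
#' the main preference (0 = strict specialists, 1 = auxiliary resources as
#' important as the main one). Zero preferences stay zero: the sweep never
#' invents trophic links.
#'
#' @param traits trait data frame (or the \code{guilds} table of a bundle).
#' @param omega omnivory parameter in [0, 1].
#' @return the table with rescaled preferences.
#' @export
apply_omnivory <- function(traits, omega) {
  stopifnot(is.numeric(omega), length(omega) == 1, omega >= 0, omega <= 1)
  pref_mat <- as.matrix(traits[, PREF_COLS])
  for (i in seq_len(nrow(pref_mat))) {
    p <- pref_mat[i, ]
    main <- max(p)
    aux <- p > 0 & p < main
    p[aux] <- omega * main
    pref_mat[i, ] <- p
  }
  traits[, PREF_COLS] <- pref_mat
  traits
}

#' Build the weighted diet matrix of a site's food web
#'
#' Constructs the column-stochastic diet matrix W over the seven basal
#' resources plus all guilds (rows) and all consumer guilds (columns).
#' Basal links take the guild's (refined) resource preferences. Animal
#' links i -> j take the product of the animal preference, the body-mass
#' niche overlap at the optimum predator-prey mass ratio, the microhabitat
#' overlap, the prey protection multiplier, the relative prey biomass
#' (B_i / max feasible prey biomass), and the isotopic-distance weight.
#' Each consumer column is split between the basal and animal preference
#' budgets implied by the refined preferences, then normalised to sum 1.
#'
#' @param bundle an \code{fw_bundle} whose preferences have already been
#'   refined (see [refine_preferences()]); self-predation is excluded.
#' @param config an [fw_config()].
#' @param save_factors attach the six factor matrices as attribute
#'   \code{"factors"} for diagnostics.
#' @return an object of class \code{food_web}: list with \code{nodes}
#'   (data frame), \code{W} (matrix, rows = nodes, columns = consumers),
#'   \code{resources} and \code{consumers} (character vectors).
#' @export
build_diet_matrix <- function(bundle, config = fw_config(),
                              save_factors = FALSE) {
  stopifnot(inherits(bundle, "fw_bundle"))
  g <- bundle$guilds
  G <- nrow(g)
  gids <- g$guild_id
  node_ids <- c(RESOURCE_IDS, gids)
  n <- length(node_ids)

  sigma <- ifelse(is.na(g$sigma_log_mass), config$sigma_log_mass,
                  g$sigma_log_mass)
  mu <- log10(g$mean_body_mass)  # log10 mg; only differences matter

  W <- matrix(0, n, G, dimnames = list(node_ids, gids))
  factors <- if (save_factors) {
    lapply(stats::setNames(nm = c("preference", "ppmr", "habitat",
                                  "protection", "biomass", "isotope")),
           function(nm) matrix(NA_real_, G, G, dimnames = list(gids, gids)))
  }

  hab <- as.matrix(g[, HAB_COLS])
  feasible_prey_b <- g$biomass
  for (j in seq_len(G)) {
    prefs <- as.numeric(g[j, PREF_COLS])
    names(prefs) <- PREF_COLS
    basal <- prefs[paste0("pref_", RESOURCE_IDS)]
    animal <- prefs[["pref_animal"]]
    total_budget <- sum(basal) + animal
    if (total_budget <= 0) {
      stop("consumer '", gids[j], "' has an all-zero preference column: ",
           "web is infeasible")
    }

    raw_animal <- numeric(G)
    if (animal > 0) {
      prey <- setdiff(seq_len(G), j)
      if (length(prey) == 0) {
        stop("consumer '", gids[j], "' has an animal-prey preference but no ",
             "feasible prey: web is infeasible")
      }
      bmax <- max(feasible_prey_b[prey])
      for (i in prey) {
        w_ppmr <- ppmr_weight(mu[j], mu[i],
                              sigma = sqrt((sigma[i]^2 + sigma[j]^2) / 2),
                              ppmr_optimum = config$ppmr_optimum)
        w_hab <- habitat_overlap(hab[j, ], hab[i, ])
        w_prot <- g$protection[i]
        w_bio <- if (bmax > 0) feasible_prey_b[i] / bmax else 0
        w_iso <- isotope_weight(g$d15N[j], g$d13C[j], g$d15N[i], g$d13C[i],
                                config)
        raw_animal[i] <- animal * w_ppmr * w_hab * w_prot * w_bio * w_iso
        if (save_factors) {
          factors$preference[i, j] <- animal
          factors$ppmr[i, j] <- w_ppmr
          factors$habitat[i, j] <- w_hab
          factors$protection[i, j] <- w_prot
          factors$biomass[i, j] <- w_bio
          factors$isotope[i, j] <- w_iso
        }
      }
      if (sum(raw_animal) <= 0) {
        stop("consumer '", gids[j], "' has an animal-prey preference but no ",
             "feasible prey: web is infeasible")
      }
    }

    animal_share <- animal / total_budget
    basal_share <- sum(basal) / total_budget
    col <- numeric(n)
    if (basal_share > 0) {
      col[seq_along(RESOURCE_IDS)] <- basal / sum(basal) * basal_share
    }
    if (animal_share > 0) {
      col[length(RESOURCE_IDS) + seq_len(G)] <-
        raw_animal / sum(raw_animal) * animal_share
    }
    W[, j] <- col
  }

  nodes <- data.frame(
    node_id = node_ids,
    type = c(rep("resource", length(RESOURCE_IDS)), rep("guild", G)),
    biomass = c(rep(NA_real_, length(RESOURCE_IDS)), g$biomass),
    mass_mg = c(rep(NA_real_, length(RESOURCE_IDS)), g$mean_body_mass),
    N_pct = c(rep(NA_real_, length(RESOURCE_IDS)), g$N_pct),
    stringsAsFactors = FALSE
  )
  web <- structure(
    list(nodes = nodes, W = W, resources = RESOURCE_IDS, consumers = gids,
         site_id = bundle$site_id, context = bundle$context),
    class = "food_web")
  if (save_factors) attr(web, "factors") <- factors
  web
}

#' @export
print.food_web <- function(x, ...) {
  cat("<food_web>", x$site_id %||% "", "-", length(x$consumers),
      "consumer guilds over", length(x$resources), "basal resources;",
      sum(x$W > 0), "links\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
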