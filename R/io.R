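# Table readers, validators and network export.
#
# All inputs are plain comma-separated UTF-8 files with "." decimals.
# Column contracts:
#   community.csv: site_id, layer, guild_id, and biomass (g fresh m-2) or
#     both density (ind m-2) and mean_body_mass (mg fresh)
#   traits.csv:    guild_id, taxon_group, phylo_group, pref_A..pref_S,
#     pref_animal, protection, hab_soil, hab_litter, hab_ground,
#     hab_aboveground, is_earthworm, is_omnivore [, sigma_log_mass]
#   isotopes.csv:  guild_id [, d15N, d13C, C_pct, N_pct]
#   sites.csv:     site_id, forest_type, mean_annual_temperature, NPP,
#     soil_pH, litter_CN

PREF_COLS <- paste0("pref_", c(RESOURCE_IDS, "animal"))
HAB_COLS <- paste0("hab_", HABITAT_LAYERS)

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Load a community table
#'
#' Reads per-site, per-layer guild densities and biomasses. When biomass is
#' absent it is derived as density times mean individual body mass
#' (individuals per square metre times mg, reported in g per square metre).
#'
#' @param path community CSV (columns \code{site_id}, \code{layer},
#'   \code{guild_id}, and \code{biomass} or \code{density} +
#'   \code{mean_body_mass}).
#' @return a validated data frame with columns site_id, layer, guild_id,
#'   density, mean_body_mass, biomass.
#' @export
load_community <- function(path) {
  df <- read_csv_checked(path, c("site_id", "layer", "guild_id"), "community")
  if (!"biomass" %in% names(df) &&
      !all(c("density", "mean_body_mass") %in% names(df))) {
    stop("community table needs a 'biomass' column or both 'density' and ",
         "'mean_body_mass'")
  }
  for (col in c("biomass", "density", "mean_body_mass")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }
  validate_community(df)
}

#' Validate (and complete) a community table
#'
#' @param df data frame with the community.csv columns.
#' @return the validated data frame, biomass filled in where derivable.
#' @export
validate_community <- function(df) {
  bad_layer <- setdiff(unique(df$layer), c("litter", "soil"))
  if (length(bad_layer)) {
    stop("community layers must be 'litter' or 'soil'; found: ",
         paste(bad_layer, collapse = ", "))
  }
  key <- paste(df$site_id, df$layer, df$guild_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (site, layer, guild) rows: ",
         paste(gsub("\r", "/", dup), collapse = "; "))
  }
  derive <- is.na(df$biomass)
  if (any(derive)) {
    need <- derive & (is.na(df$density) | is.na(df$mean_body_mass))
    if (any(need)) {
      stop("rows lacking biomass must provide density and mean_body_mass ",
           "(guilds: ", paste(unique(df$guild_id[need]), collapse = ", "), ")")
    }
    # density [ind m-2] * mass [mg] -> g m-2
    df$biomass[derive] <- df$density[derive] * df$mean_body_mass[derive] / 1000
  }
  if (any(df$biomass < 0, na.rm = TRUE)) {
    stop("negative biomass for guild(s): ",
         paste(unique(df$guild_id[df$biomass < 0]), collapse = ", "))
  }
  if (any(!is.na(df$mean_body_mass) & df$mean_body_mass <= 0)) {
    stop("mean_body_mass must be positive")
  }
  df
}

#' Load a guild trait table
#'
#' @param path traits CSV with graded feeding preferences over the seven
#'   basal resources and animal prey, a protection multiplier, microhabitat
#'   weights and phylogenetic group.
#' @return validated data frame.
#' @export
load_traits <- function(path) {
  df <- read_csv_checked(
    path, c("guild_id", "taxon_group", "phylo_group", PREF_COLS, HAB_COLS,
            "protection", "is_earthworm", "is_omnivore"),
    "trait")
  validate_traits(df)
}

#' Validate a trait table
#' @param df data frame with the traits.csv columns.
#' @return the validated data frame.
#' @export
validate_traits <- function(df) {
  if (anyDuplicated(df$guild_id)) {
    stop("duplicate guild_id in trait table: ",
         paste(unique(df$guild_id[duplicated(df$guild_id)]), collapse = ", "))
  }
  prefs <- as.matrix(df[, PREF_COLS])
  if (any(!is.finite(prefs)) || any(prefs < 0) || any(prefs > 1)) {
    stop("feeding preferences must lie in [0, 1]")
  }
  if (any(rowSums(prefs) <= 0)) {
    stop("every guild needs at least one nonzero feeding preference ",
         "(offending: ",
         paste(df$guild_id[rowSums(prefs) <= 0], collapse = ", "), ")")
  }
  hab <- as.matrix(df[, HAB_COLS])
  if (any(abs(rowSums(hab) - 1) > 1e-9)) {
    stop("microhabitat weights must sum to 1 (offending: ",
         paste(df$guild_id[abs(rowSums(hab) - 1) > 1e-9], collapse = ", "), ")")
  }
  if (any(df$protection < 0 | df$protection > 1)) {
    stop("protection multiplier must lie in [0, 1]")
  }
  df$is_earthworm <- as.logical(df$is_earthworm)
  df$is_omnivore <- as.logical(df$is_omnivore)
  if (!"sigma_log_mass" %in% names(df)) df$sigma_log_mass <- NA_real_
  df
}

#' Load a guild isotope table
#'
#' @param path isotopes CSV: litter-calibrated d15N and d13C (permil) and
#'   elemental C and N content (mass percent) per guild; any value may be
#'   missing.
#' @return data frame with columns guild_id, d15N, d13C, C_pct, N_pct.
#' @export
load_isotopes <- function(path) {
  df <- read_csv_checked(path, "guild_id", "isotope")
  for (col in c("d15N", "d13C", "C_pct", "N_pct")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Load a site context table
#'
#' @param path sites CSV: forest type, mean annual temperature (deg C), NPP
#'   (g fresh biomass per square metre per year), soil pH, litter C/N.
#' @return validated data frame.
#' @export
load_sites <- function(path) {
  df <- read_csv_checked(
    path, c("site_id", "forest_type", "mean_annual_temperature"), "site")
  for (col in c("NPP", "soil_pH", "litter_CN")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }
  if (any(!is.finite(df$mean_annual_temperature))) {
    stop("mean_annual_temperature must be finite for every site")
  }
  df
}

#' Merge community, trait, isotope and site tables into analysis bundles
#'
#' Layers (litter and soil) are summed per guild before reconstruction: one
#' food web is built per site, with layer identity kept only for biomass
#' reporting. Guilds without isotope values are flagged; downstream the
#' isotopic link weight falls back to neutral (1) for them.
#'
#' @param community,traits,isotopes,context data frames as returned by the
#'   `load_*` readers (`isotopes` may be NULL).
#' @return a named list of per-site bundles (class \code{fw_bundle}), each
#'   with elements \code{site_id}, \code{context} (1-row data frame),
#'   \code{guilds} (data frame with biomass_litter, biomass_soil, biomass,
#'   traits, isotopes) and \code{missing_isotopes} (character vector of
#'   flagged guilds).
#' @export
merge_tables <- function(community, traits, isotopes = NULL, context = NULL) {
  community <- validate_community(community)
  traits <- validate_traits(traits)
  unknown <- setdiff(unique(community$guild_id), traits$guild_id)
  if (length(unknown)) {
    stop("community guild(s) absent from trait table: ",
         paste(unknown, collapse = ", "))
  }
  sites <- unique(community$site_id)
  out <- lapply(sites, function(sid) {
    com <- community[community$site_id == sid, , drop = FALSE]
    gids <- unique(com$guild_id)
    g <- traits[match(gids, traits$guild_id), , drop = FALSE]
    g$biomass_litter <- vapply(gids, function(id) {
      sum(com$biomass[com$guild_id == id & com$layer == "litter"])
    }, numeric(1))
    g$biomass_soil <- vapply(gids, function(id) {
      sum(com$biomass[com$guild_id == id & com$layer == "soil"])
    }, numeric(1))
    g$biomass <- g$biomass_litter + g$biomass_soil
    # biomass-weighted mean body mass across layers
    g$mean_body_mass <- vapply(gids, function(id) {
      rows <- com$guild_id == id & !is.na(com$mean_body_mass)
      if (!any(rows)) return(NA_real_)
      wts <- com$biomass[rows]
      if (sum(wts) <= 0) wts <- rep(1, sum(rows))
      sum(com$mean_body_mass[rows] * wts) / sum(wts)
    }, numeric(1))
    g$density <- vapply(gids, function(id) {
      rows <- com$guild_id == id & !is.na(com$density)
      if (!any(rows)) return(NA_real_)
      sum(com$density[rows])
    }, numeric(1))
    if (any(is.na(g$mean_body_mass))) {
      stop("site ", sid, ": mean_body_mass missing for guild(s): ",
           paste(gids[is.na(g$mean_body_mass)], collapse = ", "))
    }
    for (col in c("d15N", "d13C", "C_pct", "N_pct")) g[[col]] <- NA_real_
    if (!is.null(isotopes)) {
      m <- match(gids, isotopes$guild_id)
      for (col in c("d15N", "d13C", "C_pct", "N_pct")) {
        g[[col]] <- isotopes[[col]][m]
      }
    }
    flagged <- gids[is.na(g$d15N) | is.na(g$d13C)]
    if (length(flagged)) {
      warning("site ", sid, ": no complete isotope signature for ",
              paste(flagged, collapse = ", "),
              "; isotopic link weights fall back to neutral", call. = FALSE)
    }
    ctx <- if (!is.null(context)) {
      context[context$site_id == sid, , drop = FALSE]
    } else {
      data.frame(site_id = sid, forest_type = NA_character_,
                 mean_annual_temperature = NA_real_, NPP = NA_real_,
                 soil_pH = NA_real_, litter_CN = NA_real_)
    }
    if (nrow(ctx) != 1) stop("site ", sid, ": need exactly one context row")
    rownames(g) <- NULL
    structure(list(site_id = sid, context = ctx, guilds = g,
                   missing_isotopes = flagged),
              class = "fw_bundle")
  })
  names(out) <- sites
  out
}

#' @export
print.fw_bundle <- function(x, ...) {
  cat("<fw_bundle> site", x$site_id, "-", nrow(x$guilds), "guilds,",
      sprintf("%.2f g m-2 total biomass", sum(x$guilds$biomass)), "\n")
  invisible(x)
}

#' Export a solved food web as an edge list or GraphML
#'
#' Writes one row/edge per nonzero trophic link carrying the diet share
#' W_ij and the energy flux (mW per square metre), with node attributes
#' biomass, body mass, trophic level and total intake.
#'
#' @param web a \code{food_web} (see [build_diet_matrix()]).
#' @param fluxes a \code{flux_solution} for that web.
#' @param path output file.
#' @param format \code{"csv"} (edge list) or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(web, fluxes, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(web, "food_web"))
  if (!inherits(fluxes, "flux_solution")) {
    stop("web is not solved: pass the flux_solution from solve_fluxes()")
  }
  W <- web$W
  idx <- which(W > 0, arr.ind = TRUE)
  edges <- data.frame(
    source = rownames(W)[idx[, 1]],
    target = colnames(W)[idx[, 2]],
    diet_share = W[idx],
    flux_mW = fluxes$L[idx],
    stringsAsFactors = FALSE
  )
  nodes <- data.frame(
    node_id = rownames(W),
    type = ifelse(rownames(W) %in% web$resources, "resource", "guild"),
    biomass = web$nodes$biomass[match(rownames(W), web$nodes$node_id)],
    body_mass_mg = web$nodes$mass_mg[match(rownames(W), web$nodes$node_id)],
    trophic_level = fluxes$TL[rownames(W)],
    intake_mW = ifelse(rownames(W) %in% colnames(W),
                       fluxes$F[match(rownames(W), colnames(W))], 0),
    stringsAsFactors = FALSE
  )
  if (format == "csv") {
    utils::write.csv(edges, path, row.names = FALSE)
  } else {
    gr <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                        vertices = nodes)
    igraph::write_graph(gr, path, format = "graphml")
  }
  invisible(path)
}
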