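# Seeded generator of synthetic forest-site communities.
#
# Emulates the statistical structure the analysis assumes for the five
# studied forest types: site total biomass drawn from a truncated normal at
# the forest type's mean +/- SD, the litter-vs-soil layer split, a guild
# pool spanning nematodes to earthworms across the five body-mass classes,
# earthworm dominance (> 90% of biomass) in mixed broadleaved forests,
# termites confined to the tropics, and an isotopic hierarchy of ~3.4
# permil d15N per intended trophic level over a 0-permil litter baseline.

# -- guild pool ---------------------------------------------------------

guild_row <- function(guild_id, taxon_group, phylo_group, mass_mg, tl,
                      prefs = c(), protection = 1,
                      habitat = c(soil = 0.25, litter = 0.45, ground = 0.25,
                                  aboveground = 0.05),
                      is_earthworm = FALSE, is_omnivore = FALSE,
                      N_pct = 10.5, C_pct = 46) {
  p <- stats::setNames(numeric(length(PREF_COLS)), PREF_COLS)
  p[paste0("pref_", names(prefs))] <- prefs
  h <- stats::setNames(numeric(length(HAB_COLS)), HAB_COLS)
  h[paste0("hab_", names(habitat))] <- habitat
  h <- h / sum(h)
  cbind(
    data.frame(guild_id = guild_id, taxon_group = taxon_group,
               phylo_group = phylo_group, mass_mg = mass_mg,
               intended_tl = tl, protection = protection,
               is_earthworm = is_earthworm, is_omnivore = is_omnivore,
               N_pct = N_pct, C_pct = C_pct, stringsAsFactors = FALSE),
    as.data.frame(as.list(p)), as.data.frame(as.list(h))
  )
}

#' The synthetic guild pool
#'
#' A pool of soil invertebrate guilds spanning the five body-mass classes,
#' with feeding preferences, protection, microhabitat weights and an
#' intended trophic level driving the generated isotope signatures. Values
#' are plausible for testing, not calibrated measurements.
#'
#' @return data frame, one row per guild.
#' @export
synthetic_guild_pool <- function() {
  rows <- list(
    guild_row("nematode_bacterivore", "nematode-bacterivore", "nematode",
              4e-4, 2, c(B = 1), habitat = c(soil = 0.7, litter = 0.3)),
    guild_row("nematode_fungivore", "nematode-fungivore", "nematode",
              6e-4, 2, c(F = 1), habitat = c(soil = 0.7, litter = 0.3)),
    guild_row("nematode_herbivore", "nematode-herbivore", "nematode",
              1e-3, 2, c(P = 1), habitat = c(soil = 0.8, litter = 0.2)),
    guild_row("nematode_omnivore", "nematode-omnivore", "nematode",
              5e-3, 2.5, c(B = 0.5, F = 0.3, animal = 0.4),
              habitat = c(soil = 0.7, litter = 0.3), is_omnivore = TRUE),
    guild_row("nematode_predator", "nematode-predator", "nematode",
              8e-3, 3, c(animal = 1), habitat = c(soil = 0.7, litter = 0.3)),
    guild_row("springtail", "springtail", "insect",
              5e-3, 2, c(F = 0.8, L = 0.4, A = 0.2),
              habitat = c(soil = 0.25, litter = 0.55, ground = 0.2)),
    guild_row("oribatid_mite", "oribatid-mite", "arachnid",
              0.01, 2, c(F = 0.6, L = 0.6, W = 0.1), protection = 0.5,
              habitat = c(soil = 0.35, litter = 0.55, ground = 0.1)),
    guild_row("mesostigmatid_mite", "mesostigmatid-mite", "arachnid",
              0.02, 3, c(animal = 1),
              habitat = c(soil = 0.3, litter = 0.55, ground = 0.15)),
    guild_row("enchytraeid", "enchytraeid", "oligochaete",
              0.1, 2, c(L = 0.6, S = 0.4, F = 0.3),
              habitat = c(soil = 0.6, litter = 0.4)),
    guild_row("symphylan", "symphylan", "myriapod",
              0.2, 2, c(F = 0.5, L = 0.5, P = 0.3),
              habitat = c(soil = 0.6, litter = 0.4)),
    guild_row("pseudoscorpion", "pseudoscorpion", "arachnid",
              0.5, 3, c(animal = 1),
              habitat = c(litter = 0.7, ground = 0.3)),
    guild_row("thrips_psocoptera", "small-insect", "insect",
              0.3, 2, c(F = 0.5, A = 0.5, L = 0.3),
              habitat = c(litter = 0.6, ground = 0.2, aboveground = 0.2)),
    guild_row("spider", "spider", "arachnid",
              10, 3.5, c(animal = 1),
              habitat = c(litter = 0.4, ground = 0.45, aboveground = 0.15)),
    guild_row("centipede", "centipede", "myriapod",
              20, 3.5, c(animal = 1),
              habitat = c(soil = 0.25, litter = 0.5, ground = 0.25)),
    guild_row("ground_beetle", "beetle-predator", "insect",
              15, 3, c(animal = 1),
              habitat = c(litter = 0.4, ground = 0.6)),
    guild_row("detritivorous_beetle", "beetle-detritivore", "insect",
              10, 2, c(L = 0.6, W = 0.4, F = 0.2), protection = 0.7,
              habitat = c(soil = 0.2, litter = 0.5, ground = 0.3)),
    guild_row("millipede", "millipede", "myriapod",
              25, 2, c(L = 0.8, S = 0.3, W = 0.2), protection = 0.6,
              habitat = c(soil = 0.2, litter = 0.6, ground = 0.2)),
    guild_row("woodlouse", "woodlouse", "crustacean",
              12, 2, c(L = 0.7, W = 0.3), protection = 0.8,
              habitat = c(litter = 0.6, ground = 0.4)),
    guild_row("earthworm_epigeic", "earthworm", "oligochaete",
              150, 2, c(L = 0.8, S = 0.4),
              habitat = c(soil = 0.35, litter = 0.65),
              is_earthworm = TRUE),
    guild_row("earthworm_endogeic", "earthworm", "oligochaete",
              400, 2, c(S = 0.8, L = 0.3),
              habitat = c(soil = 0.9, litter = 0.1),
              is_earthworm = TRUE),
    guild_row("termite", "termite", "insect",
              3, 2, c(W = 0.7, L = 0.4, S = 0.2),
              habitat = c(soil = 0.4, litter = 0.4, ground = 0.2)),
    guild_row("ant", "ant", "insect",
              5, 3, c(animal = 0.6, P = 0.2, F = 0.1), protection = 0.8,
              habitat = c(soil = 0.2, litter = 0.3, ground = 0.4,
                          aboveground = 0.1), is_omnivore = TRUE),
    guild_row("dipluran", "dipluran", "insect",
              2, 3.5, c(animal = 1),
              habitat = c(soil = 0.5, litter = 0.5)),
    guild_row("orthopteran", "orthopteran", "insect",
              80, 2, c(P = 0.8, L = 0.3),
              habitat = c(litter = 0.2, ground = 0.5, aboveground = 0.3))
  )
  do.call(rbind, rows)
}

# Guilds always present so every size class and trophic role is covered.
CORE_GUILDS <- c("nematode_bacterivore", "nematode_fungivore",
                 "nematode_predator", "springtail", "oribatid_mite",
                 "mesostigmatid_mite", "enchytraeid", "millipede",
                 "detritivorous_beetle", "spider", "earthworm_epigeic",
                 "earthworm_endogeic")

#' Forest-type presets of the synthetic generator
#'
#' One preset per forest type: site total biomass (mean and SD, g fresh per
#' square metre), the litter and soil layer means whose sum is the total,
#' mean annual temperature, NPP, and relative biomass weights per guild
#' (ranges; draws are renormalised to shares). Mixed broadleaved presets
#' put > 90% of the biomass into earthworms; termites occur only in the
#' tropical presets; macrofauna weights rise toward the tropics.
#'
#' @return named list of presets over the five forest types.
#' @export
forest_presets <- function() {
  w <- function(...) {
    v <- list(...)
    data.frame(guild_id = names(v),
               w_lo = vapply(v, `[`, numeric(1), 1),
               w_hi = vapply(v, `[`, numeric(1), 2),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(
    taiga = list(
      forest_type = "taiga",
      total_mean = 7.8, total_sd = 3.3,
      litter_mean = 4.1, soil_mean = 3.7,
      temperature = 5.2, NPP = 4091, soil_pH = 4.5, litter_CN = 35,
      weights = w(
        nematode_bacterivore = c(2, 5), nematode_fungivore = c(1, 3),
        nematode_herbivore = c(0.5, 2), nematode_omnivore = c(0.5, 2),
        nematode_predator = c(0.5, 1.5), springtail = c(6, 12),
        oribatid_mite = c(6, 12), mesostigmatid_mite = c(1, 3),
        enchytraeid = c(8, 15), symphylan = c(0.5, 2),
        pseudoscorpion = c(0.2, 1), thrips_psocoptera = c(0.3, 1),
        spider = c(2, 5), centipede = c(1, 3), ground_beetle = c(2, 5),
        detritivorous_beetle = c(2, 5), millipede = c(1, 4),
        woodlouse = c(0.5, 2), earthworm_epigeic = c(10, 25),
        earthworm_endogeic = c(10, 25), orthopteran = c(0.2, 1))
    ),
    mixed_broadleaved = list(
      forest_type = "mixed_broadleaved",
      total_mean = 17.1, total_sd = 8.7,
      litter_mean = 2.1, soil_mean = 14.9,
      temperature = 7.1, NPP = 3095, soil_pH = 5.5, litter_CN = 25,
      weights = w(
        nematode_bacterivore = c(0.1, 0.4), nematode_fungivore = c(0.1, 0.3),
        nematode_herbivore = c(0.05, 0.2), nematode_omnivore = c(0.05, 0.2),
        nematode_predator = c(0.05, 0.15), springtail = c(0.3, 0.8),
        oribatid_mite = c(0.3, 0.8), mesostigmatid_mite = c(0.1, 0.3),
        enchytraeid = c(0.3, 0.8), symphylan = c(0.05, 0.2),
        pseudoscorpion = c(0.02, 0.1), thrips_psocoptera = c(0.02, 0.1),
        spider = c(0.2, 0.6), centipede = c(0.2, 0.5),
        ground_beetle = c(0.2, 0.6), detritivorous_beetle = c(0.2, 0.6),
        millipede = c(0.2, 0.6), woodlouse = c(0.1, 0.3),
        earthworm_epigeic = c(25, 35), earthworm_endogeic = c(65, 90),
        orthopteran = c(0.02, 0.1))
    ),
    beech = list(
      forest_type = "beech",
      total_mean = 26.9, total_sd = 11.5,
      litter_mean = 15.7, soil_mean = 11.2,
      temperature = 7.5, NPP = 4690, soil_pH = 5.0, litter_CN = 28,
      weights = w(
        nematode_bacterivore = c(1, 3), nematode_fungivore = c(1, 3),
        nematode_herbivore = c(0.3, 1), nematode_omnivore = c(0.3, 1),
        nematode_predator = c(0.3, 1), springtail = c(4, 8),
        oribatid_mite = c(4, 8), mesostigmatid_mite = c(1, 2),
        enchytraeid = c(4, 8), symphylan = c(0.5, 1.5),
        pseudoscorpion = c(0.2, 0.8), thrips_psocoptera = c(0.2, 0.8),
        spider = c(3, 6), centipede = c(2, 5), ground_beetle = c(3, 6),
        detritivorous_beetle = c(3, 6), millipede = c(3, 7),
        woodlouse = c(1, 3), earthworm_epigeic = c(15, 30),
        earthworm_endogeic = c(20, 35), dipluran = c(0.2, 0.8),
        orthopteran = c(0.2, 0.8))
    ),
    monsoon = list(
      forest_type = "monsoon",
      total_mean = 50.4, total_sd = 25.1,
      litter_mean = 27.5, soil_mean = 22.9,
      temperature = 26.0, NPP = 6050, soil_pH = 6.0, litter_CN = 22,
      weights = w(
        nematode_bacterivore = c(0.3, 1), nematode_fungivore = c(0.2, 0.8),
        nematode_herbivore = c(0.2, 0.8), nematode_omnivore = c(0.2, 0.6),
        nematode_predator = c(0.1, 0.5), springtail = c(1, 3),
        oribatid_mite = c(1, 3), mesostigmatid_mite = c(0.3, 1),
        enchytraeid = c(0.5, 2), symphylan = c(0.2, 0.8),
        pseudoscorpion = c(0.1, 0.5), thrips_psocoptera = c(0.2, 0.8),
        spider = c(5, 10), centipede = c(4, 8), ground_beetle = c(5, 10),
        detritivorous_beetle = c(6, 12), millipede = c(8, 15),
        woodlouse = c(2, 5), earthworm_epigeic = c(10, 20),
        earthworm_endogeic = c(15, 30), termite = c(8, 16),
        ant = c(4, 8), dipluran = c(0.5, 1.5), orthopteran = c(3, 8))
    ),
    rainforest = list(
      forest_type = "rainforest",
      total_mean = 6.6, total_sd = 3.1,
      litter_mean = 2.9, soil_mean = 3.7,
      temperature = 25.2, NPP = 7177, soil_pH = 4.3, litter_CN = 30,
      weights = w(
        nematode_bacterivore = c(0.3, 1), nematode_fungivore = c(0.2, 0.8),
        nematode_herbivore = c(0.2, 0.8), nematode_omnivore = c(0.2, 0.6),
        nematode_predator = c(0.1, 0.5), springtail = c(1.5, 4),
        oribatid_mite = c(1.5, 4), mesostigmatid_mite = c(0.3, 1),
        enchytraeid = c(0.5, 2), symphylan = c(0.2, 0.8),
        pseudoscorpion = c(0.1, 0.5), thrips_psocoptera = c(0.2, 0.8),
        spider = c(4, 8), centipede = c(3, 7), ground_beetle = c(4, 9),
        detritivorous_beetle = c(5, 10), millipede = c(6, 12),
        woodlouse = c(2, 5), earthworm_epigeic = c(6, 14),
        earthworm_endogeic = c(10, 20), termite = c(6, 12),
        ant = c(4, 8), dipluran = c(0.5, 1.5), orthopteran = c(2, 5))
    )
  )
}

# Taxon groups counted as macrofauna for the biomass-gradient diagnostics.
MACROFAUNA_GUILDS <- c("spider", "centipede", "ground_beetle",
                       "detritivorous_beetle", "millipede", "woodlouse",
                       "earthworm_epigeic", "earthworm_endogeic", "termite",
                       "ant", "orthopteran")

rtruncnorm_pos <- function(n, mean, sd) {
  # inverse-CDF sampling of Normal(mean, sd) truncated to (0, Inf)
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

#' Generate a synthetic forest site
#'
#' Draws one site's community, trait and isotope tables plus its context
#' row, reproducibly from the seed. Site total biomass comes from a
#' truncated normal at the forest preset's mean and SD; 12-20 guilds are
#' drawn from the pool (core guilds spanning all five body-mass classes
#' are always present; earthworms dominate mixed broadleaved sites); body
#' masses vary log-normally (SD 0.3 decades) around the pool means; d15N
#' is the litter baseline (0 permil) plus 3.4 permil per intended trophic
#' step plus Normal(0, 0.5) noise, and d13C analogously with the 0.4
#' permil enrichment.
#'
#' @param forest_type one of taiga, mixed_broadleaved, beech, monsoon,
#'   rainforest.
#' @param seed integer seed.
#' @param site_id site identifier (default derived from type and seed).
#' @return list of class \code{fw_site_tables} with elements
#'   \code{community}, \code{traits}, \code{isotopes}, \code{context} --
#'   data frames matching the CSV contracts of the `load_*` readers.
#' @export
generate_site <- function(forest_type, seed,
                          site_id = paste0(forest_type, "_", seed)) {
  presets <- forest_presets()
  if (!forest_type %in% names(presets)) {
    stop("unknown forest_type '", forest_type, "'; expected one of: ",
         paste(names(presets), collapse = ", "))
  }
  preset <- presets[[forest_type]]
  pool <- synthetic_guild_pool()

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  total_b <- rtruncnorm_pos(1, preset$total_mean, preset$total_sd)
  litter_frac <- preset$litter_mean / (preset$litter_mean + preset$soil_mean)

  avail <- preset$weights$guild_id
  core <- intersect(CORE_GUILDS, avail)
  extras <- setdiff(avail, core)
  n_guilds <- sample(12:20, 1)
  n_extra <- min(length(extras), max(0, n_guilds - length(core)))
  chosen <- c(core, if (n_extra > 0) sample(extras, n_extra))
  wtab <- preset$weights[match(chosen, preset$weights$guild_id), ]
  wdraw <- stats::runif(nrow(wtab), wtab$w_lo, wtab$w_hi)
  shares <- wdraw / sum(wdraw)

  g <- pool[match(chosen, pool$guild_id), ]
  mass <- 10^(log10(g$mass_mg) + stats::rnorm(nrow(g), 0, 0.3))
  biomass <- total_b * shares
  d15N <- 3.4 * (g$intended_tl - 1) + stats::rnorm(nrow(g), 0, 0.5)
  d13C <- 0.4 * (g$intended_tl - 1) + stats::rnorm(nrow(g), 0, 0.5)

  community <- do.call(rbind, lapply(c("litter", "soil"), function(layer) {
    frac <- if (layer == "litter") litter_frac else 1 - litter_frac
    data.frame(site_id = site_id, layer = layer, guild_id = g$guild_id,
               density = biomass * frac * 1000 / mass,
               mean_body_mass = mass, biomass = biomass * frac,
               stringsAsFactors = FALSE)
  }))
  rownames(community) <- NULL

  traits <- data.frame(
    guild_id = g$guild_id, taxon_group = g$taxon_group,
    phylo_group = g$phylo_group, g[, PREF_COLS], protection = g$protection,
    g[, HAB_COLS], is_earthworm = g$is_earthworm,
    is_omnivore = g$is_omnivore, sigma_log_mass = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)

  isotopes <- data.frame(guild_id = g$guild_id, d15N = d15N, d13C = d13C,
                         C_pct = g$C_pct, N_pct = g$N_pct,
                         stringsAsFactors = FALSE)

  context <- data.frame(
    site_id = site_id, forest_type = forest_type,
    mean_annual_temperature = preset$temperature, NPP = preset$NPP,
    soil_pH = preset$soil_pH, litter_CN = preset$litter_CN,
    stringsAsFactors = FALSE)

  structure(list(community = community, traits = traits,
                 isotopes = isotopes, context = context),
            class = "fw_site_tables")
}

#' Write a generated site to CSV files plus a config stub
#'
#' @param tables an \code{fw_site_tables} (see [generate_site()]).
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
simulate_site_files <- function(tables, dir) {
  stopifnot(inherits(tables, "fw_site_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(tables$community, file.path(dir, "community.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$isotopes, file.path(dir, "isotopes.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$context, file.path(dir, "sites.csv"),
                   row.names = FALSE)
  write_config(fw_config(), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Merge generated site tables into an analysis bundle
#'
#' @param tables an \code{fw_site_tables}.
#' @return a single \code{fw_bundle}.
#' @export
as_bundle <- function(tables) {
  stopifnot(inherits(tables, "fw_site_tables"))
  merge_tables(tables$community, tables$traits, tables$isotopes,
               tables$context)[[1]]
}

#' Tiny hand-specified fixture webs
#'
#' Deterministic miniature communities with analytically tractable flux
#' solutions: \code{"chain3"} (litter -> detritivore -> predator at the
#' optimum mass ratio), \code{"loop"} (two mutually preying omnivores over
#' litter), and \code{"star"} (one predator over three prey identical
#' except for biomass 1:2:4).
#'
#' @param kind fixture name.
#' @return an \code{fw_bundle}.
#' @export
generate_fixture_web <- function(kind = c("chain3", "loop", "star")) {
  kind <- match.arg(kind)
  fixture_guild <- function(guild_id, mass_mg, biomass, prefs,
                            protection = 1, is_omnivore = FALSE) {
    r <- guild_row(guild_id, guild_id, "default", mass_mg, NA,
                   prefs, protection = protection,
                   habitat = c(litter = 1), is_omnivore = is_omnivore)
    r$intended_tl <- NULL
    names(r)[names(r) == "mass_mg"] <- "mean_body_mass"
    r$biomass_litter <- biomass
    r$biomass_soil <- 0
    r$biomass <- biomass
    r$density <- biomass * 1000 / mass_mg
    r$sigma_log_mass <- NA_real_
    r$d15N <- NA_real_; r$d13C <- NA_real_
    r$C_pct <- NA_real_
    r
  }
  guilds <- switch(kind,
    chain3 = rbind(
      fixture_guild("detritivore", 1, 2, c(L = 1)),
      fixture_guild("predator", 100, 0.5, c(animal = 1))),
    loop = rbind(
      fixture_guild("omnivore_a", 1, 1, c(L = 0.5, animal = 0.5),
                    is_omnivore = TRUE),
      fixture_guild("omnivore_b", 1, 1, c(L = 0.5, animal = 0.5),
                    is_omnivore = TRUE)),
    star = rbind(
      fixture_guild("prey_small", 1, 1, c(L = 1)),
      fixture_guild("prey_mid", 1, 2, c(L = 1)),
      fixture_guild("prey_big", 1, 4, c(L = 1)),
      fixture_guild("predator", 100, 0.5, c(animal = 1)))
  )
  rownames(guilds) <- NULL
  context <- data.frame(site_id = paste0("fixture_", kind),
                        forest_type = NA_character_,
                        mean_annual_temperature = 10, NPP = NA_real_,
                        soil_pH = NA_real_, litter_CN = NA_real_,
                        stringsAsFactors = FALSE)
  structure(list(site_id = paste0("fixture_", kind), context = context,
                 guilds = guilds, missing_isotopes = guilds$guild_id),
            class = "fw_bundle")
}
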