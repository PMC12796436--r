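# Independent oracles used to cross-check the package implementation.
# These deliberately re-derive everything from first principles and share
# no code with the package internals.

# Damped fixed-point iteration for the steady-state balance
#   e_bar_j F_j = X_j + sum_k W_jk F_k
# starting from F = 0. Independent of the linear solve in solve_fluxes().
fixed_point_fluxes <- function(W, X, e, damping = 0.5, tol = 1e-12,
                               max_iter = 200000) {
  consumers <- colnames(W)
  e <- e[rownames(W)]
  X <- X[consumers]
  e_bar <- as.numeric(t(e) %*% W)
  Wc <- W[consumers, , drop = FALSE]
  F_cur <- rep(0, length(consumers))
  for (i in seq_len(max_iter)) {
    F_new <- (X + as.numeric(Wc %*% F_cur)) / e_bar
    F_next <- (1 - damping) * F_cur + damping * F_new
    if (max(abs(F_next - F_cur)) <= tol * max(1, max(abs(F_next)))) {
      return(stats::setNames(F_next, consumers))
    }
    F_cur <- F_next
  }
  stop("fixed-point oracle did not converge")
}

# Seeded generator of small feasible random webs (<= 8 nodes): a couple of
# basal rows, consumers feeding mostly downward (plus occasional back-edges
# forming omnivory loops), efficiencies in (0.2, 0.99].
random_feasible_web <- function(seed) {
  set.seed(seed)
  n_res <- sample(1:2, 1)
  n_con <- sample(2:6, 1)
  nodes <- c(paste0("r", seq_len(n_res)), paste0("c", seq_len(n_con)))
  consumers <- paste0("c", seq_len(n_con))
  n <- length(nodes)
  W <- matrix(0, n, n_con, dimnames = list(nodes, consumers))
  for (j in seq_len(n_con)) {
    col_idx <- n_res + j
    lower <- seq_len(col_idx - 1)
    n_pick <- sample.int(length(lower), 1)
    picks <- lower[sample.int(length(lower), n_pick)]
    w <- stats::runif(length(picks))
    W[picks, j] <- w
    # occasional back-edge (omnivory loop), kept small so the web stays
    # energetically feasible; never onto the consumer itself
    if (col_idx < n && stats::runif(1) < 0.3) {
      higher <- (col_idx + 1):n
      back <- higher[sample.int(length(higher), 1)]
      W[back, j] <- 0.1 * stats::runif(1)
    }
    W[, j] <- W[, j] / sum(W[, j])
  }
  X <- stats::setNames(stats::runif(n_con, 0.1, 5), consumers)
  e <- stats::setNames(stats::runif(n, 0.2, 0.99), nodes)
  list(W = W, X = X, e = e)
}

# Entrywise brute-force recomputation of the diet matrix from a bundle's
# guild table, using plain formula evaluation (normal overlap coefficient,
# min-overlap of habitat vectors, Gaussian isotope kernel, biomass and
# protection scaling, preference budgets).
brute_force_diet_matrix <- function(bundle, config = trophicflux::fw_config()) {
  g <- bundle$guilds
  G <- nrow(g)
  res_ids <- c("A", "P", "B", "F", "L", "W", "S")
  nodes <- c(res_ids, g$guild_id)
  W <- matrix(0, length(nodes), G, dimnames = list(nodes, g$guild_id))
  sigma <- ifelse(is.na(g$sigma_log_mass), config$sigma_log_mass,
                  g$sigma_log_mass)
  for (j in seq_len(G)) {
    basal <- sapply(res_ids, function(r) g[[paste0("pref_", r)]][j])
    animal_pref <- g$pref_animal[j]
    total <- sum(basal) + animal_pref
    raw <- numeric(G)
    if (animal_pref > 0) {
      bmax <- max(g$biomass[-j])
      for (i in setdiff(seq_len(G), j)) {
        s <- sqrt((sigma[i]^2 + sigma[j]^2) / 2)
        d <- abs(log10(g$mean_body_mass[i]) -
                   (log10(g$mean_body_mass[j]) - log10(config$ppmr_optimum)))
        w_ppmr <- 2 * pnorm(-d / (2 * s))
        hj <- unlist(g[j, paste0("hab_", c("soil", "litter", "ground",
                                           "aboveground"))])
        hi <- unlist(g[i, paste0("hab_", c("soil", "litter", "ground",
                                           "aboveground"))])
        w_hab <- sum(pmin(hj, hi))
        iso <- c(g$d15N[j], g$d13C[j], g$d15N[i], g$d13C[i])
        w_iso <- if (anyNA(iso)) 1 else {
          dn <- iso[1] - (iso[3] + config$tef_d15N)
          dc <- iso[2] - (iso[4] + config$tef_d13C)
          exp(-(dn^2 + dc^2) / (2 * config$isotope_bandwidth^2))
        }
        raw[i] <- animal_pref * w_ppmr * w_hab * g$protection[i] *
          (if (bmax > 0) g$biomass[i] / bmax else 0) * w_iso
      }
    }
    col <- numeric(length(nodes))
    if (sum(basal) > 0) {
      col[seq_along(res_ids)] <- basal / sum(basal) * (sum(basal) / total)
    }
    if (animal_pref > 0 && sum(raw) > 0) {
      col[length(res_ids) + seq_len(G)] <- raw / sum(raw) *
        (animal_pref / total)
    }
    W[, j] <- col
  }
  W
}

# Minimal hand-built bundle for reconstruction tests (traits fully spelled
# out, independent of the package's fixture constructors).
manual_bundle <- function(guilds_df, site_id = "manual") {
  ctx <- data.frame(site_id = site_id, forest_type = NA_character_,
                    mean_annual_temperature = 10, NPP = NA_real_,
                    soil_pH = NA_real_, litter_CN = NA_real_,
                    stringsAsFactors = FALSE)
  structure(list(site_id = site_id, context = ctx, guilds = guilds_df,
                 missing_isotopes = character(0)),
            class = "fw_bundle")
}

manual_guild <- function(guild_id, mass_mg, biomass, prefs = c(),
                         protection = 1,
                         habitat = c(soil = 0, litter = 1, ground = 0,
                                     aboveground = 0),
                         d15N = NA_real_, d13C = NA_real_,
                         N_pct = 10, is_earthworm = FALSE,
                         is_omnivore = FALSE) {
  pref_names <- paste0("pref_", c("A", "P", "B", "F", "L", "W", "S",
                                  "animal"))
  p <- stats::setNames(as.list(numeric(8)), pref_names)
  for (nm in names(prefs)) p[[paste0("pref_", nm)]] <- prefs[[nm]]
  hab_names <- paste0("hab_", c("soil", "litter", "ground", "aboveground"))
  h <- stats::setNames(as.list(habitat[c("soil", "litter", "ground",
                                         "aboveground")]), hab_names)
  data.frame(guild_id = guild_id, taxon_group = guild_id,
             phylo_group = "default", mean_body_mass = mass_mg,
             biomass_litter = biomass, biomass_soil = 0, biomass = biomass,
             density = biomass * 1000 / mass_mg,
             sigma_log_mass = NA_real_, protection = protection,
             d15N = d15N, d13C = d13C, C_pct = NA_real_, N_pct = N_pct,
             is_earthworm = is_earthworm, is_omnivore = is_omnivore,
             as.data.frame(p), as.data.frame(h),
             stringsAsFactors = FALSE)
}
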