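# Per-site orchestration, the omnivory sensitivity sweep and multi-site
# aggregation.

#' Run the full analysis for one site
#'
#' Chains the stages: isotope-based preference refinements, diet-matrix
#' construction, metabolic demands at the site temperature, the
#' steady-state flux solve, and the summary layer (trophic functions,
#' fungivory:bacterivory ratio, body-mass spectrum, NPP share when the
#' context provides NPP).
#'
#' @param bundle an \code{fw_bundle}.
#' @param config an [fw_config()].
#' @param omega optional omnivory parameter overriding the trait-table
#'   preferences (see [apply_omnivory()]); the default uses the
#'   preferences as given.
#' @param save_factors keep the reconstruction factor matrices on the web.
#' @return list of class \code{fw_site_result}: \code{web},
#'   \code{solution}, \code{X}, \code{e}, \code{functions},
#'   \code{fb_ratio}, \code{spectrum}, \code{npp_share},
#'   \code{total_flux}, \code{site_id}.
#' @export
run_site <- function(bundle, config = fw_config(), omega = NULL,
                     save_factors = FALSE) {
  stopifnot(inherits(bundle, "fw_bundle"))
  sid <- bundle$site_id
  withCallingHandlers({
    if (is.null(omega) && is.numeric(config$omnivory_parameter)) {
      omega <- config$omnivory_parameter
    }
    if (!is.null(omega)) {
      bundle$guilds <- apply_omnivory(bundle$guilds, omega)
    }
    bundle <- refine_preferences(bundle, config)
    web <- build_diet_matrix(bundle, config, save_factors = save_factors)

    temp <- bundle$context$mean_annual_temperature
    coef_tab <- config$metabolic_coefficients
    g <- bundle$guilds
    X <- vapply(seq_len(nrow(g)), function(i) {
      co <- coef_tab[[g$phylo_group[i]]]
      if (is.null(co)) co <- coef_tab[["default"]]
      if (is.null(co)) stop("no metabolic coefficients for group '",
                            g$phylo_group[i], "'")
      node_metabolic_demand(g$biomass[i], g$mean_body_mass[i], temp, co,
                            config$boltzmann_k)
    }, numeric(1))
    names(X) <- g$guild_id
    e <- node_efficiencies(web, config)

    solution <- solve_fluxes(web$W, X, e)
    fns <- trophic_functions(solution, web)
    spectrum <- bin_spectrum(web, solution)
    npp <- bundle$context$NPP
    share <- if (is.finite(npp) && npp > 0) {
      npp_share(solution$total_flux, npp, config)
    } else {
      NA_real_
    }
    structure(list(site_id = sid, web = web, solution = solution, X = X,
                   e = e, functions = fns, fb_ratio = fb_ratio(fns),
                   spectrum = spectrum, npp_share = share,
                   total_flux = solution$total_flux),
              class = "fw_site_result")
  }, error = function(err) {
    stop("site ", sid, ": ", conditionMessage(err), call. = FALSE)
  })
}

#' @export
print.fw_site_result <- function(x, ...) {
  cat("<fw_site_result>", x$site_id, "- total flux",
      sprintf("%.4g mW m-2", x$total_flux))
  if (is.finite(x$npp_share)) cat(sprintf(" (%.1f%% of NPP)", x$npp_share))
  cat("\n")
  invisible(x)
}

#' Omnivory sensitivity sweep
#'
#' Re-runs reconstruction and flux estimation over the 11-point omnivory
#' grid (0, 0.1, ..., 1), rescaling every guild's auxiliary resource
#' preferences relative to its main resource, and tabulates the
#' trophic-function percentages per grid point. An infeasible grid point is
#' recorded as missing with a warning and the sweep continues.
#'
#' @param bundle an \code{fw_bundle}.
#' @param config an [fw_config()].
#' @param grid omnivory parameter values (default \code{seq(0, 1, 0.1)}).
#' @return data frame with columns \code{omega}, \code{total_flux} and one
#'   percentage column per trophic function; attribute \code{ranges} holds
#'   the min-max range of each function over the feasible grid points.
#' @export
omnivory_sweep <- function(bundle, config = fw_config(),
                           grid = seq(0, 1, by = 0.1)) {
  fn_names <- names(TROPHIC_FUNCTIONS)
  rows <- lapply(grid, function(om) {
    res <- tryCatch(run_site(bundle, config, omega = om),
                    error = function(err) {
                      warning("omnivory grid point ", om, " infeasible: ",
                              conditionMessage(err), call. = FALSE)
                      NULL
                    })
    if (is.null(res)) {
      as.data.frame(c(list(omega = om, total_flux = NA_real_),
                      stats::setNames(as.list(rep(NA_real_,
                                                  length(fn_names))),
                                      fn_names)))
    } else {
      pct <- stats::setNames(as.list(res$functions$percent),
                             res$functions$fn)
      as.data.frame(c(list(omega = om, total_flux = res$total_flux), pct))
    }
  })
  out <- do.call(rbind, rows)
  ranges <- vapply(fn_names, function(fn) {
    v <- out[[fn]]
    if (all(is.na(v))) c(NA_real_, NA_real_) else range(v, na.rm = TRUE)
  }, numeric(2))
  attr(out, "ranges") <- t(ranges)
  out
}

#' Aggregate per-site results by forest type
#'
#' Arithmetic mean and sample SD per forest type of total biomass, total
#' flux, NPP share, the trophic-function percentages and the spectrum
#' slopes, plus a layer-wise biomass table (litter, soil, total means).
#'
#' @param results list of \code{fw_site_result} objects.
#' @param bundles the matching list of \code{fw_bundle}s (for biomass and
#'   forest type).
#' @return list with data frames \code{summary} (one row per forest type
#'   and variable) and \code{biomass_layers}.
#' @export
aggregate_sites <- function(results, bundles) {
  stopifnot(length(results) == length(bundles), length(results) >= 1)
  per_site <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]; b <- bundles[[i]]
    pct <- stats::setNames(r$functions$percent,
                           paste0("pct_", r$functions$fn))
    data.frame(
      site_id = r$site_id,
      forest_type = b$context$forest_type,
      biomass_litter = sum(b$guilds$biomass_litter),
      biomass_soil = sum(b$guilds$biomass_soil),
      biomass_total = sum(b$guilds$biomass),
      total_flux = r$total_flux,
      npp_share = r$npp_share,
      fb_ratio = as.numeric(r$fb_ratio),
      slope_biomass = attr(r$spectrum, "slope_biomass"),
      slope_flux = attr(r$spectrum, "slope_flux"),
      t(pct),
      stringsAsFactors = FALSE)
  }))
  vars <- setdiff(names(per_site), c("site_id", "forest_type"))
  types <- unique(per_site$forest_type)
  summary <- do.call(rbind, lapply(types, function(ft) {
    sub <- per_site[per_site$forest_type == ft, vars, drop = FALSE]
    do.call(rbind, lapply(vars, function(v) {
      x <- sub[[v]]
      data.frame(forest_type = ft, variable = v, n = sum(!is.na(x)),
                 mean = mean(x, na.rm = TRUE),
                 sd = if (sum(!is.na(x)) > 1) stats::sd(x, na.rm = TRUE)
                      else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summary) <- NULL
  bl <- summary[summary$variable %in%
                  c("biomass_litter", "biomass_soil", "biomass_total"), ]
  list(summary = summary, biomass_layers = bl, per_site = per_site)
}

#' Write the standard per-site output files
#'
#' nodes.csv (biomass, body mass, demand, intake, trophic level),
#' edges.csv (diet shares and fluxes), spectrum.csv and summary.json.
#'
#' @param result an \code{fw_site_result}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_site_outputs <- function(result, dir) {
  stopifnot(inherits(result, "fw_site_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  web <- result$web; sol <- result$solution
  nodes <- data.frame(
    node_id = rownames(web$W),
    type = ifelse(rownames(web$W) %in% web$resources, "resource", "guild"),
    biomass = web$nodes$biomass,
    body_mass_mg = web$nodes$mass_mg,
    demand_mW = ifelse(rownames(web$W) %in% names(result$X),
                       result$X[rownames(web$W)], 0),
    intake_mW = ifelse(rownames(web$W) %in% names(sol$F),
                       sol$F[rownames(web$W)], 0),
    trophic_level = sol$TL[rownames(web$W)],
    stringsAsFactors = FALSE)
  utils::write.csv(nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  export_network(web, sol, file.path(dir, "edges.csv"), "csv")
  utils::write.csv(as.data.frame(result$spectrum),
                   file.path(dir, "spectrum.csv"), row.names = FALSE)
  summary <- list(
    site_id = result$site_id,
    total_flux_mW = result$total_flux,
    npp_share_percent = result$npp_share,
    fb_ratio = as.numeric(result$fb_ratio),
    functions = stats::setNames(as.list(result$functions$flux_mW),
                                result$functions$fn),
    percentages = stats::setNames(as.list(result$functions$percent),
                                  result$functions$fn),
    spectrum_slope_biomass = attr(result$spectrum, "slope_biomass"),
    spectrum_slope_flux = attr(result$spectrum, "slope_flux"))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
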