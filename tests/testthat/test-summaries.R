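# Trophic functions, spectrum binning and slopes, unit conversions.

test_that("trophic functions partition the total flux", {
  # all intake from litter
  b <- manual_bundle(manual_guild("det", 1, 1, c(L = 1)))
  res <- suppressWarnings(run_site(b))
  fns <- res$functions
  expect_equal(fns$percent[fns$fn == "litter_consumption"], 100)
  expect_equal(sum(fns$percent), 100, tolerance = 1e-6)

  # the worked chain: predator intake 1/0.9, detritivore (2 + 1/0.9)/0.18
  W <- matrix(0, 3, 2, dimnames = list(c("L", "det", "pred"),
                                       c("det", "pred")))
  W["L", "det"] <- 1; W["det", "pred"] <- 1
  sol <- solve_fluxes(W, c(det = 2, pred = 1),
                      c(L = 0.18, det = 0.9, pred = 0.9))
  web <- structure(list(
    nodes = data.frame(node_id = c("L", "det", "pred"),
                       type = c("resource", "guild", "guild"),
                       biomass = c(NA, 1, 0.5), mass_mg = c(NA, 1, 100),
                       N_pct = NA_real_),
    W = W, resources = "L", consumers = c("det", "pred")),
    class = "food_web")
  fns2 <- trophic_functions(sol, web)
  pred_pct <- fns2$percent[fns2$fn == "predation"]
  expect_equal(pred_pct, 1.11111 / (1.11111 + 17.28395) * 100,
               tolerance = 1e-4)
  expect_equal(pred_pct, 6.0386, tolerance = 1e-3)
  expect_equal(sum(fns2$percent), 100, tolerance = 1e-6)
  expect_equal(sum(fns2$flux_mW), sol$total_flux, tolerance = 1e-12)
})

test_that("fungivory-to-bacterivory ratio handles zero bacterivory", {
  df <- data.frame(fn = c("fungivory", "bacterivory"), flux_mW = c(3, 1),
                   percent = c(75, 25))
  expect_equal(fb_ratio(df), 3)
  df0 <- data.frame(fn = c("fungivory", "bacterivory"), flux_mW = c(3, 0),
                    percent = c(100, 0))
  r <- fb_ratio(df0)
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))
  # and equals an independent re-aggregation of the edge table
  res <- run_site(as_bundle(generate_site("beech", 1)))
  L <- res$solution$L
  expect_equal(as.numeric(res$fb_ratio),
               sum(L["F", ]) / sum(L["B", ]), tolerance = 1e-12)
})

test_that("mass bins follow the half-open log-linear edges", {
  expect_equal(mass_bin(10), 2L)      # large microfauna/microarthropods
  expect_equal(mass_bin(1.6), 2L)     # half-open lower edge
  expect_equal(mass_bin(0.05), 1L)
  expect_equal(mass_bin(1e5), 5L)     # 0.1 g
  expect_warning(b5 <- mass_bin(2e6), "clamped")  # 2 g
  expect_equal(b5, 5L)
  expect_warning(b1 <- mass_bin(0.01), "clamped")
  expect_equal(b1, 1L)
  # exhaustive and mutually exclusive over the clamped domain
  masses <- 10^seq(log10(0.06), log10(1.6e6), length.out = 500)
  bins <- mass_bin(masses)
  expect_setequal(unique(bins), 1:5)
  expect_true(all(diff(bins) >= 0))
})

test_that("spectrum slope uses bins 1-4 on the geometric midpoints", {
  spec <- data.frame(
    bin = 1:5,
    mid_log10_ug = (log10(0.05 * 32^(0:4)) + log10(0.05 * 32^(1:5))) / 2,
    biomass = c(1, 10, 100, 1000, 5),
    flux_mW = NA_real_)
  slope <- spectrum_slope(spec, "biomass")
  expect_equal(slope, 1 / 1.50515, tolerance = 1e-5)
  # equal sums -> slope 0
  spec$biomass <- rep(2, 5)
  expect_equal(spectrum_slope(spec, "biomass"), 0, tolerance = 1e-12)
  # bin 5 never enters the fit
  spec$biomass <- c(1, 10, 100, 1000, 123456)
  expect_equal(spectrum_slope(spec, "biomass"), slope, tolerance = 1e-12)
  # degenerate spectra are refused
  spec$biomass <- c(1, 10, 0, 0, 5)
  expect_error(suppressWarnings(spectrum_slope(spec, "biomass")),
               "fewer than 3")
})

test_that("bin_spectrum sums guild biomass and intake per class", {
  res <- run_site(as_bundle(generate_site("monsoon", 4)))
  spec <- res$spectrum
  g <- res$web$nodes[res$web$nodes$type == "guild", ]
  expect_equal(sum(spec$biomass), sum(g$biomass), tolerance = 1e-12)
  expect_equal(sum(spec$flux_mW), res$total_flux, tolerance = 1e-9)
  expect_true(is.finite(attr(spec, "slope_biomass")))
})

test_that("energy flux converts to fresh biomass and NPP shares", {
  expect_equal(flux_to_fresh_biomass(0), 0)
  # one kilogram's energy over a 365-day year
  expect_equal(flux_to_fresh_biomass(7e6 / 31536000 * 1000), 1000,
               tolerance = 1e-9)
  expect_equal(flux_to_fresh_biomass(221.969), 1000, tolerance = 1e-2)
  expect_equal(flux_to_fresh_biomass(1090), 1.090 * 31536000 / 7e6 * 1000,
               tolerance = 1e-9)
  expect_equal(flux_to_fresh_biomass(1090), 4910.6, tolerance = 1e-4)
  # linearity and scale invariance of the share
  expect_equal(flux_to_fresh_biomass(2 * 13.7),
               2 * flux_to_fresh_biomass(13.7), tolerance = 1e-12)
  expect_equal(npp_share(100, 1000), npp_share(700, 7000),
               tolerance = 1e-12)
  expect_error(npp_share(10, 0))
})

test_that("annual mean of a monthly relative-biomass series", {
  expect_equal(annual_mean_relative_biomass(rep(100, 12)), 100)
  expect_equal(annual_mean_relative_biomass(c(50, 150)), 100)
  series <- c(70, 55, 40, 33, 60, 100, 182, 182, 120, 90, 80, 68)
  expect_equal(annual_mean_relative_biomass(series), mean(series))
  expect_error(annual_mean_relative_biomass(rep(10, 13)))
})
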