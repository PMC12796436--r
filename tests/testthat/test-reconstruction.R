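# Diet-matrix construction: factor weights, refinements, normalisation.

test_that("body-mass-ratio weight is the normal overlap coefficient", {
  # prey exactly at the optimum ratio below the predator
  expect_equal(ppmr_weight(2, 0), 1)
  # two decades of mismatch at sigma 1: 2 * pnorm(-1)
  expect_equal(ppmr_weight(4, 0), 2 * pnorm(-1), tolerance = 1e-12)
  expect_equal(2 * pnorm(-1), 0.31731, tolerance = 1e-5)
  # symmetric in the mismatch, strictly decreasing, vanishing in the limit
  d <- seq(0, 8, by = 0.25)
  w_up <- ppmr_weight(2 + d, 0)
  w_dn <- ppmr_weight(2 - d, 0)
  expect_equal(w_up, w_dn, tolerance = 1e-12)
  expect_true(all(diff(w_up) < 0 | d[-1] == 0))
  expect_lt(ppmr_weight(40, 0), 1e-15)
})

test_that("habitat overlap is the min-sum of the weight vectors", {
  expect_equal(habitat_overlap(c(0.25, 0.25, 0.25, 0.25),
                               c(0.25, 0.25, 0.25, 0.25)), 1)
  # ground predator vs endogeic earthworm: disjoint layers
  expect_equal(habitat_overlap(c(0, 0, 1, 0), c(1, 0, 0, 0)), 0)
  expect_equal(habitat_overlap(c(0.5, 0.5, 0, 0), c(1, 0, 0, 0)), 0.5)
  expect_error(habitat_overlap(c(0.5, 0.2, 0, 0), c(1, 0, 0, 0)))
})

test_that("isotope weight is a Gaussian kernel after TEF shift", {
  cfg <- fw_config()
  # predator exactly one enrichment step above prey
  expect_equal(isotope_weight(3.4, 0.4, 0, 0, cfg), 1)
  # distance equal to the bandwidth
  expect_equal(isotope_weight(3.4 + cfg$isotope_bandwidth, 0.4, 0, 0, cfg),
               exp(-0.5), tolerance = 1e-12)
  expect_equal(exp(-0.5), 0.60653, tolerance = 1e-5)
  # missing values fall back to neutral
  expect_equal(isotope_weight(3.4, 0.4, 0, NA, cfg), 1)
  expect_warning(isotope_weight(NA, 0.4, 0, 0, cfg, warn = TRUE), "neutral")
})

test_that("isotope refinements reproduce their closed-form anchors", {
  expect_equal(refine_algivory(-1.4), 1)
  expect_equal(refine_algivory(2.0), 0)
  expect_equal(refine_algivory(0.3), 0.5)
  expect_equal(refine_algivory(-5), 1)   # clamped

  expect_equal(refine_earthworm_soil(1.2)$soil, 0)
  expect_equal(refine_earthworm_soil(1.2)$litter, 1)
  expect_equal(refine_earthworm_soil(5.5)$soil, 1)
  expect_equal(refine_earthworm_soil(3.35)$soil, 0.5)
  expect_error(refine_earthworm_soil(3, is_earthworm = FALSE), "earthworm")

  expect_equal(refine_omnivore_predation(0, 0, 8), 0)
  expect_equal(refine_omnivore_predation(8, 0, 8), 1)
  expect_equal(refine_omnivore_predation(4, 0, 8), 0.5)
  expect_warning(p <- refine_omnivore_predation(3, 3, 3), "degenerate")
  expect_equal(p, 0.5)
})

test_that("refine_preferences rewrites guild diet budgets from d15N", {
  g <- rbind(
    manual_guild("algivore", 0.01, 1, c(F = 0.5, L = 0.5), d15N = 0.3,
                 d13C = 0),
    manual_guild("worm", 300, 5, c(L = 0.6, S = 0.2), d15N = 3.35,
                 d13C = 1, is_earthworm = TRUE),
    manual_guild("omni", 1, 1, c(B = 0.4, F = 0.4, animal = 0.2),
                 d15N = 1.825, d13C = 0.5, is_omnivore = TRUE))
  b <- refine_preferences(manual_bundle(g))
  rg <- b$guilds
  # d15N 0.3 -> algal fraction 0.5; the rest shares the other half
  expect_equal(rg$pref_A[1], 0.5)
  expect_equal(rg$pref_F[1] + rg$pref_L[1], 0.5)
  expect_equal(rg$pref_F[1], rg$pref_L[1])
  # earthworm at the d15N midpoint splits its detrital mass evenly
  expect_equal(rg$pref_S[2], rg$pref_L[2])
  # refinement order: the algivory step first renormalises the worm's
  # preferences (algal fraction 0 at d15N 3.35), so its detrital mass is 1
  expect_equal(rg$pref_S[2] + rg$pref_L[2], 1)
  # omnivore: web d15N range is [0.3, 3.35]; predation fraction
  p_exp <- (1.825 - 0.3) / (3.35 - 0.3)
  expect_equal(rg$pref_animal[3], p_exp)
  basal <- sum(rg[3, paste0("pref_", c("A", "P", "B", "F", "L", "W", "S"))])
  expect_equal(basal, 1 - p_exp)
})

test_that("omnivory rescaling pins auxiliaries to the main resource", {
  g <- manual_guild("omni", 1, 1, c(F = 0.8, L = 0.3, B = 0.1))
  g0 <- apply_omnivory(g, 0)
  expect_equal(g0$pref_L, 0); expect_equal(g0$pref_B, 0)
  expect_equal(g0$pref_F, 0.8)
  g1 <- apply_omnivory(g, 1)
  expect_equal(g1$pref_L, 0.8); expect_equal(g1$pref_B, 0.8)
  gh <- apply_omnivory(g, 0.5)
  expect_equal(gh$pref_L, 0.4)
  expect_equal(gh$pref_P, 0)  # zero preferences never become links
})

test_that("diet columns are normalised and biomass-dependent", {
  # single-resource consumer -> unit column on that resource
  b <- manual_bundle(manual_guild("det", 1, 1, c(L = 1)))
  W <- build_diet_matrix(b)$W
  expect_equal(unname(W["L", "det"]), 1)

  # two prey identical except biomass 2:1 -> diet shares 2/3, 1/3
  g <- rbind(
    manual_guild("prey_a", 1, 2, c(L = 1)),
    manual_guild("prey_b", 1, 1, c(L = 1)),
    manual_guild("pred", 100, 0.5, c(animal = 1)))
  W2 <- build_diet_matrix(manual_bundle(g))$W
  expect_equal(unname(W2["prey_a", "pred"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(W2["prey_b", "pred"]), 1 / 3, tolerance = 1e-12)
  expect_true(all(abs(colSums(W2) - 1) < 1e-9))
  expect_true(all(diag(W2[colnames(W2), ]) == 0))

  # infeasibility names the guild
  lone <- manual_bundle(manual_guild("pred", 100, 1, c(animal = 1)))
  expect_error(build_diet_matrix(lone), "pred")
})

test_that("diet matrix equals the brute-force oracle on small webs", {
  webs <- list(
    generate_fixture_web("chain3"),
    generate_fixture_web("loop"),
    generate_fixture_web("star"),
    manual_bundle(rbind(
      manual_guild("grazer", 0.01, 0.5, c(A = 0.3, F = 0.7), d15N = 1.0,
                   d13C = 0.2),
      manual_guild("shredder", 5, 2, c(L = 0.8, W = 0.2), protection = 0.6,
                   d15N = 0.5, d13C = 0.1,
                   habitat = c(soil = 0.3, litter = 0.7, ground = 0,
                               aboveground = 0)),
      manual_guild("hunter", 80, 0.8, c(animal = 1), d15N = 4.2, d13C = 0.9,
                   habitat = c(soil = 0.1, litter = 0.6, ground = 0.3,
                               aboveground = 0)),
      manual_guild("mixer", 2, 1.2, c(B = 0.5, animal = 0.5), d15N = 2.4,
                   d13C = 0.4))))
  cfg <- fw_config()
  for (b in webs) {
    W_pkg <- build_diet_matrix(b, cfg)$W
    W_ora <- brute_force_diet_matrix(b, cfg)
    expect_equal(W_pkg, W_ora, tolerance = 1e-12)
  }
})

test_that("entrywise product never exceeds any single factor", {
  b <- as_bundle(generate_site("monsoon", 2))
  b <- refine_preferences(b)
  web <- build_diet_matrix(b, save_factors = TRUE)
  f <- attr(web, "factors")
  for (nm in names(f)) {
    m <- f[[nm]]
    expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 1))
  }
  # the raw animal weight (before normalisation) is bounded by each factor
  raw <- f$preference * f$ppmr * f$habitat * f$protection * f$biomass *
    f$isotope
  for (nm in names(f)) {
    expect_true(all(raw[!is.na(raw)] <= f[[nm]][!is.na(raw)] + 1e-15))
  }
})
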