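# Steady-state flux balance: analytic cases, oracle agreement, invariants.

chain_W <- function() {
  W <- matrix(0, 3, 2, dimnames = list(c("L", "det", "pred"),
                                       c("det", "pred")))
  W["L", "det"] <- 1
  W["det", "pred"] <- 1
  W
}

test_that("single consumer solves to intake = metabolism / efficiency", {
  W <- matrix(c(1, 0), 2, 1, dimnames = list(c("L", "det"), "det"))
  sol <- solve_fluxes(W, c(det = 1.8), c(L = 0.18, det = 0.7))
  expect_equal(unname(sol$F), 10)
  expect_equal(sol$total_flux, 10)
  expect_lt(max(abs(sol$residuals)), 1e-9)
})

test_that("two-level chain matches the hand derivation and the oracle", {
  W <- chain_W()
  X <- c(det = 2, pred = 1)
  e <- c(L = 0.18, det = 0.9, pred = 0.9)
  sol <- solve_fluxes(W, X, e)
  expect_equal(unname(sol$F["pred"]), 1 / 0.9, tolerance = 1e-9)
  expect_equal(unname(sol$F["det"]), (2 + 1 / 0.9) / 0.18, tolerance = 1e-9)
  expect_equal(unname(sol$F["pred"]), 1.11111, tolerance = 1e-5)
  expect_equal(unname(sol$F["det"]), 17.28395, tolerance = 1e-5)
  ora <- fixed_point_fluxes(W, X, e)
  expect_equal(sol$F, ora, tolerance = 1e-10)
  # link fluxes follow L_ij = W_ij F_j
  expect_equal(unname(sol$L["det", "pred"]), unname(sol$F["pred"]))
})

test_that("infeasible webs raise structured errors", {
  # predator column not summing to 1 is rejected outright
  W <- chain_W(); W["det", "pred"] <- 0
  expect_error(solve_fluxes(W, c(det = 1, pred = 1),
                            c(L = 0.2, det = 0.9, pred = 0.9)),
               "sum to 1")
  # cannibalism is rejected
  W2 <- chain_W(); W2["pred", "pred"] <- 0.5; W2["det", "pred"] <- 0.5
  expect_error(solve_fluxes(W2, c(det = 1, pred = 1),
                            c(L = 0.2, det = 0.9, pred = 0.9)),
               "self-predation")
})

test_that("100 seeded random webs agree with the fixed-point oracle", {
  worst <- 0
  for (seed in 1:100) {
    w <- random_feasible_web(seed)
    sol <- solve_fluxes(w$W, w$X, w$e)
    ora <- fixed_point_fluxes(w$W, w$X, w$e)
    rel <- max(abs(sol$F - ora) / pmax(abs(ora), 1e-12))
    worst <- max(worst, rel)
    expect_lt(max(abs(sol$residuals)), 1e-9 * max(w$X))
  }
  expect_lt(worst, 1e-8)
})

test_that("omnivory loops balance to solver tolerance", {
  b <- generate_fixture_web("loop")
  res <- suppressWarnings(run_site(b))
  expect_lt(max(abs(res$solution$residuals)), 1e-9 * max(res$X))
  bal <- check_balance(res$solution, res$web$W, res$X, res$e)
  expect_lt(bal$max_abs, 1e-9 * max(res$X))
  # perturbing one intake breaks the balance on that node
  sol2 <- res$solution
  sol2$F[1] <- sol2$F[1] + 1
  bal2 <- check_balance(sol2, res$web$W, res$X, res$e)
  expect_gt(abs(bal2$residuals[1]), 1e-3)
})

test_that("global conservation, monotonicity and linearity hold", {
  for (seed in c(3, 17, 42)) {
    w <- random_feasible_web(seed)
    sol <- solve_fluxes(w$W, w$X, w$e)
    # sum over consumers of assimilated intake minus predation losses
    # equals total metabolism
    e_bar <- as.numeric(t(w$e[rownames(w$W)]) %*% w$W)
    pred_in <- sum(w$W[colnames(w$W), , drop = FALSE] %*% sol$F)
    expect_equal(sum(e_bar * sol$F) - pred_in, sum(w$X),
                 tolerance = 1e-9 * sum(w$X))
    # increasing one demand never decreases total flux
    X2 <- w$X; X2[1] <- X2[1] * 2
    expect_gte(solve_fluxes(w$W, X2, w$e)$total_flux,
               sol$total_flux - 1e-12)
    # linear scaling
    sol_c <- solve_fluxes(w$W, 3 * w$X, w$e)
    expect_equal(sol_c$F, 3 * sol$F, tolerance = 1e-9)
    expect_equal(sol_c$L, 3 * sol$L, tolerance = 1e-9)
  }
})

test_that("trophic levels solve the diet-weighted recursion", {
  W <- chain_W()
  TL <- trophic_levels(W)
  expect_equal(unname(TL[c("L", "det", "pred")]), c(1, 2, 3))
  # mixed diet: 50% litter + 50% detritivore -> 2.5
  W2 <- matrix(0, 3, 2, dimnames = list(c("L", "det", "omni"),
                                        c("det", "omni")))
  W2["L", "det"] <- 1
  W2["L", "omni"] <- 0.5; W2["det", "omni"] <- 0.5
  expect_equal(unname(trophic_levels(W2)["omni"]), 2.5)
  # loops are handled by the linear solve
  b <- generate_fixture_web("loop")
  web <- build_diet_matrix(b)
  TL3 <- trophic_levels(web$W)
  expect_true(all(is.finite(TL3)))
  expect_equal(unname(TL3["omnivore_a"]), unname(TL3["omnivore_b"]))
  # TL = 1 + 0.5 * 1 + 0.5 * TL  =>  TL = 3 for symmetric mutual predation
  expect_equal(unname(TL3["omnivore_a"]), 3, tolerance = 1e-9)
})
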