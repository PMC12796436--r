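# Steady-state energy-flux balance on a weighted trophic network.
#
# For every consumer j with diet column W_.j, metabolic demand X_j and
# prey-specific assimilation efficiencies e_i, the balance "losses = gains"
# reads
#     (sum_i e_i W_ij) F_j = X_j + sum_k W_jk F_k
# i.e. diet-weighted assimilated intake covers metabolism plus losses to
# predation. This is linear in the intake vector F and solved directly as
#     (diag(e_bar) - Wc) F = X
# where e_bar_j = sum_i e_i W_ij and Wc is the consumer-row submatrix of W
# (entry (j, k) = W_jk, the share of consumer j in consumer k's diet).
# Basal resources are unlimited sources: they appear as rows only.

#' Solve the steady-state energy fluxes of a food web
#'
#' @param W diet matrix: rows = all nodes (resources first, then guilds),
#'   columns = consumer guilds; every column sums to 1. Must carry
#'   dimnames.
#' @param X named metabolic demand per consumer, mW per square metre
#'   (non-negative).
#' @param e named assimilation efficiency per node (prey-defined,
#'   diet-specific), in (0, 1].
#' @return an object of class \code{flux_solution}: \code{F} per-consumer
#'   intake (mW m-2), \code{L} per-link flux matrix (\code{L_ij = W_ij *
#'   F_j}), \code{TL} trophic levels per node, \code{total_flux}
#'   (\code{sum(F)}), \code{residuals} per-consumer balance error.
#' @export
#' @examples
#' W <- matrix(c(1), 1, 1, dimnames = list("L", "det"))
#' W <- rbind(W, det = 0)
#' sol <- solve_fluxes(W, c(det = 1.8), c(L = 0.18, det = 0.7))
#' sol$F  # 10 mW m-2: intake = metabolism / efficiency
solve_fluxes <- function(W, X, e) {
  check_diet_matrix(W)
  consumers <- colnames(W)
  nodes <- rownames(W)
  X <- X[consumers]
  e <- e[nodes]
  if (anyNA(X) || any(X < 0)) {
    stop("metabolic demand X must be a non-negative value per consumer")
  }
  if (anyNA(e) || any(e <= 0) || any(e > 1)) {
    stop("assimilation efficiency must lie in (0, 1] for every node")
  }

  e_bar <- as.numeric(crossprod(e, W))          # diet-weighted efficiency
  Wc <- W[consumers, , drop = FALSE]            # losses to predation
  A <- diag(e_bar, nrow = length(consumers)) - Wc
  F_vec <- tryCatch(solve(A, X),
                    error = function(err) {
                      stop("structurally infeasible web: singular balance ",
                           "system (", conditionMessage(err), ")",
                           call. = FALSE)
                    })
  names(F_vec) <- consumers
  if (any(F_vec < -1e-9 * max(X, 1))) {
    stop("energetically infeasible web: negative intake for ",
         paste(consumers[F_vec < 0], collapse = ", "))
  }
  F_vec <- pmax(F_vec, 0)

  L <- sweep(W, 2, F_vec, `*`)
  sol <- structure(
    list(F = F_vec, L = L, TL = trophic_levels(W),
         total_flux = sum(F_vec), residuals = NULL),
    class = "flux_solution")
  sol$residuals <- check_balance(sol, W, X, e)$residuals
  sol
}

check_diet_matrix <- function(W) {
  if (is.null(rownames(W)) || is.null(colnames(W))) {
    stop("diet matrix must carry node row names and consumer column names")
  }
  if (!all(colnames(W) %in% rownames(W))) {
    stop("every consumer column must also appear as a node row")
  }
  if (any(W < 0)) stop("diet shares must be non-negative")
  cs <- colSums(W)
  if (any(abs(cs - 1) > 1e-9)) {
    stop("diet matrix columns must sum to 1 (offending: ",
         paste(colnames(W)[abs(cs - 1) > 1e-9], collapse = ", "), ")")
  }
  diag_idx <- cbind(match(colnames(W), rownames(W)), seq_len(ncol(W)))
  if (any(W[diag_idx] != 0)) stop("self-predation (W_jj > 0) is not allowed")
  invisible(TRUE)
}

#' Flux-weighted trophic levels
#'
#' Basal resources sit at trophic level 1; every consumer is one level
#' above the diet-share-weighted mean of its prey:
#' \code{TL_j = 1 + sum_i W_ij TL_i}, solved as a linear system so that
#' omnivory loops are handled exactly.
#'
#' @param W diet matrix as in [solve_fluxes()].
#' @return named trophic level per node.
#' @export
trophic_levels <- function(W) {
  check_diet_matrix(W)
  consumers <- colnames(W)
  resources <- setdiff(rownames(W), consumers)
  Wc <- W[consumers, , drop = FALSE]
  Wr <- W[resources, , drop = FALSE]
  # TL_c = 1 + Wr' * 1 + Wc' * TL_c
  rhs <- 1 + as.numeric(colSums(Wr))
  A <- diag(length(consumers)) - t(Wc)
  TL_c <- tryCatch(as.numeric(solve(A, rhs)),
                   error = function(err) {
                     stop("trophic levels undefined: cannibalistic loop ",
                          "with no basal pathway", call. = FALSE)
                   })
  TL <- c(stats::setNames(rep(1, length(resources)), resources),
          stats::setNames(TL_c, consumers))
  TL[rownames(W)]
}

#' Verify the steady-state balance of a flux solution
#'
#' Recomputes, per consumer, assimilated inflow minus predation outflow
#' minus metabolic demand; all residuals are ~0 for a valid solution.
#'
#' @param solution a \code{flux_solution}.
#' @param W,X,e the inputs that produced it (see [solve_fluxes()]).
#' @return list with per-consumer \code{residuals} and \code{max_abs}.
#' @export
check_balance <- function(solution, W, X, e) {
  consumers <- colnames(W)
  F_vec <- solution$F[consumers]
  X <- X[consumers]
  e <- e[rownames(W)]
  inflow <- as.numeric(crossprod(e, W)) * F_vec
  outflow <- as.numeric(W[consumers, , drop = FALSE] %*% F_vec)
  res <- inflow - outflow - X
  names(res) <- consumers
  list(residuals = res, max_abs = max(abs(res)))
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution>", length(x$F), "consumers; total flux",
      sprintf("%.4g mW m-2;", x$total_flux),
      "max |residual|", format(max(abs(x$residuals)), digits = 3), "\n")
  invisible(x)
}
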