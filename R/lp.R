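# Linear programming front ends over the internal dense simplex.
#
# Two problem shapes are needed throughout the package:
#   * lp_box_eq():   optimize over {v : S v = 0, lb <= v <= ub}  (flux space)
#   * lp_polytope(): optimize over {p : G p <= h}, p free        (reduced space)
# Free variables are handled by the standard p = p+ - p- split; the polytopes
# here are bounded so the split introduces no unbounded rays in practice.

lp_status_msg <- function(status) {
  switch(as.character(status),
    "0" = "optimal",
    "1" = "infeasible",
    "2" = "unbounded",
    "3" = "iteration limit reached",
    "unknown")
}

#' Solve a linear program over a bounded inequality polytope
#'
#' Optimizes `c'p` over `{p : G p <= h}` with free variables, using the
#' package's dense two-phase simplex. Intended for the full-dimensional
#' polytopes produced by [build_polytope()] and the synthetic generators.
#'
#' @param G m x D inequality matrix.
#' @param h length-m right-hand side.
#' @param objective length-D objective vector.
#' @param maximize maximize instead of minimize?
#' @param max_iter simplex iteration cap.
#' @return list with `value`, `point` (an optimal vertex), `status` (string).
#' @keywords internal
lp_polytope <- function(G, h, objective, maximize = FALSE, max_iter = NULL) {
  G <- as.matrix(G)
  D <- ncol(G)
  stopifnot(length(objective) == D, length(h) == nrow(G))
  if (is.null(max_iter)) max_iter <- 2000L + 200L * (nrow(G) + 2L * D)
  cc <- if (maximize) -objective else objective
  A <- cbind(G, -G)
  res <- simplex_core(A, as.numeric(h), c(cc, -cc),
                      rep(0L, nrow(G)), as.integer(max_iter))
  if (res$status != 0) {
    return(list(value = NA_real_, point = NULL,
                status = lp_status_msg(res$status)))
  }
  p <- res$x[seq_len(D)] - res$x[D + seq_len(D)]
  val <- sum(objective * p)
  list(value = val, point = p, status = "optimal")
}

#' Solve a linear program over {v : S v = 0, lb <= v <= ub}
#'
#' Flux-space LP used for feasibility (anchor points), flux variability
#' analysis on models, and blocked-reaction detection. Variables are shifted
#' by the (finite) lower bounds so the simplex sees nonnegative variables.
#'
#' @param S M x N stoichiometric matrix.
#' @param lb,ub finite flux bounds.
#' @param objective length-N objective (zero vector for pure feasibility).
#' @param maximize maximize instead of minimize?
#' @return list with `value`, `point` (flux vector), `status`.
#' @keywords internal
lp_box_eq <- function(S, lb, ub, objective = NULL, maximize = FALSE,
                      max_iter = NULL) {
  S <- as.matrix(S)
  N <- ncol(S)
  if (is.null(objective)) objective <- numeric(N)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)), all(lb <= ub))
  if (is.null(max_iter)) max_iter <- 2000L + 200L * (nrow(S) + 2L * N)
  # v = lb + x, 0 <= x <= ub - lb;  S x = -S lb;  x <= ub - lb
  rng <- ub - lb
  A <- rbind(S, diag(N))
  b <- c(-as.numeric(S %*% lb), rng)
  is_eq <- c(rep(1L, nrow(S)), rep(0L, N))
  cc <- if (maximize) -objective else objective
  res <- simplex_core(A, b, cc, is_eq, as.integer(max_iter))
  if (res$status != 0) {
    return(list(value = NA_real_, point = NULL,
                status = lp_status_msg(res$status)))
  }
  v <- lb + res$x
  list(value = sum(objective * v), point = v, status = "optimal")
}
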