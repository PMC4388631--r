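# Shared fixtures and independent oracles, all built in code.

# Linear chain A -> B with import/export: v1 = v2 = v3 at steady state.
toy_chain_model <- function(lb = 0, ub = 1) {
  stoich_model(matrix(c(1, -1, 0,
                        0, 1, -1), 2, 3, byrow = TRUE),
               c("A", "B"), c("R1", "R2", "R3"),
               rep(lb, 3), rep(ub, 3))
}

# Unit box in flux space: zero stoichiometry, no coupling.
toy_box_model <- function(D = 3) {
  stoich_model(matrix(0, 1, D), "M", paste0("R", seq_len(D)),
               rep(0, D), rep(1, D))
}

# Model with two blocked reactions (B is a dead end) and one free exchange.
toy_blocked_model <- function() {
  # R1 imports A, R2 converts A -> B, B has no consumer => v1 = v2 = 0;
  # R3 touches no metabolite and stays free in [0, 1].
  stoich_model(matrix(c(1, -1, 0,
                        0, 1, 0), 2, 3, byrow = TRUE),
               c("A", "B"), c("R1", "R2", "R3"),
               c(0, 0, 0), c(10, 10, 1))
}

# Triangle {p >= 0, p1 + p2 <= 1} as a polytope.
triangle_polytope <- function() {
  flux_polytope(rbind(c(1, 1), -diag(2)), c(1, 0, 0), radius = 2)
}

# Exact LP oracle for {G p <= h}: enumerate all D-subsets of constraints.
lp_brute <- function(G, h, cc, maximize = TRUE) {
  D <- ncol(G)
  m <- nrow(G)
  bestv <- if (maximize) -Inf else Inf
  for (idx in utils::combn(m, D, simplify = FALSE)) {
    M <- G[idx, , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    p <- solve(M, h[idx])
    if (all(G %*% p <= h + 1e-8)) {
      v <- sum(cc * p)
      if ((maximize && v > bestv) || (!maximize && v < bestv)) bestv <- v
    }
  }
  bestv
}

# AR(1) series with innovations sd 1.
ar1_series <- function(T_, rho) {
  as.numeric(stats::filter(rnorm(T_), rho, method = "recursive"))
}

# Is point x inside ellipsoid E (Mahalanobis <= 1 + tol)?
in_ellipsoid <- function(E, x, tol = 1e-8) {
  d <- x - E$center
  sum(d * solve(E$shape, d)) <= 1 + tol
}

# Exact support-function check that E_inner is inside {G p <= h}.
inner_contained <- function(E, G, h, tol = 1e-8) {
  sup <- as.numeric(G %*% E$center) + sqrt(pmax(rowSums((G %*% E$shape) * G), 0))
  all(sup <= h + tol * pmax(1, abs(h)))
}
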