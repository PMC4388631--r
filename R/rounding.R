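# Ellipsoid rounding. An ellipsoid {p : (p - c)' shape^-1 (p - c) <= 1}
# matching the polytope supplies biased hit-and-run directions
# theta = normalize(A u) with A A' = shape, which is equivalent to sampling
# the affinely transformed (rounded) polytope and removes the ill-conditioning
# caused by heterogeneous flux scales. Any A with A A' = shape induces the
# same direction law (the seed vector u is spherically symmetric), so the
# Cholesky factor used here is interchangeable with a symmetric square root.

#' Construct an ellipsoid
#'
#' @param center length-D center.
#' @param shape D x D symmetric positive-definite matrix; the set is
#'   `{p : (p - center)' shape^-1 (p - center) <= 1}`.
#' @return object of class `ellipsoid` with a `transform` factor `A`
#'   satisfying `A A' = shape`.
#' @export
ellipsoid <- function(center, shape) {
  center <- as.numeric(center)
  shape <- as.matrix(shape)
  D <- length(center)
  stopifnot(nrow(shape) == D, ncol(shape) == D)
  scale <- max(abs(shape))
  if (scale <= 0) stop("zero shape matrix", call. = FALSE)
  if (max(abs(shape - t(shape))) > 1e-10 * scale)
    stop("shape matrix is not symmetric", call. = FALSE)
  shape <- (shape + t(shape)) / 2
  A <- tryCatch(t(chol(shape)), error = function(e) NULL)
  if (is.null(A)) {
    eg <- eigen(shape, symmetric = TRUE)
    if (min(eg$values) <= 0)
      stop("shape matrix is not positive definite (min eigenvalue ",
           format(min(eg$values)), ")", call. = FALSE)
    A <- eg$vectors %*% (sqrt(eg$values) * t(eg$vectors))
  }
  structure(list(center = center, shape = shape, transform = A),
            class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  d <- diameter_spectrum(x)
  cat("<ellipsoid> D = ", length(x$center), ", diameters in [",
      format(min(d), digits = 4), ", ", format(max(d), digits = 4), "]\n",
      sep = "")
  invisible(x)
}

#' Log-volume of an ellipsoid
#'
#' `log vol = log V_D + 0.5 log det(shape)` with `V_D` the unit-ball volume.
#'
#' @param E an [ellipsoid()].
#' @return log volume (natural log).
#' @export
ellipsoid_log_volume <- function(E) {
  D <- length(E$center)
  logVD <- (D / 2) * log(pi) - lgamma(D / 2 + 1)
  logVD + 0.5 * as.numeric(determinant(E$shape, logarithm = TRUE)$modulus)
}

#' Diameter spectrum of an ellipsoid
#'
#' Twice the square roots of the shape eigenvalues, sorted increasing — the
#' exact analogue, for an ellipsoid, of the (hard) diameter computation for
#' a general convex body, and the standard display of scale heterogeneity.
#'
#' @param E an [ellipsoid()].
#' @return increasing vector of D diameters.
#' @export
diameter_spectrum <- function(E) {
  stopifnot(inherits(E, "ellipsoid"))
  sort(2 * sqrt(eigen(E$shape, symmetric = TRUE, only.values = TRUE)$values))
}

#' Ellipsoid from principal component analysis of a chain
#'
#' Center = sample mean; shape = connected (mean-subtracted) covariance
#' matrix of the points; the principal axes are its eigenvectors scaled by
#' the root eigenvalues. Even a non-equilibrated pilot chain carries shape
#' information, which is why PCA works well as a refinement step after LP or
#' Lovász rounding.
#'
#' @param chain a [sample_chain()] (or bare matrix) with at least D+1 points.
#' @param ridge regularization added when the covariance is numerically
#'   singular; default `1e-10 * trace / D`, applied with a warning.
#' @return an [ellipsoid()].
#' @export
pca_ellipsoid <- function(chain, ridge = NULL) {
  X <- if (inherits(chain, "sample_chain")) chain$points else as.matrix(chain)
  D <- ncol(X)
  if (nrow(X) < D + 1)
    stop("need at least D+1 = ", D + 1, " points for a covariance estimate, ",
         "got ", nrow(X), call. = FALSE)
  ctr <- colMeans(X)
  shape <- cov(X)
  ev <- eigen(shape, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev, 0) || max(ev) <= 0) {
    if (is.null(ridge)) ridge <- 1e-10 * max(sum(diag(shape)) / D,
                                             .Machine$double.eps)
    warning("covariance numerically singular; ridge-regularized with ",
            format(ridge), call. = FALSE)
    shape <- shape + ridge * diag(D)
  }
  ellipsoid(ctr, shape)
}

#' Ellipsoid from iterative linear programming (variability analysis)
#'
#' Greedy diameter approximation: variability analysis (min/max of every
#' coordinate direction) gives, per direction, the vector joining the
#' minimizing and maximizing vertices; the longest such vector (projected
#' orthogonally to the axes already found) becomes the next ellipsoid axis,
#' and the search continues in the orthogonal complement until D axes are
#' found. The ellipsoid is centered at the midpoint of the first axis'
#' endpoints, with semi-axes equal to half the recovered lengths.
#'
#' Degenerate alternate optima (ties on facets, e.g. every box) would make
#' "the" optimizing vertex ill-defined; a fixed generic secondary objective
#' (a small pull applied identically to the min and the max problem) selects
#' a canonical vertex, so that on an axis-aligned box the recovered axes are
#' exactly the coordinate axes with the side lengths.
#'
#' @param poly a bounded full-dimensional [flux_polytope()].
#' @param tie_break weight of the secondary lexicographic-style objective.
#' @param collapse_tol relative axis length under which the polytope is
#'   declared not full-dimensional.
#' @return an [ellipsoid()].
#' @export
lp_ellipsoid <- function(poly, tie_break = 1e-7, collapse_tol = 1e-9) {
  G <- poly$G; h <- poly$h
  D <- ncol(G)
  # fixed generic pull direction, identical for min and max problems
  d <- 1 + (seq_len(D) - 1) / (7 * D)
  d <- d / sqrt(sum(d^2))
  U <- matrix(0, D, 0)
  semi <- numeric(0)
  center <- NULL
  for (k in seq_len(D)) {
    C <- if (k == 1) diag(D) else
      qr.Q(qr(U), complete = TRUE)[, k:D, drop = FALSE]
    best_len <- -1; best_w <- NULL; best_pair <- NULL
    for (j in seq_len(ncol(C))) {
      cc <- C[, j]
      hi <- lp_polytope(G, h, cc - tie_break * d, maximize = TRUE)
      lo <- lp_polytope(G, h, cc + tie_break * d, maximize = FALSE)
      if (hi$status != "optimal" || lo$status != "optimal")
        stop("LP failure in lp_ellipsoid at axis ", k, call. = FALSE)
      v <- hi$point - lo$point
      w <- if (k == 1) v else v - U %*% crossprod(U, v)
      len <- sqrt(sum(w^2))
      if (len > best_len) {
        best_len <- len; best_w <- as.numeric(w)
        best_pair <- list(hi = hi$point, lo = lo$point)
      }
    }
    ref <- if (length(semi)) 2 * semi[1] else max(1, poly$radius)
    if (best_len <= collapse_tol * ref)
      stop("dimension collapse at axis ", k, " of ", D,
           ": the polytope is not full-dimensional", call. = FALSE)
    U <- cbind(U, best_w / best_len)
    semi <- c(semi, best_len / 2)
    if (k == 1) center <- (best_pair$hi + best_pair$lo) / 2
  }
  ellipsoid(center, U %*% (semi^2 * t(U)))
}

#' Minimal-volume ellipsoid enclosing a half-ellipsoid (deep cut)
#'
#' Given an ellipsoid `E` and the half-space `{p : g'(p - z) <= 0}`, returns
#' the minimal-volume ellipsoid containing their intersection, using the
#' standard deep-cut ellipsoid-method update with cut depth
#' `alpha = (g'c - g'z) / sqrt(g' shape g)`, valid for
#' `alpha` in `[-1/D, 1)`. The volume strictly decreases whenever
#' `alpha > -1/D`; for `alpha <= -1/D` the cut cannot improve on `E`, which
#' is returned unchanged (with a message).
#'
#' @param E an [ellipsoid()].
#' @param cut_normal outward normal `g` of the discarded half-space.
#' @param cut_point point `z` on the cut hyperplane.
#' @return an [ellipsoid()]; attribute `"alpha"` records the cut depth.
#' @export
min_enclosing_halfellipsoid <- function(E, cut_normal, cut_point) {
  stopifnot(inherits(E, "ellipsoid"))
  g <- as.numeric(cut_normal)
  D <- length(E$center)
  stopifnot(length(g) == D, length(cut_point) == D)
  P <- E$shape; ctr <- E$center
  beta <- sum(g * cut_point)
  s <- sqrt(max(sum(g * as.numeric(P %*% g)), 0))
  if (s <= 0) stop("cut normal degenerate for this ellipsoid", call. = FALSE)
  alpha <- (sum(g * ctr) - beta) / s
  if (alpha >= 1)
    stop("empty cut: the half-space does not intersect the ellipsoid ",
         "(alpha = ", format(alpha), ")", call. = FALSE)
  if (alpha <= -1 / D) {
    message("cut too shallow to improve the ellipsoid (alpha = ",
            format(alpha), " <= -1/D); returning it unchanged")
    attr(E, "alpha") <- alpha
    return(E)
  }
  if (D == 1) {
    r <- sqrt(P[1, 1])
    lo <- ctr - r
    hi <- if (g > 0) beta else ctr + r
    if (g < 0) lo <- beta
    out <- ellipsoid((lo + hi) / 2, matrix(((hi - lo) / 2)^2, 1, 1))
    attr(out, "alpha") <- alpha
    return(out)
  }
  b <- as.numeric(P %*% g) / s
  ctr_new <- ctr - ((1 + D * alpha) / (D + 1)) * b
  P_new <- (D^2 * (1 - alpha^2) / (D^2 - 1)) *
    (P - (2 * (1 + D * alpha) / ((D + 1) * (1 + alpha))) * tcrossprod(b))
  out <- ellipsoid(ctr_new, P_new)
  attr(out, "alpha") <- alpha
  out
}

#' Weak Loewner-John pair by the Lovász ellipsoid method
#'
#' Starting from the ball enclosing the bounding box (from per-coordinate
#' variability analysis), repeatedly: if the ellipsoid center lies outside
#' the polytope, cut with the most-violated inequality (a hyperplane
#' separating the center from the polytope); otherwise shrink the ellipsoid
#' about its center by `shrink` and test whether the shrunken copy fits
#' inside the polytope — if some constraint is violated, cut through it.
#' Terminates when the shrunken ellipsoid is contained, returning the pair
#' `E_inner`, `E` with `E_inner` ⊆ P ⊆ `E`. Every cut goes through the
#' violated constraint's own hyperplane, so `E` always contains P and every
#' effective cut strictly reduces the volume.
#'
#' The inner-containment test is, by default, the exact per-constraint
#' support-function evaluation `g'c + shrink * sqrt(g' shape g) <= h`;
#' `check = "axis"` instead spot-checks only the 2D axis endpoints of the
#' shrunken ellipsoid (the historical variant: cheaper per iteration, weaker
#' per-cut progress, kept for fidelity comparisons).
#'
#' @param poly a bounded full-dimensional [flux_polytope()].
#' @param shrink shrink factor; default `1 / D^(3/2)` (0.5 when D = 1, where
#'   the canonical factor degenerates to 1).
#' @param max_iter iteration cap; default `50 * D^2`.
#' @param check inner-containment test: `"support"` (exact) or `"axis"`.
#' @param tol containment slack, relative to the polytope scale.
#' @return list with `E` (outer), `E_inner`, `iterations`, `cuts`,
#'   `log_volumes` (outer log-volume after each cut).
#' @export
lovasz_ellipsoid <- function(poly, shrink = NULL, max_iter = NULL,
                             check = c("support", "axis"), tol = 1e-9) {
  check <- match.arg(check)
  G <- poly$G; h <- poly$h
  D <- ncol(G)
  if (is.null(shrink)) shrink <- if (D == 1) 0.5 else D^(-1.5)
  stopifnot(shrink > 0, shrink < 1)
  if (is.null(max_iter)) max_iter <- 50 * D^2

  fv <- fva(poly)
  mn <- fv$ranges$min; mx <- fv$ranges$max
  ctr0 <- (mn + mx) / 2
  R0 <- 0.5 * sqrt(sum((mx - mn)^2)) * 1.01
  E <- ellipsoid(ctr0, R0^2 * diag(D))
  scale <- max(1, R0)
  gnorm <- sqrt(rowSums(G^2))

  cuts <- 0L
  log_volumes <- ellipsoid_log_volume(E)
  for (iter in seq_len(max_iter)) {
    ctr <- E$center; P <- E$shape
    viol <- as.numeric(G %*% ctr) - h
    if (max(viol) > tol * scale) {
      i <- which.max(viol / gnorm)     # most-violated separating hyperplane
    } else {
      sup <- sqrt(pmax(rowSums((G %*% P) * G), 0))   # sqrt(g' P g) per row
      slack <- h - as.numeric(G %*% ctr)
      if (check == "support") {
        excess <- shrink * sup - slack
        if (all(excess <= tol * scale * gnorm)) {
          return(list(E = E, E_inner = ellipsoid(ctr, shrink^2 * P),
                      iterations = iter, cuts = cuts,
                      log_volumes = log_volumes))
        }
        i <- which.max(excess / gnorm)
      } else {
        eg <- eigen(P, symmetric = TRUE)
        A <- t(shrink * sqrt(pmax(eg$values, 0)) * t(eg$vectors)) # D x D axes
        ends <- rbind(sweep(t(A), 2, ctr, "+"), sweep(-t(A), 2, ctr, "+"))
        vmat <- sweep(ends %*% t(G), 2, h, "-")       # (2D) x m violations
        if (max(vmat) <= tol * scale) {
          return(list(E = E, E_inner = ellipsoid(ctr, shrink^2 * P),
                      iterations = iter, cuts = cuts,
                      log_volumes = log_volumes))
        }
        i <- which(vmat == max(vmat), arr.ind = TRUE)[1, 2]
      }
    }
    g <- G[i, ]
    z <- ctr + ((h[i] - sum(g * ctr)) / sum(g^2)) * g  # point on the facet
    E <- min_enclosing_halfellipsoid(E, g, z)
    cuts <- cuts + 1L
    log_volumes <- c(log_volumes, ellipsoid_log_volume(E))
  }
  stop("Lovász ellipsoid method did not converge in ", max_iter,
       " iterations; current outer log-volume ",
       format(tail(log_volumes, 1)), " after ", cuts, " cuts",
       call. = FALSE)
}
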