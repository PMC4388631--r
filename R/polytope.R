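# Full-dimensional representation of the steady-state polytope and the
# geometric primitives the samplers need (FVA, membership, chords).
#
# All sampling happens in the D-dimensional null-space coordinates p; a flux
# vector is reconstructed as v = anchor + basis %*% p. Without this reduction
# the hit-and-run chord would collapse to a point for almost every direction
# and the dynamics would freeze.

#' Construct a full-dimensional polytope {p : G p <= h}
#'
#' Low-level constructor used by [build_polytope()] and the synthetic shape
#' generators. `anchor` and `basis` define the affine map back to flux space;
#' for directly constructed shapes they default to the identity embedding.
#'
#' @param G m x D inequality matrix.
#' @param h length-m right-hand side (finite: the set must be bounded).
#' @param anchor length-N feasible flux vector (defaults to the origin of
#'   p-space).
#' @param basis N x D matrix with orthonormal columns spanning the flux-space
#'   directions of the polytope (defaults to the identity).
#' @param labels reaction / coordinate labels.
#' @param radius a finite bound on `max ||p||` over the polytope, used to
#'   scale chord and membership tolerances.
#' @param model optional originating [stoich_model()].
#' @return object of class `flux_polytope`.
#' @export
flux_polytope <- function(G, h, anchor = NULL, basis = NULL, labels = NULL,
                          radius = NULL, model = NULL) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  h <- as.numeric(h)
  D <- ncol(G)
  if (D < 1) stop("polytope dimension must be >= 1", call. = FALSE)
  if (length(h) != nrow(G)) stop("G/h dimension mismatch", call. = FALSE)
  if (!all(is.finite(G)) || !all(is.finite(h)))
    stop("G and h must be finite (bounded polytopes only)", call. = FALSE)
  if (is.null(basis)) basis <- diag(D)
  if (is.null(anchor)) anchor <- numeric(nrow(basis))
  if (is.null(labels)) labels <- paste0("x", seq_len(nrow(basis)))
  if (is.null(radius)) {
    # crude but valid for shapes built from explicit boxes; callers that know
    # better pass their own bound
    radius <- sqrt(D) * max(abs(h), 1)
  }
  structure(list(G = G, h = h, anchor = as.numeric(anchor),
                 basis = as.matrix(basis), labels = labels,
                 radius = radius, model = model),
            class = "flux_polytope")
}

#' @export
print.flux_polytope <- function(x, ...) {
  cat("<flux_polytope> D = ", ncol(x$G), ", ", nrow(x$G),
      " inequality rows, flux space N = ", nrow(x$basis), "\n", sep = "")
  invisible(x)
}

#' @export
dim.flux_polytope <- function(x) c(nrow(x$G), ncol(x$G))

#' Map full-dimensional points back to flux space
#'
#' Applies `v = anchor + basis p` rowwise.
#'
#' @param poly a [flux_polytope()].
#' @param points D-vector or T x D matrix of p-space points.
#' @return flux-space vector or T x N matrix with reaction labels.
#' @export
flux_map <- function(poly, points) {
  if (is.null(dim(points))) {
    v <- poly$anchor + as.numeric(poly$basis %*% points)
    names(v) <- poly$labels
    return(v)
  }
  V <- sweep(points %*% t(poly$basis), 2, poly$anchor, "+")
  colnames(V) <- poly$labels
  V
}

#' Build the full-dimensional steady-state polytope of a model
#'
#' The feasible set `{v : S v = 0, lb <= v <= ub}` is re-parameterized on the
#' null space of `S`: an anchor point is found by linear programming (and
#' projected onto the null space so that `||S anchor||` is at machine
#' precision), an orthonormal null-space basis `B` comes from the singular
#' value decomposition (numerical rank with threshold
#' `max(M, N) * eps * sigma_max`), and each finite flux bound contributes one
#' inequality row: `lb <= anchor + B p <= ub`.
#'
#' @param model a validated [stoich_model()].
#' @param equality_tol tolerance for `||S v||_inf` on reconstructed fluxes.
#' @return a [flux_polytope()] with `D = N - rank(S)` coordinates.
#' @export
build_polytope <- function(model,
                           equality_tol = .fluxhr_defaults$equality_tol) {
  stopifnot(inherits(model, "stoich_model"))
  S <- model$S
  N <- ncol(S)
  lb <- model$lower_bounds
  ub <- model$upper_bounds

  sv <- svd(S, nu = 0, nv = N)
  tol_rank <- max(dim(S)) * .Machine$double.eps *
    (if (length(sv$d)) max(sv$d) else 0)
  r <- sum(sv$d > tol_rank)
  D <- N - r
  if (D < 1)
    stop("the constraint set has dimension 0: S has full column rank, ",
         "the model is (at most) a single point", call. = FALSE)
  B <- sv$v[, (r + 1):N, drop = FALSE]          # orthonormal null-space basis

  feas <- lp_box_eq(S, lb, ub)
  if (feas$status != "infeasible" && feas$status != "optimal")
    stop("LP failure while searching a feasible point: ", feas$status,
         call. = FALSE)
  if (feas$status == "infeasible")
    stop("infeasible model: no flux vector satisfies S v = 0 within the ",
         "bounds (phase-1 simplex certifies positive infeasibility)",
         call. = FALSE)
  anchor <- feas$point
  if (r > 0) {                                  # exact null-space projection
    Vr <- sv$v[, seq_len(r), drop = FALSE]
    anchor <- anchor - as.numeric(Vr %*% (t(Vr) %*% anchor))
  }
  resid <- max(abs(S %*% anchor))
  if (resid > equality_tol)
    stop("anchor violates S v = 0 beyond tolerance: ", resid, call. = FALSE)

  # inequality rows from finite bounds; rows whose normal vanishes on the
  # null space constrain a flux that is constant over the polytope
  rows <- list(); rhs <- numeric(0); lab <- character(0)
  for (i in seq_len(N)) {
    g <- B[i, ]
    if (sqrt(sum(g^2)) <= 1e-12) {
      if (anchor[i] > ub[i] + 1e-7 || anchor[i] < lb[i] - 1e-7)
        stop("constant flux ", model$reaction_ids[i],
             " falls outside its bounds", call. = FALSE)
      next
    }
    if (is.finite(ub[i])) {
      rows[[length(rows) + 1]] <- g
      rhs <- c(rhs, ub[i] - anchor[i])
      lab <- c(lab, paste0(model$reaction_ids[i], "<=ub"))
    }
    if (is.finite(lb[i])) {
      rows[[length(rows) + 1]] <- -g
      rhs <- c(rhs, anchor[i] - lb[i])
      lab <- c(lab, paste0(model$reaction_ids[i], ">=lb"))
    }
  }
  G <- do.call(rbind, rows)
  rownames(G) <- lab
  radius <- sqrt(sum((ub - lb)^2))   # ||p|| = ||v - anchor|| <= box diagonal
  flux_polytope(G, rhs, anchor = anchor, basis = B,
                labels = model$reaction_ids, radius = radius, model = model)
}

#' Flux variability analysis over a polytope
#'
#' Minimizes and maximizes each variable by linear programming: each
#' full-dimensional coordinate (`space = "coordinate"`), or each reaction
#' flux through the affine map (`space = "flux"`).
#'
#' @param poly a [flux_polytope()].
#' @param space optimize p-space coordinates or reaction fluxes.
#' @return object of class `fva_result`: data frame `ranges` (min, max) plus
#'   matrices `argmin`, `argmax` holding the optimizing vertices (p-space
#'   coordinates, one row per variable).
#' @export
fva <- function(poly, space = c("coordinate", "flux")) {
  space <- match.arg(space)
  D <- ncol(poly$G)
  objs <- if (space == "coordinate") diag(D) else poly$basis
  nv <- nrow(objs)
  mn <- mx <- numeric(nv)
  argmin <- argmax <- matrix(NA_real_, nv, D)
  for (i in seq_len(nv)) {
    lo <- lp_polytope(poly$G, poly$h, objs[i, ], maximize = FALSE)
    hi <- lp_polytope(poly$G, poly$h, objs[i, ], maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("LP failure in FVA at variable ", i, ": ",
           lo$status, " / ", hi$status, call. = FALSE)
    mn[i] <- lo$value; mx[i] <- hi$value
    argmin[i, ] <- lo$point; argmax[i, ] <- hi$point
  }
  if (space == "flux") {
    off <- poly$anchor[seq_len(nv)]
    mn <- mn + off; mx <- mx + off
  }
  vars <- if (space == "coordinate") paste0("p", seq_len(D)) else poly$labels
  structure(list(ranges = data.frame(variable = vars, min = mn, max = mx,
                                     stringsAsFactors = FALSE),
                 argmin = argmin, argmax = argmax, space = space),
            class = "fva_result")
}

#' @export
print.fva_result <- function(x, ...) {
  cat("<fva_result> ", nrow(x$ranges), " variables (", x$space, " space)\n",
      sep = "")
  print(utils::head(x$ranges, 10))
  if (nrow(x$ranges) > 10) cat("...\n")
  invisible(x)
}

#' Flux variability analysis of a model (flux space)
#'
#' Per-reaction `min v_i` / `max v_i` over `{S v = 0, lb <= v <= ub}` by
#' direct flux-space linear programs (no null-space reduction needed).
#'
#' @param model a [stoich_model()].
#' @return data frame with columns `reaction`, `min`, `max`.
#' @export
fva_model <- function(model) {
  stopifnot(inherits(model, "stoich_model"))
  N <- ncol(model$S)
  mn <- mx <- numeric(N)
  for (i in seq_len(N)) {
    e <- numeric(N); e[i] <- 1
    lo <- lp_box_eq(model$S, model$lower_bounds, model$upper_bounds, e)
    hi <- lp_box_eq(model$S, model$lower_bounds, model$upper_bounds, e,
                    maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("LP failure in FVA for reaction ", model$reaction_ids[i],
           ": ", lo$status, " / ", hi$status, call. = FALSE)
    mn[i] <- lo$value; mx[i] <- hi$value
  }
  data.frame(reaction = model$reaction_ids, min = mn, max = mx,
             stringsAsFactors = FALSE)
}

#' Remove blocked reactions from a model
#'
#' A reaction is blocked when flux variability analysis pins its flux to zero
#' everywhere on the polytope (`max - min <= tol` and `|max| <= tol`).
#' Blocked reactions are deleted, as are metabolites left with no
#' participating reaction. Idempotent.
#'
#' @param model a [stoich_model()].
#' @param tol blocked-reaction tolerance (flux units).
#' @return the pruned [stoich_model()]; attribute `"removed"` lists the
#'   deleted reaction ids.
#' @export
remove_blocked <- function(model, tol = .fluxhr_defaults$blocked_tol) {
  stopifnot(inherits(model, "stoich_model"))
  rng <- fva_model(model)
  blocked <- (rng$max - rng$min) <= tol & abs(rng$max) <= tol &
    abs(rng$min) <= tol
  keep <- !blocked
  if (!any(keep))
    stop("all reactions are blocked; the polytope is the origin",
         call. = FALSE)
  S2 <- model$S[, keep, drop = FALSE]
  met_keep <- rowSums(S2 != 0) > 0
  out <- stoich_model(S2[met_keep, , drop = FALSE],
                      model$metabolite_ids[met_keep],
                      model$reaction_ids[keep],
                      model$lower_bounds[keep], model$upper_bounds[keep])
  attr(out, "removed") <- model$reaction_ids[blocked]
  out
}

#' Strictly interior point of a polytope
#'
#' Midpoint of two distinct vertices obtained by maximizing a random linear
#' objective and its negation; retries with fresh objectives when the
#' midpoint sits within boundary tolerance of a facet, then falls back to
#' averaging all FVA vertices.
#'
#' @param poly a [flux_polytope()].
#' @param max_tries retry cap for random objectives.
#' @param boundary_tol strictness margin, relative to the polytope radius.
#' @return length-D interior point.
#' @export
find_interior_point <- function(poly, max_tries = 10,
                                boundary_tol = .fluxhr_defaults$boundary_tol) {
  D <- ncol(poly$G)
  tol <- boundary_tol * max(1, poly$radius)
  for (k in seq_len(max_tries)) {
    obj <- rnorm(D)
    v1 <- lp_polytope(poly$G, poly$h, obj, maximize = TRUE)
    v2 <- lp_polytope(poly$G, poly$h, obj, maximize = FALSE)
    if (v1$status != "optimal" || v2$status != "optimal") next
    if (sqrt(sum((v1$point - v2$point)^2)) <= tol) next
    mid <- (v1$point + v2$point) / 2
    if (all(poly$h - poly$G %*% mid > tol)) return(mid)
  }
  # fall back: average of all FVA vertices (centroid-like, interior for any
  # full-dimensional polytope unless degeneracy is extreme)
  fv <- fva(poly)
  mid <- colMeans(rbind(fv$argmin, fv$argmax))
  if (all(poly$h - poly$G %*% mid > tol)) return(mid)
  stop("could not find a strictly interior point; the polytope appears to ",
       "have empty interior (dimension likely 0)", call. = FALSE)
}

#' Membership test
#'
#' `TRUE` iff `G p <= h + tol` elementwise.
#'
#' @param poly a [flux_polytope()].
#' @param p length-D point.
#' @param tol slack tolerance (absolute).
#' @return logical scalar.
#' @export
contains <- function(poly, p,
                     tol = .fluxhr_defaults$boundary_tol * max(1, poly$radius)) {
  if (length(p) != ncol(poly$G))
    stop("point has dimension ", length(p), ", polytope has dimension ",
         ncol(poly$G), call. = FALSE)
  all(poly$G %*% p <= poly$h + tol)
}

#' Chord of a polytope through an interior point
#'
#' For a unit direction `theta`, returns the interval `[lambda_min,
#' lambda_max]` such that `x + lambda theta` stays in the polytope: per
#' inequality row the ratio bound `(h_i - g_i x) / (g_i theta)` caps lambda
#' on one side, and the tightest cap on each side wins. When the chord width
#' falls below the floor the result is flagged degenerate so a sampler can
#' resample the direction instead of freezing.
#'
#' @param poly a [flux_polytope()].
#' @param x interior point.
#' @param theta unit direction.
#' @param chord_floor minimal usable chord width (absolute; defaults to
#'   `1e-12` of the bounding-box-diagonal scale).
#' @return list with `lambda_min < 0 < lambda_max` and flag `degenerate`.
#' @export
chord <- function(poly, x, theta, chord_floor = NULL) {
  if (is.null(chord_floor))
    chord_floor <- .fluxhr_defaults$chord_floor * 2 * max(1, poly$radius)
  s <- as.numeric(poly$h - poly$G %*% x)
  t <- as.numeric(poly$G %*% theta)
  lmax <- suppressWarnings(min(s[t > 0] / t[t > 0]))
  lmin <- suppressWarnings(max(s[t < 0] / t[t < 0]))
  if (!is.finite(lmin) || !is.finite(lmax))
    stop("unbounded chord: polytope not bounded in this direction",
         call. = FALSE)
  list(lambda_min = lmin, lambda_max = lmax,
       degenerate = (lmax - lmin) <= chord_floor)
}
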