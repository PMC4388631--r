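# Samplers: hit-and-run (plain and ellipsoid-biased), the non-Markovian
# artificially-centered baseline, and the i.i.d. rejection oracle used to
# certify uniformity at low dimension.

#' Uniform random unit direction(s)
#'
#' Marsaglia construction: D independent standard normals, normalized to
#' unit Euclidean length — uniform on the (D-1)-sphere.
#'
#' @param D dimension (>= 1).
#' @param n number of directions.
#' @return a length-D unit vector, or an n x D matrix of unit rows.
#' @export
random_direction <- function(D, n = 1) {
  stopifnot(D >= 1, n >= 1)
  M <- matrix(rnorm(n * D), n, D)
  nrm <- sqrt(rowSums(M^2))
  while (any(nrm == 0)) {            # probability-zero guard
    i <- which(nrm == 0)
    M[i, ] <- rnorm(length(i) * D)
    nrm[i] <- sqrt(rowSums(M[i, , drop = FALSE]^2))
  }
  M <- M / nrm
  if (n == 1) as.numeric(M) else M
}

#' Hit-and-run sampling of a polytope
#'
#' The chain iterates: draw `theta = normalize(A u)` with `u` uniform on the
#' unit sphere (`A = identity` for plain hit-and-run, `A = transform` of the
#' matching ellipsoid for the rounded variant); intersect the line
#' `x + lambda theta` with the polytope to get the chord
#' `[lambda_min, lambda_max]`; draw `lambda*` uniformly on the chord
#' (endpoints nudged inward by the chord floor so iterates stay strictly
#' interior); move. Every `thin`-th state is recorded. For any fixed
#' invertible `A` the chain is Markovian with the uniform law on the
#' polytope invariant; biasing by the matching ellipsoid is equivalent to
#' running plain hit-and-run on the affinely rounded body.
#'
#' Degenerate chords (width below the floor) cause the direction to be
#' resampled from the same RNG stream; exceeding `resample_cap` consecutive
#' resamples signals frozen dynamics (a symptom of a polytope that is not
#' full-dimensional).
#'
#' @param poly a [flux_polytope()].
#' @param n number of recorded points.
#' @param seed integer seed; the chain is a deterministic function of
#'   (polytope, start, n, thin, ellipsoid, seed).
#' @param start interior starting point; default [find_interior_point()]
#'   (drawn inside the same seeded stream).
#' @param thin record every `thin`-th step (recorded, not hidden: total
#'   Monte Carlo steps = `n * thin`).
#' @param ellipsoid optional matching [ellipsoid()] whose `transform` biases
#'   the directions.
#' @param chord_floor minimal usable chord width; default `1e-12` of the
#'   bounding-box-diagonal scale.
#' @param resample_cap consecutive degenerate-chord resamples tolerated.
#' @return a [sample_chain()] with `sampler_id` `"hr"` or `"hr_rounded"`.
#' @export
hr_sample <- function(poly, n, seed, start = NULL, thin = 1L,
                      ellipsoid = NULL, chord_floor = NULL,
                      resample_cap = .fluxhr_defaults$resample_cap) {
  stopifnot(inherits(poly, "flux_polytope"), n >= 1, thin >= 1)
  set.seed(seed)
  if (is.null(start)) start <- find_interior_point(poly)
  D <- ncol(poly$G)
  stopifnot(length(start) == D)
  if (!contains(poly, start))
    stop("starting point is not inside the polytope", call. = FALSE)
  if (is.null(chord_floor))
    chord_floor <- .fluxhr_defaults$chord_floor * 2 * max(1, poly$radius)
  use_bias <- !is.null(ellipsoid)
  A <- if (use_bias) ellipsoid$transform else diag(D)
  if (use_bias) stopifnot(nrow(A) == D, ncol(A) == D)
  res <- hr_chain_core(poly$G, poly$h, start, A, use_bias,
                       as.integer(n), as.integer(thin),
                       chord_floor, as.integer(resample_cap))
  if (res$status != 0)
    stop("frozen dynamics: direction resample cap (", resample_cap,
         ") exceeded after ", res$stored, " stored points; the polytope ",
         "representation is likely not full-dimensional", call. = FALSE)
  sample_chain(res$points,
               sampler_id = if (use_bias) "hr_rounded" else "hr",
               seed = seed, thinning = thin,
               labels = paste0("p", seq_len(D)),
               ellipsoid_ref = if (use_bias) "matching-ellipsoid" else NULL,
               resamples = res$resamples)
}

#' Artificially-centered hit-and-run (baseline, no uniformity guarantee)
#'
#' Non-Markovian heuristic: directions join a uniformly chosen previously
#' sampled point to the running center of all previous points, which adapts
#' to elongated bodies without any rounding step — but the adaptation breaks
#' the Markov property, so convergence to the uniform law is not guaranteed.
#' Provided strictly for comparison studies.
#'
#' @inheritParams hr_sample
#' @param warmup number of plain hit-and-run steps seeding the direction
#'   pool; must be at least D+1.
#' @return a [sample_chain()] with `sampler_id = "achr"`.
#' @export
achr_sample <- function(poly, n, seed, start = NULL, thin = 1L,
                        warmup = NULL, chord_floor = NULL,
                        resample_cap = .fluxhr_defaults$resample_cap) {
  stopifnot(inherits(poly, "flux_polytope"), n >= 1, thin >= 1)
  set.seed(seed)
  D <- ncol(poly$G)
  if (is.null(warmup)) warmup <- D + 1L
  if (warmup < D + 1)
    stop("warmup must be at least D+1 = ", D + 1, call. = FALSE)
  if (is.null(start)) start <- find_interior_point(poly)
  if (!contains(poly, start))
    stop("starting point is not inside the polytope", call. = FALSE)
  if (is.null(chord_floor))
    chord_floor <- .fluxhr_defaults$chord_floor * 2 * max(1, poly$radius)
  res <- achr_chain_core(poly$G, poly$h, start, as.integer(n),
                         as.integer(thin), as.integer(warmup),
                         chord_floor, as.integer(resample_cap))
  if (res$status != 0)
    stop("frozen dynamics in ACHR after ", res$stored, " stored points",
         call. = FALSE)
  sample_chain(res$points, sampler_id = "achr", seed = seed,
               thinning = thin, labels = paste0("p", seq_len(D)),
               resamples = res$resamples)
}

#' Rejection sampling (exact uniformity oracle, low dimension only)
#'
#' Proposes uniform points in the bounding box (from variability analysis)
#' and keeps those inside the polytope: i.i.d. exactly uniform samples,
#' feasible only while the volume ratio is workable — hence the `D <= 10`
#' guard and the acceptance-rate floor.
#'
#' @inheritParams hr_sample
#' @param min_acceptance abort when the running acceptance rate (after at
#'   least 10^5 proposals) drops below this.
#' @return a [sample_chain()] with `sampler_id = "rejection"`; attribute
#'   `"acceptance_rate"` records accepted / proposed.
#' @export
rejection_sample <- function(poly, n, seed, min_acceptance = 1e-6) {
  stopifnot(inherits(poly, "flux_polytope"), n >= 1)
  D <- ncol(poly$G)
  if (D > 10)
    stop("rejection sampling is guarded to D <= 10 (got D = ", D, ")",
         call. = FALSE)
  set.seed(seed)
  fv <- fva(poly)
  lo <- fv$ranges$min; hi <- fv$ranges$max
  kept <- matrix(numeric(0), 0, D)
  proposed <- 0
  accepted <- 0
  Gt <- t(poly$G)
  while (accepted < n) {
    B <- max(10000L, n)
    X <- matrix(runif(B * D), B, D)
    X <- sweep(sweep(X, 2, hi - lo, "*"), 2, lo, "+")
    ok <- rowSums(X %*% Gt > rep(poly$h, each = B)) == 0
    proposed <- proposed + B
    acc <- X[ok, , drop = FALSE]
    accepted <- accepted + nrow(acc)
    kept <- rbind(kept, acc)
    if (proposed >= 1e5 && accepted / proposed < min_acceptance)
      stop("rejection sampling impractical: acceptance rate ",
           format(accepted / proposed), " < ", min_acceptance, call. = FALSE)
  }
  out <- sample_chain(kept[seq_len(n), , drop = FALSE], "rejection",
                      seed = seed, thinning = 1L,
                      labels = paste0("p", seq_len(D)))
  attr(out, "acceptance_rate") <- accepted / proposed
  out
}
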