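# Seeded synthetic polytopes with analytically known marginals, and the
# controlled rounding-comparison experiment built on them.

#' Unit hypercube [0, 1]^D as a polytope
#'
#' @param D dimension.
#' @return a [flux_polytope()] with 2D inequality rows and identity flux map.
#' @export
make_hypercube <- function(D) {
  stopifnot(D >= 1)
  G <- rbind(diag(D), -diag(D))
  h <- c(rep(1, D), rep(0, D))
  poly <- flux_polytope(G, h, radius = sqrt(D))
  attr(poly, "flat_ranges") <- cbind(rep(0, D), rep(1, D))
  poly
}

#' Axis-aligned (optionally rotated) hyper-rectangle
#'
#' Box `[0, L_1] x ... x [0, L_D]`. By default the side lengths are spaced
#' geometrically across `10^log_range`, emulating the many-decade spread of
#' flux scales that makes unrounded hit-and-run fail. With `rotate = TRUE`
#' the box is tilted by a seeded random orthogonal matrix (diameters of a
#' tilted box are no longer readable off the per-coordinate ranges).
#'
#' @param D dimension.
#' @param lengths explicit positive side lengths (overrides `log_range`).
#' @param log_range `c(lo, hi)`: sides are `10^seq(lo, hi, length.out = D)`.
#' @param rotate tilt by a random orthogonal matrix?
#' @param seed seed for the rotation.
#' @return a [flux_polytope()]; attribute `"flat_ranges"` holds the exact
#'   per-coordinate marginal ranges when the box is axis-aligned.
#' @export
make_hyperrectangle <- function(D, lengths = NULL, log_range = c(-2, 5),
                                rotate = FALSE, seed = 1) {
  stopifnot(D >= 1)
  if (is.null(lengths)) {
    lengths <- if (D == 1) 10^mean(log_range) else
      10^seq(log_range[1], log_range[2], length.out = D)
  }
  stopifnot(length(lengths) == D, all(lengths > 0))
  if (!rotate) {
    G <- rbind(diag(D), -diag(D))
    h <- c(lengths, rep(0, D))
    poly <- flux_polytope(G, h, radius = sqrt(sum(lengths^2)))
    attr(poly, "flat_ranges") <- cbind(rep(0, D), lengths)
    attr(poly, "lengths") <- lengths
    return(poly)
  }
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(D * D), D, D)))
  # box in z = Q'p coordinates: 0 <= Q'p <= L
  G <- rbind(t(Q), -t(Q))
  h <- c(lengths, rep(0, D))
  poly <- flux_polytope(G, h, radius = sqrt(sum(lengths^2)))
  attr(poly, "lengths") <- lengths
  attr(poly, "rotation") <- Q
  poly
}

#' Seeded random bounded polytope
#'
#' Intersects `n_constraints` half-spaces with standard-normal (normalized)
#' normals and offsets drawn from Uniform(0.5, 1.5) — the origin is always
#' interior — and regenerates until the result is bounded (checked by
#' variability analysis). Deterministic given the seed.
#'
#' @param D dimension.
#' @param n_constraints at least D+1 half-spaces.
#' @param seed integer seed.
#' @param max_tries regeneration attempts before giving up.
#' @return a [flux_polytope()].
#' @export
make_random_polytope <- function(D, n_constraints, seed, max_tries = 50) {
  stopifnot(D >= 1, n_constraints >= D + 1)
  set.seed(seed)
  for (k in seq_len(max_tries)) {
    N <- matrix(rnorm(n_constraints * D), n_constraints, D)
    N <- N / sqrt(rowSums(N^2))
    h <- runif(n_constraints, 0.5, 1.5)
    poly <- flux_polytope(N, h, radius = 2 * sqrt(D) * max(h))
    bounded <- tryCatch({
      fv <- fva(poly)
      all(is.finite(fv$ranges$min), is.finite(fv$ranges$max))
    }, error = function(e) FALSE)
    if (bounded) {
      # tight radius bound now that the box is known
      fv <- fva(poly)
      poly$radius <- sqrt(sum(pmax(abs(fv$ranges$min),
                                   abs(fv$ranges$max))^2))
      return(poly)
    }
  }
  stop("could not generate a bounded polytope in ", max_tries,
       " attempts (D = ", D, ", m = ", n_constraints, ")", call. = FALSE)
}

#' Benchmark specification
#'
#' @param shape `"hypercube"`, `"hyperrectangle"` or `"random_polytope"`.
#' @param D dimension.
#' @param axis_lengths optional explicit side lengths (hyperrectangle).
#' @param log_range geometric side-length range (hyperrectangle).
#' @param n_constraints constraint count (random polytope).
#' @param step_budget Monte Carlo steps per sampler.
#' @param samplers subset of `"hr"`, `"hr_rounded"`, `"achr"`.
#' @param rounding rounding method for `"hr_rounded"`: `"lp"`, `"lem"`,
#'   `"pca"`, `"lp+pca"`, `"lem+pca"`.
#' @param bins KLD histogram bins.
#' @param seed integer seed.
#' @return list of class `benchmark_spec`.
#' @export
benchmark_spec <- function(shape = c("hypercube", "hyperrectangle",
                                     "random_polytope"),
                           D, axis_lengths = NULL, log_range = c(-2, 5),
                           n_constraints = NULL, step_budget = 1e5,
                           samplers = c("hr", "hr_rounded"),
                           rounding = "lp", bins = 100, seed = 1) {
  shape <- match.arg(shape)
  stopifnot(D >= 1, step_budget >= D)
  if (!length(samplers)) stop("empty sampler list", call. = FALSE)
  samplers <- match.arg(samplers, c("hr", "hr_rounded", "achr"),
                        several.ok = TRUE)
  if (!is.null(axis_lengths)) stopifnot(all(axis_lengths > 0))
  structure(list(shape = shape, D = as.integer(D),
                 axis_lengths = axis_lengths, log_range = log_range,
                 n_constraints = n_constraints,
                 step_budget = as.integer(step_budget), samplers = samplers,
                 rounding = rounding, bins = bins, seed = as.integer(seed)),
            class = "benchmark_spec")
}

build_benchmark_shape <- function(spec) {
  switch(spec$shape,
    hypercube = make_hypercube(spec$D),
    hyperrectangle = make_hyperrectangle(spec$D, lengths = spec$axis_lengths,
                                         log_range = spec$log_range,
                                         seed = spec$seed),
    random_polytope = make_random_polytope(
      spec$D, if (is.null(spec$n_constraints)) 3L * spec$D else
        spec$n_constraints, seed = spec$seed))
}

#' Run a controlled rounding comparison on a synthetic shape
#'
#' Runs every requested sampler at the same Monte Carlo step budget on the
#' same shape, then computes per-axis KLD against the exact flat marginal
#' (axis-aligned boxes) and per-axis integrated autocorrelation times. KLD
#' verdicts use the 0.05 / 0.5 bit classification (good / approximate /
#' poor).
#'
#' @param spec a [benchmark_spec()].
#' @return list of class `benchmark_result`: per-sampler
#'   [diagnose_chain()] reports, a summary data frame, and the shape.
#' @export
run_rounding_comparison <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  poly <- build_benchmark_shape(spec)
  flat <- attr(poly, "flat_ranges")
  D <- spec$D
  n <- max(100L, as.integer(spec$step_budget))

  ell <- NULL
  if ("hr_rounded" %in% spec$samplers)
    ell <- make_rounding_ellipsoid(poly, spec$rounding, seed = spec$seed)

  reports <- list()
  for (s in spec$samplers) {
    ch <- switch(s,
      hr = hr_sample(poly, n = n, seed = spec$seed),
      hr_rounded = hr_sample(poly, n = n, seed = spec$seed, ellipsoid = ell),
      achr = achr_sample(poly, n = n, seed = spec$seed))
    reports[[s]] <- diagnose_chain(ch, flat_ranges = flat,
                                   ellipsoid = if (s == "hr_rounded") ell,
                                   bins = spec$bins)
  }
  summary <- do.call(rbind, lapply(names(reports), function(s) {
    rp <- reports[[s]]
    data.frame(sampler = s, tau_max = rp$tau_max,
               kld_max = if (all(is.na(rp$kld_bits))) NA else
                 max(rp$kld_bits),
               kld_mean = if (all(is.na(rp$kld_bits))) NA else
                 mean(rp$kld_bits),
               n_good = sum(rp$kld_bits < 0.05),
               n_poor = sum(rp$kld_bits > 0.5),
               stringsAsFactors = FALSE)
  }))
  structure(list(spec = spec, reports = reports, summary = summary),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> ", x$spec$shape, " D = ", x$spec$D,
      ", budget = ", x$spec$step_budget, " steps\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Build a rounding ellipsoid by a named schedule
#'
#' `"pca"`: pilot plain hit-and-run chain, covariance ellipsoid. `"lp"` /
#' `"lem"`: the direct constructions. `"lp+pca"` / `"lem+pca"`: the direct
#' ellipsoid first, then a pilot chain biased by it, then PCA of that pilot
#' — the schedule that estimates the stationary connected covariance best.
#' `"none"`: identity (unit ball) ellipsoid.
#'
#' @param poly a [flux_polytope()].
#' @param method one of `"none"`, `"pca"`, `"lp"`, `"lem"`, `"lp+pca"`,
#'   `"lem+pca"`.
#' @param pilot_n pilot-chain length for the PCA stages.
#' @param seed seed for pilot chains.
#' @return an [ellipsoid()], or `NULL` for `"none"`.
#' @export
make_rounding_ellipsoid <- function(poly, method, pilot_n = 20000, seed = 1) {
  method <- match.arg(method, c("none", "pca", "lp", "lem",
                                "lp+pca", "lem+pca"))
  D <- ncol(poly$G)
  base <- switch(method,
    none = return(NULL),
    pca = NULL,
    lp = return(lp_ellipsoid(poly)),
    lem = return(lovasz_ellipsoid(poly)$E),
    `lp+pca` = lp_ellipsoid(poly),
    `lem+pca` = lovasz_ellipsoid(poly)$E)
  pilot <- hr_sample(poly, n = max(pilot_n, D + 2), seed = seed,
                     ellipsoid = base)
  pca_ellipsoid(pilot)
}
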