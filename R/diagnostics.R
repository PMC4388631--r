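# Chain-quality diagnostics: integrated autocorrelation times by binning
# (batch means), Kolmogorov-Smirnov uniformity checks, and histogram
# Kullback-Leibler divergence in bits.

#' Integrated autocorrelation time by binning (batch means)
#'
#' For bin lengths `b` in powers of two, `r(b) = b * Var(bin means) /
#' Var(series)` grows to the plateau `2 tau_int`; the estimator reports half
#' the plateau value, where the plateau is the first `b` at which `r(b)`
#' changes by less than 10% from `r(b/2)`, capped at `b = T/20`. If no
#' plateau is reached before the cap the cap value is returned flagged
#' `converged = FALSE`. An uncorrelated series gives `tau ~ 1/2` (the
#' convention in which `tau` counts Monte Carlo steps per effective sample);
#' `tau < 1/2` flags anticorrelation.
#'
#' @param series numeric vector, length >= 100.
#' @param plateau_rel relative change defining the plateau.
#' @return object of class `tau_estimate`: list with `tau`, `se` (delete-one
#'   -bin jackknife standard error at the plateau), `converged`,
#'   `anticorrelated`, and the `r_curve` (bin length vs `r(b)`).
#' @export
integrated_autocorrelation <- function(series, plateau_rel = 0.1) {
  x <- as.numeric(series)
  T_ <- length(x)
  if (T_ < 100) stop("need a series of length >= 100, got ", T_,
                     call. = FALSE)
  v0 <- var(x)
  if (v0 == 0) stop("constant series: autocorrelation time undefined",
                    call. = FALSE)
  bmax <- floor(T_ / 20)
  bs <- 2^(0:floor(log2(bmax)))
  r <- numeric(length(bs))
  jse <- numeric(length(bs))
  for (i in seq_along(bs)) {
    b <- bs[i]
    k <- floor(T_ / b)
    m <- colMeans(matrix(x[seq_len(k * b)], nrow = b))
    r[i] <- b * var(m) / v0
    # delete-one-bin jackknife on r(b)
    sm <- sum(m); sm2 <- sum(m^2)
    vj <- ((sm2 - m^2) - (sm - m)^2 / (k - 1)) / (k - 2)
    rj <- b * vj / v0
    jse[i] <- sqrt((k - 1) / k * sum((rj - mean(rj))^2))
  }
  conv <- FALSE; idx <- length(bs)
  for (i in 2:length(bs)) {
    if (abs(r[i] - r[i - 1]) < plateau_rel * max(r[i - 1], 1e-12)) {
      conv <- TRUE; idx <- i; break
    }
  }
  tau <- r[idx] / 2
  structure(list(tau = tau, se = jse[idx] / 2, converged = conv,
                 anticorrelated = tau < 0.45,
                 r_curve = data.frame(bin = bs, r = r, se = jse)),
            class = "tau_estimate")
}

#' @export
print.tau_estimate <- function(x, ...) {
  cat("tau_int = ", format(x$tau, digits = 4), " +/- ",
      format(x$se, digits = 2), " MC steps",
      if (!x$converged) " [no plateau: not converged]",
      if (x$anticorrelated) " [anticorrelated]", "\n", sep = "")
  invisible(x)
}

#' Per-coordinate autocorrelation times of a chain
#'
#' Applies [integrated_autocorrelation()] to every coordinate and reports
#' the maximum plus the increasing-ordered list (the standard display for
#' comparing preprocessing schedules). Times are in Monte Carlo steps:
#' the chain's thinning factor is multiplied back in.
#'
#' @param chain a [sample_chain()] with at least 100 points.
#' @return list with `tau_max`, `tau_sorted` (increasing), `tau` (per
#'   coordinate, chain order), `converged` (all plateaus found), `details`.
#' @export
max_autocorrelation <- function(chain) {
  stopifnot(inherits(chain, "sample_chain"))
  X <- chain$points
  if (nrow(X) < 100) stop("need >= 100 chain points", call. = FALSE)
  ests <- lapply(seq_len(ncol(X)), function(j)
    integrated_autocorrelation(X[, j]))
  tau <- vapply(ests, `[[`, numeric(1), "tau") * chain$thinning
  list(tau_max = max(tau), tau_sorted = sort(tau), tau = tau,
       converged = all(vapply(ests, `[[`, logical(1), "converged")),
       details = ests)
}

#' Kolmogorov-Smirnov uniformity / two-sample test
#'
#' One-sample against Uniform(a, b), or two-sample against a reference
#' sample. Correlated chain output should be subsampled to effectively
#' independent points first: pass `tau` to apply a stride of `ceil(2 tau)`.
#'
#' @param samples numeric vector under test.
#' @param reference `c(a, b)` for the one-sample uniform test (default the
#'   unit interval), or a second sample (length > 2) for the two-sample test.
#' @param tau optional integrated autocorrelation time of `samples`; when
#'   given, `samples` is subsampled with stride `ceiling(2 * tau)`.
#' @param level rejection level.
#' @return list with `statistic`, `p_value`, `reject`, `n_effective`.
#' @export
ks_uniformity <- function(samples, reference = c(0, 1), tau = NULL,
                          level = 0.05) {
  x <- as.numeric(samples)
  if (!is.null(tau)) {
    stride <- max(1L, as.integer(ceiling(2 * tau)))
    x <- x[seq(1, length(x), by = stride)]
  }
  if (length(x) < 20)
    stop("fewer than 20 effectively independent samples (", length(x), ")",
         call. = FALSE)
  if (length(reference) == 2 && is.numeric(reference) &&
      !inherits(reference, "sample_chain")) {
    ht <- suppressWarnings(ks.test(x, "punif", min = reference[1],
                                   max = reference[2]))
  } else {
    ht <- suppressWarnings(ks.test(x, as.numeric(reference)))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       reject = ht$p.value < level, n_effective = length(x))
}

#' Histogram Kullback-Leibler divergence in bits
#'
#' Plug-in estimate of `KLD(Q | P) = sum_bins P log2(P / Q)` — the
#' information lost when approximating P by Q; `N` samples from Q deceive an
#' observer expecting P with probability `2^(-N KLD)`. Both distributions
#' are histogrammed on a shared binning over the union range with a
#' pseudo-count per bin regularizing empty bins. `p_samples` may instead be
#' `c(a, b)`, interpreted as the exact Uniform(a, b) reference (used for the
#' flat marginals of axis-aligned boxes, where the truth is known).
#'
#' @param q_samples samples of the approximating distribution Q.
#' @param p_samples samples of the reference distribution P, or `c(a, b)`
#'   with `attr(., "uniform") = TRUE` / passed via `p_uniform`.
#' @param bins number of bins (shared).
#' @param pseudo_count added to every bin count.
#' @param p_uniform optional `c(a, b)`: use the exact flat density on
#'   `[a, b]` as P instead of a P sample.
#' @return KLD estimate in bits (`Inf` when the supports do not overlap).
#' @export
kld_histogram <- function(q_samples, p_samples = NULL, bins = 100,
                          pseudo_count = 0.5, p_uniform = NULL) {
  q <- as.numeric(q_samples)
  if (!length(q)) stop("empty Q sample", call. = FALSE)
  if (is.null(p_samples) && is.null(p_uniform))
    stop("need a P sample or a uniform reference range", call. = FALSE)
  if (!is.null(p_uniform)) {
    stopifnot(length(p_uniform) == 2, p_uniform[2] > p_uniform[1])
    lo <- min(q, p_uniform[1]); hi <- max(q, p_uniform[2])
    if (min(q) >= p_uniform[2] || max(q) <= p_uniform[1]) return(Inf)
    breaks <- seq(lo, hi, length.out = bins + 1)
    qc <- tabulate(findInterval(q, breaks, rightmost.closed = TRUE,
                                all.inside = TRUE), nbins = bins)
    Qp <- (qc + pseudo_count) / (length(q) + pseudo_count * bins)
    ov <- pmax(pmin(breaks[-1], p_uniform[2]) -
                 pmax(breaks[-length(breaks)], p_uniform[1]), 0)
    Pp <- ov / (p_uniform[2] - p_uniform[1])
    nz <- Pp > 0
    return(sum(Pp[nz] * log2(Pp[nz] / Qp[nz])))
  }
  p <- as.numeric(p_samples)
  if (!length(p)) stop("empty P sample", call. = FALSE)
  if (min(q) >= max(p) || max(q) <= min(p)) return(Inf)
  lo <- min(q, p); hi <- max(q, p)
  breaks <- seq(lo, hi, length.out = bins + 1)
  qc <- tabulate(findInterval(q, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = bins)
  pc <- tabulate(findInterval(p, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = bins)
  Qp <- (qc + pseudo_count) / (length(q) + pseudo_count * bins)
  Pp <- (pc + pseudo_count) / (length(p) + pseudo_count * bins)
  sum(Pp * log2(Pp / Qp))
}

#' Probability of mistaking N samples of Q for P
#'
#' Direct evaluation of `2^(-N * KLD)`.
#'
#' @param n_samples N.
#' @param kld_bits divergence in bits.
#' @return deception probability.
#' @export
deception_probability <- function(n_samples, kld_bits) {
  2^(-n_samples * kld_bits)
}

#' Fit the scaling exponent of tau_max versus dimension
#'
#' Least-squares fit of `log tau ~ log D`; at least three dimensions needed.
#'
#' @param D dimensions.
#' @param tau corresponding autocorrelation times.
#' @return list with `exponent`, `ci` (95%), `fit`.
#' @export
fit_scaling_exponent <- function(D, tau) {
  stopifnot(length(D) == length(tau))
  if (length(unique(D)) < 3)
    stop("need at least 3 distinct dimensions to fit a scaling exponent",
         call. = FALSE)
  fit <- lm(log(tau) ~ log(D))
  ci <- tryCatch(confint(fit)[2, ], error = function(e) c(NA, NA))
  if (any(!is.finite(ci)))
    warning("degenerate scaling fit", call. = FALSE)
  list(exponent = unname(coef(fit)[2]), ci = unname(ci), fit = fit)
}

#' Empirical mixing-time scaling on hypercubes
#'
#' Runs the rounded hit-and-run sampler on unit hypercubes of increasing
#' dimension (the hypercube is isotropic, so its matching ellipsoid has
#' sandwiching ratio O(1)), estimates `tau_max` for each dimension and fits
#' the scaling exponent of `tau_max` versus D — an empirical probe of the
#' polynomial mixing `tau = O(D^2 R^2 / r^2)`, not a proof.
#'
#' @param D_values at least 3 hypercube dimensions.
#' @param n_points recorded points per chain.
#' @param reps independent chains per dimension (averaged).
#' @param seed integer seed.
#' @return list with `table` (D, mean tau_max), `exponent`, `ci`.
#' @export
mixing_scaling_probe <- function(D_values, n_points = 20000, reps = 2,
                                 seed = 1) {
  if (length(unique(D_values)) < 3)
    stop("need at least 3 distinct dimensions", call. = FALSE)
  taus <- vapply(seq_along(D_values), function(i) {
    D <- D_values[i]
    poly <- make_hypercube(D)
    mean(vapply(seq_len(reps), function(r) {
      ch <- hr_sample(poly, n = n_points, seed = seed + 1000L * i + r,
                      start = rep(0.5, D))
      max_autocorrelation(ch)$tau_max
    }, numeric(1)))
  }, numeric(1))
  fitres <- fit_scaling_exponent(D_values, taus)
  list(table = data.frame(D = D_values, tau_max = taus),
       exponent = fitres$exponent, ci = fitres$ci)
}

#' Full diagnostics report for a chain
#'
#' Bundles per-coordinate integrated autocorrelation times, per-coordinate
#' Kolmogorov-Smirnov tests against a reference (when known), per-coordinate
#' KLD values, and an optional ellipsoid diameter spectrum.
#'
#' @param chain a [sample_chain()].
#' @param flat_ranges optional 2-column matrix (per-coordinate `a`, `b`)
#'   when the exact flat marginals are known (axis-aligned boxes).
#' @param ellipsoid optional [ellipsoid()] whose diameter spectrum to attach.
#' @param bins histogram bins for the KLD estimate.
#' @return object of class `diagnostics_report`.
#' @export
diagnose_chain <- function(chain, flat_ranges = NULL, ellipsoid = NULL,
                           bins = 100) {
  stopifnot(inherits(chain, "sample_chain"))
  ac <- max_autocorrelation(chain)
  D <- ncol(chain$points)
  ks_stat <- ks_p <- kld <- rep(NA_real_, D)
  if (!is.null(flat_ranges)) {
    flat_ranges <- as.matrix(flat_ranges)
    stopifnot(nrow(flat_ranges) == D, ncol(flat_ranges) == 2)
    for (j in seq_len(D)) {
      kt <- ks_uniformity(chain$points[, j], reference = flat_ranges[j, ],
                          tau = ac$tau[j] / chain$thinning)
      ks_stat[j] <- kt$statistic; ks_p[j] <- kt$p_value
      kld[j] <- kld_histogram(chain$points[, j], bins = bins,
                              p_uniform = flat_ranges[j, ])
    }
  }
  structure(list(tau = ac$tau, tau_sorted = ac$tau_sorted,
                 tau_max = ac$tau_max, tau_converged = ac$converged,
                 ks_statistic = ks_stat, ks_p_value = ks_p,
                 kld_bits = kld,
                 diameter_spectrum = if (!is.null(ellipsoid))
                   diameter_spectrum(ellipsoid),
                 sampler_id = chain$sampler_id, seed = chain$seed,
                 thinning = chain$thinning, n_points = nrow(chain$points)),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("<diagnostics_report> sampler = ", x$sampler_id, ", ", x$n_points,
      " points\n  tau_max = ", format(x$tau_max, digits = 4), " MC steps",
      if (!x$tau_converged) " [some coordinates not converged]", "\n",
      sep = "")
  if (!all(is.na(x$kld_bits)))
    cat("  KLD vs flat: max = ", format(max(x$kld_bits), digits = 3),
        " bits, mean = ", format(mean(x$kld_bits), digits = 3), " bits\n",
        sep = "")
  invisible(x)
}

#' Write a diagnostics report as TSV + JSON summary
#'
#' @param report a [diagnose_chain()] result.
#' @param path_tsv per-coordinate table destination.
#' @param path_json scalar-summary destination.
#' @export
write_report <- function(report, path_tsv, path_json) {
  df <- data.frame(coordinate = seq_along(report$tau), tau = report$tau,
                   ks_statistic = report$ks_statistic,
                   ks_p_value = report$ks_p_value,
                   kld_bits = report$kld_bits)
  utils::write.table(df, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summ <- list(sampler_id = report$sampler_id, seed = report$seed,
               thinning = report$thinning, n_points = report$n_points,
               tau_max = report$tau_max,
               tau_converged = report$tau_converged,
               kld_max_bits = if (all(is.na(report$kld_bits))) NULL else
                 max(report$kld_bits))
  jsonlite::write_json(summ, path_json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(NULL)
}
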