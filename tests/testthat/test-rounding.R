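test_that("ellipsoid construction validates shape and factors it", {
  expect_error(ellipsoid(c(0, 0), matrix(c(1, 0.5, 0, 1), 2, 2)),
               "not symmetric")
  expect_error(ellipsoid(c(0, 0), matrix(c(1, 2, 2, 1), 2, 2)),
               "not positive definite")
  set.seed(7)
  M <- matrix(rnorm(9), 3, 3)
  P <- crossprod(M) + diag(3)
  E <- ellipsoid(rnorm(3), P)
  expect_lt(max(abs(tcrossprod(E$transform) - E$shape)),
            1e-8 * max(abs(E$shape)))
})

test_that("diameter spectrum matches analytic and brute-force extremal chords", {
  expect_equal(diameter_spectrum(ellipsoid(c(0, 0), diag(c(1, 4)))), c(2, 4))
  expect_equal(diameter_spectrum(ellipsoid(rep(0, 3), diag(3))), rep(2, 3))
  set.seed(8)
  M <- matrix(rnorm(9), 3, 3)
  P <- crossprod(M) + 0.1 * diag(3)
  ds <- diameter_spectrum(ellipsoid(rep(0, 3), P))
  # widest chord: maximize 2 sqrt(u' P u) over random unit directions
  U <- random_direction(3, n = 20000)
  widest <- max(2 * sqrt(rowSums((U %*% P) * U)))
  expect_equal(max(ds), widest, tolerance = 0.01)
})

test_that("PCA ellipsoid recovers box covariances and handles degeneracy", {
  set.seed(9)
  a <- c(2, 5)
  X <- cbind(runif(1e5, 0, a[1]), runif(1e5, 0, a[2]))
  E <- pca_ellipsoid(X)
  expect_equal(diag(E$shape), a^2 / 12, tolerance = 0.05)
  expect_equal(E$center, a / 2, tolerance = 0.05)
  expect_lt(abs(E$shape[1, 2]), 0.05)

  # isotropic cloud: axis ratio ~ 1
  Y <- matrix(rnorm(2e4), ncol = 2)
  dsY <- diameter_spectrum(pca_ellipsoid(Y))
  expect_equal(dsY[2] / dsY[1], 1, tolerance = 0.1)

  # identical points: ridge with a warning
  Z <- matrix(1, 10, 2)
  expect_warning(EZ <- pca_ellipsoid(Z), "ridge")
  expect_true(all(eigen(EZ$shape)$values > 0))
  expect_error(pca_ellipsoid(matrix(rnorm(4), 2, 2)), "at least D\\+1")
})

test_that("PCA ellipsoid is equivariant under affine maps", {
  set.seed(10)
  X <- matrix(runif(3000), ncol = 3)
  M <- matrix(rnorm(9), 3, 3)
  b <- rnorm(3)
  E1 <- pca_ellipsoid(X)
  E2 <- pca_ellipsoid(sweep(X %*% t(M), 2, b, "+"))
  expect_equal(E2$center, as.numeric(M %*% E1$center + b), tolerance = 1e-9)
  expect_equal(E2$shape, M %*% E1$shape %*% t(M), tolerance = 1e-9)
})

test_that("LP ellipsoid recovers box axes exactly and flags collapse", {
  p <- make_hyperrectangle(3, lengths = c(10, 1, 0.1))
  E <- lp_ellipsoid(p)
  expect_equal(diameter_spectrum(E), c(0.1, 1, 10), tolerance = 1e-6)
  eg <- eigen(E$shape, symmetric = TRUE)
  # eigenvectors align with coordinate axes
  expect_equal(abs(eg$vectors[cbind(order(-eg$values), 1:3)]), rep(1, 3),
               tolerance = 1e-6)

  # unit square: the two axis lengths tie by symmetry
  E2 <- lp_ellipsoid(make_hypercube(2))
  ds <- diameter_spectrum(E2)
  expect_equal(ds[1], ds[2], tolerance = 1e-9)

  # a segment embedded in 2-D is not full-dimensional
  seg <- flux_polytope(rbind(diag(2), -diag(2)), c(1, 0, 0, 0), radius = 2)
  expect_error(lp_ellipsoid(seg), "dimension collapse")
})

test_that("LP ellipsoid axis lengths are proportional to box side lengths", {
  set.seed(11)
  for (rep in 1:5) {
    D <- sample(2:5, 1)
    L <- 10^runif(D, -2, 2)
    E <- lp_ellipsoid(make_hyperrectangle(D, lengths = L))
    expect_equal(diameter_spectrum(E) / sort(L), rep(1, D),
                 tolerance = 1e-6)
  }
})

test_that("central deep cut of the unit disk matches the classic formulas", {
  E <- ellipsoid(c(0, 0), diag(2))
  # keep {x1 <= 0}: cut through the center with normal e1
  E2 <- min_enclosing_halfellipsoid(E, c(1, 0), c(0, 0))
  expect_equal(E2$center, c(-1 / 3, 0), tolerance = 1e-12)
  expect_equal(sort(sqrt(eigen(E2$shape)$values)), c(2 / 3, 2 / sqrt(3)),
               tolerance = 1e-12)
  # brute force: dense half-disk must be contained
  th <- seq(0, 2 * pi, length.out = 400)
  pts <- rbind(cbind(cos(th), sin(th)), cbind(runif(2000, -1, 0),
                                              runif(2000, -1, 1)))
  pts <- pts[pts[, 1] <= 0 & rowSums(pts^2) <= 1, ]
  expect_true(all(apply(pts, 1, function(x) in_ellipsoid(E2, x, 1e-9))))
})

test_that("deep cuts shrink volume monotonically in the cut depth", {
  E <- ellipsoid(c(0, 0), diag(2))
  alphas <- c(0, 0.2, 0.4, 0.6, 0.8, 0.95)
  vols <- vapply(alphas, function(a) {
    ellipsoid_log_volume(min_enclosing_halfellipsoid(E, c(1, 0), c(-a, 0)))
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
  expect_lt(tail(vols, 1), ellipsoid_log_volume(E) - 3)  # alpha -> 1: tiny
})

test_that("too-shallow cuts return the ellipsoid unchanged, empty cuts error", {
  E <- ellipsoid(c(0, 0), diag(2))
  # keeping {x1 <= 0.9} removes almost nothing: alpha = -0.9 <= -1/D
  expect_message(E2 <- min_enclosing_halfellipsoid(E, c(1, 0), c(0.9, 0)),
                 "too shallow")
  expect_equal(E2$shape, E$shape)
  expect_equal(E2$center, E$center)
  # keeping {x1 <= -1.5} misses the ellipsoid entirely: alpha >= 1
  expect_error(min_enclosing_halfellipsoid(E, c(1, 0), c(-1.5, 0)),
               "empty cut")
})

test_that("Lovász method returns a certified sandwiching pair", {
  # square centered like [0,2]^2: immediate termination, zero cuts
  sq <- make_hyperrectangle(2, lengths = c(2, 2))
  lv <- lovasz_ellipsoid(sq)
  expect_identical(lv$cuts, 0L)
  expect_true(inner_contained(lv$E_inner, sq$G, sq$h))

  # heterogeneous boxes and random polytopes: E_inner <= P <= E with exact
  # support-function / vertex checks, and monotone volumes
  set.seed(12)
  shapes <- list(make_hyperrectangle(2, lengths = c(8, 0.25)),
                 make_random_polytope(3, 12, seed = 31),
                 make_random_polytope(6, 24, seed = 32))
  for (p in shapes) {
    D <- ncol(p$G)
    lv <- lovasz_ellipsoid(p)
    expect_true(inner_contained(lv$E_inner, p$G, p$h))
    fv <- fva(p)
    verts <- rbind(fv$argmin, fv$argmax)
    expect_true(all(apply(verts, 1, function(v) in_ellipsoid(lv$E, v, 1e-6))))
    expect_true(all(diff(lv$log_volumes) <= 1e-9))
    # the shrink relation between the pair is exact
    expect_equal(lv$E_inner$shape, (if (D == 1) 0.5 else D^-1.5)^2 * lv$E$shape,
                 tolerance = 1e-12)
  }
})

test_that("the axis-endpoint containment variant also converges", {
  p <- make_hyperrectangle(2, lengths = c(4, 0.5))
  lv <- lovasz_ellipsoid(p, check = "axis")
  # axis spot-check certifies only the endpoints; validate the result with
  # the exact support criterion allowing a loose margin
  ok <- inner_contained(lv$E_inner, p$G, p$h, tol = 1e-6)
  sup_excess <- max(as.numeric(p$G %*% lv$E_inner$center) +
                      sqrt(rowSums((p$G %*% lv$E_inner$shape) * p$G)) - p$h)
  expect_true(ok || sup_excess < 0.1 * max(p$h))
  expect_gte(lv$cuts, 0L)
})
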