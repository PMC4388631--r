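test_that("null-space reduction finds the right dimension", {
  # v1 = v2 segment
  m <- stoich_model(matrix(c(1, -1), 1, 2), "A", c("R1", "R2"),
                    c(0, 0), c(1, 1))
  p <- build_polytope(m)
  expect_identical(ncol(p$G), 1L)
  # no coupling: D = N
  p3 <- build_polytope(toy_box_model(3))
  expect_identical(ncol(p3$G), 3L)
  # random full-rank 5 x 12: D = 12 - rank(S), rank from an independent
  # QR-based oracle
  set.seed(42)
  S <- matrix(rnorm(60), 5, 12)
  mr <- stoich_model(S, paste0("M", 1:5), paste0("R", 1:12),
                     rep(-10, 12), rep(10, 12))
  pr <- build_polytope(mr)
  expect_identical(ncol(pr$G), 12L - qr(S)$rank)
})

test_that("reduction produces an orthonormal basis and a feasible anchor", {
  set.seed(43)
  S <- matrix(rnorm(60), 5, 12)
  m <- stoich_model(S, paste0("M", 1:5), paste0("R", 1:12),
                    rep(-10, 12), rep(10, 12))
  p <- build_polytope(m)
  expect_equal(crossprod(p$basis), diag(ncol(p$basis)), tolerance = 1e-12)
  expect_lt(max(abs(S %*% p$basis)), 1e-9)
  expect_lt(max(abs(S %*% p$anchor)), 1e-9)
  expect_true(all(p$anchor >= m$lower_bounds - 1e-9))
  expect_true(all(p$anchor <= m$upper_bounds + 1e-9))
})

test_that("infeasible and zero-dimensional models are signalled", {
  infeas <- stoich_model(matrix(c(1, 1), 1, 2), "A", c("R1", "R2"),
                         c(1, 1), c(2, 2))
  expect_error(build_polytope(infeas), "infeasible")
  point <- stoich_model(diag(2), c("A", "B"), c("R1", "R2"),
                        c(-1, -1), c(1, 1))
  expect_error(build_polytope(point), "dimension 0")
})

test_that("FVA recovers known coordinate and flux ranges", {
  cube <- make_hypercube(4)
  fv <- fva(cube)
  expect_equal(fv$ranges$min, rep(0, 4))
  expect_equal(fv$ranges$max, rep(1, 4))
  tri <- triangle_polytope()
  ft <- fva(tri)
  expect_equal(ft$ranges$max[1], 1, tolerance = 1e-9)
  expect_equal(ft$ranges$min[1], 0, tolerance = 1e-9)
  # vertices satisfy the constraints
  expect_true(all(tri$G %*% ft$argmax[1, ] <= tri$h + 1e-9))

  # steady state couples v1 = v2: both flux ranges shrink to [0, 1]
  m <- stoich_model(matrix(c(1, -1), 1, 2), "A", c("R1", "R2"),
                    c(0, 0), c(2, 1))
  p <- build_polytope(m)
  ff <- fva(p, space = "flux")
  expect_equal(ff$ranges$min, c(0, 0), tolerance = 1e-9)
  expect_equal(ff$ranges$max, c(1, 1), tolerance = 1e-9)
  # and agrees with the direct flux-space LP route
  fm <- fva_model(m)
  expect_equal(fm$min, ff$ranges$min, tolerance = 1e-9)
  expect_equal(fm$max, ff$ranges$max, tolerance = 1e-9)
})

test_that("flux-space FVA is invariant under orthonormal re-basing", {
  set.seed(44)
  m <- toy_chain_model(lb = 0, ub = 2)
  p <- build_polytope(m)
  D <- ncol(p$G)
  Q <- qr.Q(qr(matrix(rnorm(D * D), D, D)))
  p2 <- p
  p2$basis <- p$basis %*% Q
  p2$G <- p$G %*% Q
  expect_equal(fva(p, space = "flux")$ranges, fva(p2, space = "flux")$ranges,
               tolerance = 1e-9)
})

test_that("blocked reactions and orphaned metabolites are pruned, idempotently", {
  m <- toy_blocked_model()
  pr <- remove_blocked(m)
  expect_identical(pr$reaction_ids, "R3")
  expect_identical(attr(pr, "removed"), c("R1", "R2"))
  expect_identical(length(pr$metabolite_ids), 0L)
  # fixed-to-zero bounds are removed too
  m2 <- stoich_model(matrix(0, 1, 2), "M", c("R1", "R2"),
                     c(0, 0), c(0, 1))
  expect_identical(remove_blocked(m2)$reaction_ids, "R2")
  # uncoupled box: nothing to remove; idempotence
  m3 <- toy_box_model(3)
  pr3 <- remove_blocked(m3)
  expect_identical(pr3$reaction_ids, m3$reaction_ids)
  pr3b <- remove_blocked(pr3)
  expect_identical(pr3b$reaction_ids, pr3$reaction_ids)
  expect_equal(pr3b$S, pr3$S)
})

test_that("interior points are strictly interior", {
  set.seed(45)
  sq <- make_hypercube(2)
  x <- find_interior_point(sq)
  expect_true(all(x > 0 & x < 1))
  seg <- make_hypercube(1)
  xs <- find_interior_point(seg)
  expect_true(xs > 0 && xs < 1)
  rp <- make_random_polytope(5, 20, seed = 9)
  xr <- find_interior_point(rp)
  expect_true(all(rp$G %*% xr < rp$h - 1e-9))
})

test_that("membership respects the boundary tolerance", {
  sq <- make_hypercube(2)
  tol <- 1e-6
  expect_true(contains(sq, c(0.5, 0.5), tol = tol))
  expect_false(contains(sq, c(1 + 2 * tol, 0.5), tol = tol))
  expect_true(contains(sq, c(1, 0.5), tol = tol))   # exactly on a facet
  expect_error(contains(sq, c(0.5, 0.5, 0.5)), "dimension")
})

test_that("chords match geometry and a bisection oracle", {
  sq <- make_hypercube(2)
  ch <- chord(sq, c(0.5, 0.5), c(1, 0))
  expect_equal(c(ch$lambda_min, ch$lambda_max), c(-0.5, 0.5))
  chd <- chord(sq, c(0.5, 0.5), c(1, 1) / sqrt(2))
  expect_equal(c(chd$lambda_min, chd$lambda_max),
               c(-sqrt(2) / 2, sqrt(2) / 2))

  # triangle case against brute-force bisection on membership
  tri <- triangle_polytope()
  x <- c(0.25, 0.25)
  th <- c(1, 0)
  ct <- chord(tri, x, th)
  bisect <- function(sgn) {
    lo <- 0; hi <- 10
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (contains(tri, x + sgn * mid * th, tol = 0)) lo <- mid else hi <- mid
    }
    sgn * lo
  }
  expect_equal(ct$lambda_max, bisect(1), tolerance = 1e-9)
  expect_equal(ct$lambda_min, bisect(-1), tolerance = 1e-9)
  expect_equal(c(ct$lambda_min, ct$lambda_max), c(-0.25, 0.5))
})

test_that("chord endpoints lie on the boundary and midpoints stay interior", {
  set.seed(46)
  for (rep in 1:10) {
    rp <- make_random_polytope(4, 16, seed = 50 + rep)
    x <- find_interior_point(rp)
    th <- random_direction(4)
    ch <- chord(rp, x, th)
    expect_false(ch$degenerate)
    expect_true(contains(rp, x + ch$lambda_max * th, tol = 1e-8))
    expect_true(contains(rp, x + ch$lambda_min * th, tol = 1e-8))
    mid <- x + (ch$lambda_min + ch$lambda_max) / 2 * th
    expect_true(contains(rp, mid))
  }
})
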