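test_that("random directions are unit length and sphere-symmetric", {
  set.seed(20)
  U <- random_direction(7, n = 200)
  expect_equal(sqrt(rowSums(U^2)), rep(1, 200), tolerance = 1e-12)
  # D = 1: +/-1 with equal probability
  u1 <- random_direction(1, n = 10000)
  expect_true(all(abs(u1) == 1))
  expect_lt(abs(mean(u1)), 4 / sqrt(10000) * 2)
  # D = 3: per-coordinate means vanish at the CLT scale
  U3 <- random_direction(3, n = 1e5)
  expect_true(all(abs(colMeans(U3)) < 4 / sqrt(1e5)))
})

test_that("one-dimensional hit-and-run is exactly uniform", {
  seg <- make_hypercube(1)
  ch <- hr_sample(seg, n = 2000, seed = 21, start = 0.7)
  # every step redraws lambda over the whole segment: i.i.d. uniform
  kt <- ks_uniformity(ch$points[, 1], reference = c(0, 1))
  expect_false(kt$reject)
})

test_that("hit-and-run samples the unit square uniformly and stays inside", {
  sq <- make_hypercube(2)
  ch <- hr_sample(sq, n = 1e4, seed = 22, start = c(0.5, 0.5))
  expect_true(all(ch$points >= 0 & ch$points <= 1))
  ac <- max_autocorrelation(ch)
  for (j in 1:2) {
    kt <- ks_uniformity(ch$points[, j], reference = c(0, 1),
                        tau = ac$tau[j])
    expect_false(kt$reject)
  }
})

test_that("chains are bitwise deterministic given the seed", {
  rp <- make_random_polytope(4, 16, seed = 5)
  a <- hr_sample(rp, n = 500, seed = 77)
  b <- hr_sample(rp, n = 500, seed = 77)
  expect_identical(a$points, b$points)
  c <- hr_sample(rp, n = 500, seed = 78)
  expect_false(identical(a$points, c$points))
  d1 <- achr_sample(rp, n = 300, seed = 9)
  d2 <- achr_sample(rp, n = 300, seed = 9)
  expect_identical(d1$points, d2$points)
  r1 <- rejection_sample(rp, n = 300, seed = 10)
  r2 <- rejection_sample(rp, n = 300, seed = 10)
  expect_identical(r1$points, r2$points)
})

test_that("ellipsoid-biased HR equals plain HR on the affinely mapped body", {
  # bias A on P = [0,1] x [0,3]  vs  plain HR on A^-1 P = unit square,
  # mapped forward by A: identical laws
  A <- diag(c(1, 3))
  P <- make_hyperrectangle(2, lengths = c(1, 3))
  Eb <- ellipsoid(c(0.5, 1.5), A %*% t(A))
  ch_bias <- hr_sample(P, n = 8000, seed = 23, ellipsoid = Eb,
                       start = c(0.5, 1.5))
  sq <- make_hypercube(2)
  ch_sq <- hr_sample(sq, n = 8000, seed = 24, start = c(0.5, 0.5))
  mapped <- ch_sq$points %*% t(A)
  for (j in 1:2) {
    tau <- max(integrated_autocorrelation(ch_bias$points[, j])$tau,
               integrated_autocorrelation(mapped[, j])$tau)
    stride <- max(1L, ceiling(2 * tau))
    x <- ch_bias$points[seq(1, 8000, by = stride), j]
    y <- mapped[seq(1, 8000, by = stride), j]
    kt <- suppressWarnings(ks.test(x, y))
    expect_gt(kt$p.value, 0.01)
  }
})

test_that("frozen dynamics on a degenerate polytope is reported", {
  # segment embedded in 2-D: zero width in x2
  seg <- flux_polytope(rbind(diag(2), -diag(2)), c(1, 0, 0, 0), radius = 2)
  expect_error(hr_sample(seg, n = 100, seed = 25, start = c(0.5, 0),
                         chord_floor = 1e-9, resample_cap = 50),
               "frozen dynamics")
})

test_that("ACHR stays inside and matches uniformity in low dimension", {
  sq <- make_hypercube(2)
  ch <- achr_sample(sq, n = 1e4, seed = 26, start = c(0.5, 0.5))
  expect_true(all(ch$points >= -1e-9 & ch$points <= 1 + 1e-9))
  ac <- max_autocorrelation(ch)
  for (j in 1:2) {
    kt <- ks_uniformity(ch$points[, j], reference = c(0, 1),
                        tau = ac$tau[j])
    expect_false(kt$reject)
  }
  expect_error(achr_sample(sq, n = 10, seed = 1, warmup = 2),
               "warmup")
})

test_that("rejection sampling acceptance rates match known volume ratios", {
  sq <- make_hypercube(2)
  r <- rejection_sample(sq, n = 2000, seed = 27)
  expect_identical(attr(r, "acceptance_rate"), 1)
  tri <- triangle_polytope()
  rt <- rejection_sample(tri, n = 5000, seed = 28)
  # area ratio 1/2 within a generous binomial interval
  expect_equal(attr(rt, "acceptance_rate"), 0.5, tolerance = 0.05)
  expect_true(all(rt$points %*% c(1, 1) <= 1 + 1e-9))

  # L1 ball in D = 5: volume 2^D / D! over box 2^D => acceptance 1/120
  D <- 5
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), D)))
  l1 <- flux_polytope(signs, rep(1, 2^D), radius = sqrt(D))
  rl <- rejection_sample(l1, n = 1500, seed = 29)
  expect_equal(attr(rl, "acceptance_rate"), 1 / 120, tolerance = 0.15)
  expect_error(rejection_sample(make_hypercube(11), 10, seed = 1),
               "D <= 10")
})

test_that("rounded HR agrees with the exact rejection oracle", {
  rp <- make_random_polytope(4, 14, seed = 41)
  el <- lp_ellipsoid(rp)
  hr <- hr_sample(rp, n = 2e4, seed = 42, ellipsoid = el)
  rj <- rejection_sample(rp, n = 4000, seed = 43)
  ac <- max_autocorrelation(hr)
  for (j in 1:4) {
    stride <- max(1L, ceiling(2 * ac$tau[j]))
    x <- hr$points[seq(1, nrow(hr$points), by = stride), j]
    kt <- suppressWarnings(ks.test(x, rj$points[, j]))
    expect_gt(kt$p.value, 0.05 / 4)   # Bonferroni across coordinates
  }
})
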