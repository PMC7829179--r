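test_that("FRic equals known hull volumes and ignores interior points", {
  expect_equal(as.numeric(fric(unit_square())), 1.0)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(as.numeric(fric(cube)), 1.0)
  expect_equal(as.numeric(fric(rbind(unit_square(), c(0.5, 0.5)))), 1.0)
})

test_that("hull volume matches the shoelace oracle on random 2-D clouds", {
  set.seed(21)
  for (r in 1:50) {
    n <- sample(3:40, 1)
    p <- matrix(rnorm(2 * n), ncol = 2)
    expect_equal(convhull_volume(p)$volume, shoelace_area(p),
                 tolerance = 1e-10)
  }
})

test_that("hull volume is exact for rotated solids in 3-5 dimensions", {
  for (d in 3:5) {
    set.seed(d)
    Q <- qr.Q(qr(matrix(rnorm(d * d), d)))   # random rotation
    corners <- as.matrix(expand.grid(rep(list(0:1), d)))
    inner <- matrix(runif(15 * d, 0.1, 0.9), ncol = d)
    expect_equal(convhull_volume(rbind(corners, inner) %*% t(Q))$volume,
                 1.0, tolerance = 1e-9)
    simplex <- rbind(rep(0, d), diag(d)) %*% t(Q)
    expect_equal(convhull_volume(simplex)$volume, 1 / factorial(d),
                 tolerance = 1e-12)
    crosspoly <- rbind(diag(d), -diag(d)) %*% t(Q)
    expect_equal(convhull_volume(crosspoly)$volume, 2^d / factorial(d),
                 tolerance = 1e-12)
  }
})

test_that("FRic obeys invariance and scaling laws", {
  set.seed(31)
  p <- matrix(rnorm(12 * 3), ncol = 3)
  v <- as.numeric(fric(p))
  # translation and rotation invariance
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(as.numeric(fric(sweep(p %*% t(Q), 2, c(5, -2, 1), "+"))),
               v, tolerance = 1e-9)
  # scaling: c^k
  expect_equal(as.numeric(fric(2.5 * p)), 2.5^3 * v, tolerance = 1e-9)
})

test_that("FRic reduces dimensionality for small assemblages and flags
           degeneracy", {
  p <- matrix(rnorm(3 * 5), ncol = 5)   # S = 3 in 5 axes
  f <- fric(p, k = 5)
  expect_equal(attr(f, "k_used"), 2)
  expect_true(attr(f, "reduced"))
  expect_true(as.numeric(f) > 0)
  # collinear points are degenerate in 2-D: volume 0, flagged, no error
  coll <- cbind(0:3, 0:3)
  fd <- fric(coll, k = 2)
  expect_equal(as.numeric(fd), 0)
  expect_true(attr(fd, "degenerate"))
})

test_that("FEve equals 1 for even spacing and matches the hand case", {
  expect_equal(feve(cbind(0:3, 0)), 1.0)
  expect_equal(feve(cbind(c(0, 1, 2), 0)), 1.0)
  # triangle with equal MST branches
  expect_equal(feve(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))), 1.0)
  # 0,1,2,102: (2/102 + 1/3 - 1/3)/(2/3) = 3/102
  expect_equal(feve(cbind(c(0, 1, 2, 102), 0)), 3 / 102)
  expect_error(feve(cbind(c(0, 1), 0)), "3 species")
  expect_error(feve(matrix(1, 4, 2)), "identical")
})

test_that("FEve stays within [0, 1] on random point sets", {
  set.seed(41)
  for (r in 1:20) {
    S <- sample(3:30, 1)
    p <- matrix(rnorm(S * 4), ncol = 4)
    fe <- feve(p)
    expect_true(fe >= 0 && fe <= 1)
  }
})

test_that("nearest-neighbour distances match enumerated line cases", {
  expect_equal(nnd(cbind(0:3, 0)), c(mNND = 1, sdNND = 0))
  expect_equal(nnd(cbind(c(0, 7), 0)), c(mNND = 7, sdNND = 0))
  # {0,1,5}: NN distances {1,1,4}, mean 2, sd sqrt(3)
  expect_equal(nnd(cbind(c(0, 1, 5), 0)), c(mNND = 2, sdNND = sqrt(3)))
  expect_error(nnd(cbind(1, 1)), "2 species")
})

test_that("nnd agrees with a direct R computation and duplicate points
           cannot increase mNND", {
  set.seed(51)
  p <- matrix(rnorm(20 * 3), ncol = 3)
  dm <- as.matrix(dist(p)); diag(dm) <- Inf
  nn <- apply(dm, 1, min)
  expect_equal(nnd(p), c(mNND = mean(nn), sdNND = sd(nn)))
  # duplicating a point gives it NN distance 0
  expect_lte(nnd(rbind(p, p[1, ]))[["mNND"]], nnd(p)[["mNND"]])
})

test_that("interior points never increase mNND under hull invariance", {
  set.seed(61)
  p <- unit_square() * 10
  inside <- c(5, 5)
  expect_equal(as.numeric(fric(rbind(p, inside))), as.numeric(fric(p)))
  expect_lte(nnd(rbind(p, inside))[["mNND"]], nnd(p)[["mNND"]])
})

test_that("2-D hypervolume is grid-consistent and scales as c^2", {
  set.seed(71)
  p <- matrix(rnorm(25 * 2, sd = c(1, 0.5)), ncol = 2, byrow = TRUE)
  a200 <- as.numeric(hypervolume2d(p, grid_n = 200))
  a400 <- as.numeric(hypervolume2d(p, grid_n = 400))
  expect_lt(abs(a200 - a400) / a400, 0.02)
  # dimensional analysis: Silverman bandwidths scale with the data
  a_sc <- as.numeric(hypervolume2d(3 * p, grid_n = 200))
  expect_equal(a_sc, 9 * a200, tolerance = 0.01)
})

test_that("2-D hypervolume is additive over distant modes at fixed
           bandwidth", {
  set.seed(81)
  cl <- matrix(rnorm(30 * 2, sd = 0.1), ncol = 2)
  bw <- c(0.05, 0.05)
  one <- as.numeric(hypervolume2d(cl, bw = bw, grid_n = 400))
  two <- as.numeric(hypervolume2d(rbind(cl, sweep(cl, 2, c(5, 0), "+")),
                                  bw = bw, grid_n = 400))
  expect_equal(two, 2 * one, tolerance = 0.05)
  expect_error(hypervolume2d(cl[1:2, ]), "3 species")
})
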