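test_that("Gower dissimilarity matches the hand-computed mixed-scale case", {
  tt <- two_species_traits()
  D <- gower_dissimilarity(tt)
  # (rhizome 0 + dissection 2/2 + texture 2/2 + length 20/20 + hyd 1)/5
  expect_equal(D["A", "B"], 0.8)
  expect_equal(diag(unclass(D)), c(A = 0, B = 0))

  # identical species have zero dissimilarity
  tt2 <- make_traits(data.frame(
    rhizome_type = c(2, 2, 1), laminar_dissection = c(1, 1, 0),
    laminar_texture = c(2, 2, 1), laminar_length = c(20, 20, 10),
    hydathodes = c(1, 1, 0), row.names = c("A", "B", "C")))
  D2 <- gower_dissimilarity(tt2)
  expect_equal(D2["A", "B"], 0)

  # maximal difference in every trait reaches the upper bound 1
  tt3 <- make_traits(data.frame(
    rhizome_type = c(0, 3), laminar_dissection = c(0, 2),
    laminar_texture = c(1, 3), laminar_length = c(10, 30),
    hydathodes = c(0, 1), row.names = c("A", "B")))
  expect_equal(gower_dissimilarity(tt3)["A", "B"], 1)
})

test_that("Gower is symmetric, zero-diagonal and bounded on random tables", {
  set.seed(3)
  for (r in 1:5) {
    cfg <- sim_config(n_species_pool = 25, peak_richness = 10)
    tt <- gen_trait_table(cfg)
    D <- unclass(gower_dissimilarity(tt))
    expect_equal(D, t(D))
    expect_equal(diag(D), setNames(rep(0, 25), rownames(tt)))
    expect_true(all(D >= 0 & D <= 1))
  }
})

test_that("Gower agrees with an independent mixed-variable implementation", {
  skip_if_not_installed("cluster")
  set.seed(5)
  cfg <- sim_config(n_species_pool = 30, peak_richness = 10)
  tt <- gen_trait_table(cfg)
  # force full realized ranges so daisy's observed-range normalization
  # coincides with the declared-domain normalization used here
  tt$laminar_dissection[1:3] <- c(0, 1, 2)
  tt$laminar_texture[1:3] <- c(1, 2, 3)
  tt <- trait_table(as.data.frame(tt), species_ids = rownames(tt))
  df <- data.frame(rhizome_type = factor(tt$rhizome_type),
                   laminar_dissection = as.numeric(tt$laminar_dissection),
                   laminar_texture = as.numeric(tt$laminar_texture),
                   laminar_length = tt$laminar_length,
                   hydathodes = factor(tt$hydathodes))
  Dd <- as.matrix(cluster::daisy(df, metric = "gower"))
  D <- gower_dissimilarity(tt)
  expect_equal(unname(unclass(D)), unname(Dd), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("constant traits are flagged; all-constant tables error", {
  tt <- make_traits(data.frame(
    rhizome_type = c(1, 2, 3), laminar_dissection = c(0, 1, 2),
    laminar_texture = c(1, 2, 3), laminar_length = c(10, 10, 10),
    hydathodes = c(0, 1, 0), row.names = c("A", "B", "C")))
  expect_warning(D <- gower_dissimilarity(tt), "zero-range")
  expect_equal(attr(D, "constant_traits"), "laminar_length")
  expect_true(all(unclass(D) <= 1))
  ttc <- make_traits(data.frame(
    rhizome_type = c(1, 1), laminar_dissection = c(1, 1),
    laminar_texture = c(2, 2), laminar_length = c(10, 10),
    hydathodes = c(0, 0), row.names = c("A", "B")))
  expect_error(suppressWarnings(gower_dissimilarity(ttc)), "constant")
})

test_that("PCoA on Euclidean distances reproduces the input distances", {
  # unit square: 2 positive eigenvalues, distances recovered exactly
  p <- unit_square()
  D <- as.matrix(dist(p))
  ord <- trait_pcoa(D, n_axes = 2)
  expect_equal(length(ord$eig), 2)
  expect_equal(as.matrix(dist(ord$points)), D, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(colMeans(ord$points), c(PCo1 = 0, PCo2 = 0),
               tolerance = 1e-10)

  # random Euclidean configuration in 4-D
  set.seed(8)
  q <- matrix(rnorm(15 * 4), ncol = 4)
  Dq <- as.matrix(dist(q))
  ordq <- trait_pcoa(Dq, n_axes = 4)
  expect_equal(as.matrix(dist(ordq$points)), Dq, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCoA handles simplex and collinear configurations", {
  # regular simplex: all positive eigenvalues equal
  D <- matrix(1, 4, 4); diag(D) <- 0
  ord <- trait_pcoa(D, n_axes = 3)
  expect_equal(ord$eig, rep(ord$eig[1], 3), tolerance = 1e-8)

  # 3 collinear points: a single positive eigenvalue carries everything
  Dc <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  expect_warning(ordc <- trait_pcoa(Dc, n_axes = 2), "positive")
  expect_equal(length(ordc$eig), 1)
  expect_equal(ordc$cum_var[1], 1)
  expect_true(ordc$truncated)

  expect_error(trait_pcoa(Dc, n_axes = 3), "S - 1")
})

test_that("negative PCoA eigenvalues are discarded and counted", {
  set.seed(13)
  cfg <- sim_config(n_species_pool = 40, peak_richness = 10)
  D <- gower_dissimilarity(gen_trait_table(cfg))
  ord <- trait_pcoa(D, n_axes = 5)
  expect_true(ord$n_negative > 0)  # Gower on mixed traits is non-Euclidean
  expect_true(all(diff(ord$eig) <= 1e-12))
  expect_true(all(ord$rel_eig >= 0 & ord$rel_eig <= 1))
  expect_true(all(diff(ord$cum_var) >= -1e-12))
  # coordinates reproduce distances only up to the discarded axes,
  # but are exactly centered
  expect_equal(unname(colMeans(ord$points)), rep(0, 5), tolerance = 1e-9)
})
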