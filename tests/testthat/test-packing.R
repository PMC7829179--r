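test_that("pair ordering walks from the extremes to the richness peak", {
  pr <- order_packing_pairs(stub_assemblages(c(10, 30, 50, 40, 20)))
  expect_setequal(pr$pair, c("II-I", "III-II", "III-IV", "IV-V"))
  expect_true(all(pr$S1 > pr$S2))
  expect_equal(pr$status, rep("ok", 4))

  # monotone richness: peak at the top
  pr2 <- order_packing_pairs(stub_assemblages(c(5, 10, 15)))
  expect_setequal(pr2$pair, c("II-I", "III-II"))

  # equal richness: decomposition impossible
  pr3 <- order_packing_pairs(stub_assemblages(c(8, 8)))
  expect_equal(pr3$status, "none")

  expect_error(order_packing_pairs(stub_assemblages(7)), "2 assemblages")
})

test_that("pure packing: interior additions require no removal", {
  E2 <- unit_square()
  E1 <- rbind(E2, c(0.5, 0.5), c(0.3, 0.4), c(0.6, 0.2))
  d <- decompose_packing(E1, E2, seed = 1)
  expect_equal(d$expansion, 0)
  expect_equal(d$packing, 3)
  expect_equal(d$packing_pct, 100)
  expect_equal(d$expansion + d$packing, d$delta_S)
})

test_that("pure expansion: distant outliers are all removed", {
  E2 <- rbind(c(0, 0), c(1, 0), c(0, 1))
  E1 <- rbind(E2, c(10, 10), c(11, 10), c(10, 11))
  d <- decompose_packing(E1, E2, seed = 2)
  expect_equal(d$expansion, 3)
  expect_equal(d$packing, 0)
  expect_equal(d$expansion_pct, 100)
  # exhaustive oracle confirms 3 retained species is optimal
  expect_equal(best_subset_size(E1, d$volume_e2), 3)
})

test_that("mixed case: nested squares match the exhaustive optimum", {
  inner <- unit_square()
  outer <- (unit_square() - 0.5) * 2 + 0.5   # scaled x2 about the center
  E1 <- rbind(outer, inner, c(0.5, 0.5))     # 9 points
  E2 <- inner
  d <- decompose_packing(E1, E2, n_starts = 10, seed = 3)
  # brute force over all 2^9 subsets: the best volume-feasible subset
  # keeps 6 species (five on the main diagonal are collinear, so e.g.
  # both diagonal outer corners plus an inner corner fit in area 1),
  # hence expansion 3 / packing 2
  expect_equal(best_subset_size(E1, d$volume_e2), 6)
  expect_equal(d$expansion, 3)
  expect_equal(d$packing, 2)
  expect_equal(d$expansion + d$packing, d$delta_S)
  expect_lte(d$achieved_volume, d$volume_e2 * 1.01)
})

test_that("greedy decomposition stays within one species of the
           exhaustive optimum on random instances", {
  set.seed(2024)
  worst <- 0
  for (r in 1:200) {
    S1 <- sample(6:12, 1)
    S2 <- sample(3:(S1 - 1), 1)
    E1 <- matrix(runif(S1 * 2), ncol = 2)
    E2 <- matrix(runif(S2 * 2), ncol = 2)
    v2 <- convhull_volume(E2)$volume
    if (v2 <= 0) next
    d <- decompose_packing(E1, E2, n_starts = 10)
    expect_equal(d$expansion + d$packing, d$delta_S)  # conservation
    opt <- best_subset_size(E1, v2)
    gap <- opt - length(d$retained)
    expect_gte(gap, 0)       # greedy can never beat the exhaustive bound
    expect_lte(gap, 1)
    worst <- max(worst, gap)
  }
  expect_lte(worst, 1)
})

test_that("decomposition counts are invariant to a common rescaling", {
  set.seed(77)
  E1 <- matrix(runif(20), ncol = 2)
  E2 <- matrix(runif(10), ncol = 2)
  d1 <- decompose_packing(E1, E2, n_starts = 5, seed = 5)
  d2 <- decompose_packing(3.7 * E1, 3.7 * E2, n_starts = 5, seed = 5)
  expect_equal(d1$expansion, d2$expansion)
  expect_equal(d1$packing, d2$packing)
})

test_that("degenerate targets and misordered pairs raise errors", {
  E2 <- cbind(0:2, 0)                     # collinear: zero area
  E1 <- matrix(runif(12), ncol = 2)
  expect_error(decompose_packing(E1, E2, k = 2), "degenerate")
  expect_error(decompose_packing(E2, E1), "richer")
})

test_that("transect-level decomposition conserves species counts", {
  set.seed(87)
  cfg <- sim_config(n_species_pool = 50, peak_richness = 25)
  tt <- gen_trait_table(cfg)
  comm <- gen_transect(cfg, tt)
  asm <- bin_plots_to_intervals(comm)
  ord <- trait_pcoa(gower_dissimilarity(tt), n_axes = 5)
  pk <- packing_transect(asm, ord, seed = 6)
  ok <- pk$status == "ok"
  expect_true(any(ok))
  expect_equal(pk$expansion[ok] + pk$packing[ok], pk$S1[ok] - pk$S2[ok])
  expect_equal(pk$expansion_pct[ok] + pk$packing_pct[ok],
               rep(100, sum(ok)))
})
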