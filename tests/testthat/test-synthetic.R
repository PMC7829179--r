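test_that("trait marginals match their configured probabilities at large
           n", {
  cfg <- sim_config(n_species_pool = 10000, peak_richness = 50)
  tt <- gen_trait_table(cfg, seed = 1)
  f_rhiz <- tabulate(tt$rhizome_type + 1, 4) / 10000
  expect_true(all(abs(f_rhiz - cfg$p_rhizome) < 0.02))
  f_tex <- tabulate(tt$laminar_texture, 3) / 10000
  expect_true(all(abs(f_tex - cfg$p_texture) < 0.02))
  expect_lt(abs(mean(tt$hydathodes) - cfg$p_hydathodes), 0.02)
  expect_true(all(tt$laminar_length >= 1 & tt$laminar_length <= 600))
})

test_that("the generator is deterministic given a seed", {
  cfg <- sim_config(n_species_pool = 30, peak_richness = 15)
  t1 <- gen_trait_table(cfg, seed = 5)
  t2 <- gen_trait_table(cfg, seed = 5)
  expect_identical(t1, t2)
  c1 <- gen_transect(cfg, t1, seed = 6)
  c2 <- gen_transect(cfg, t1, seed = 6)
  expect_identical(c1$incidence, c2$incidence)
  s1 <- simulate_fourtransects(seed = 9, scale = 0.15)
  s2 <- simulate_fourtransects(seed = 9, scale = 0.15)
  expect_identical(s1$traits, s2$traits)
  expect_identical(s1$community$incidence, s2$community$incidence)

  # degenerate marginal: constant trait column
  cfgc <- sim_config(n_species_pool = 10, peak_richness = 5,
                     p_texture = c(1, 0, 0))
  ttc <- gen_trait_table(cfgc, seed = 2)
  expect_true(all(ttc$laminar_texture == 1))
})

test_that("pure-birth trees are binary with Brownian traits of the right
           scale", {
  cfg <- sim_config(n_species_pool = 32, sigma2_bm = 2)
  pb <- gen_phylo_bm(cfg, seed = 3)
  expect_true(ape::is.binary(pb$tree))
  expect_equal(pb$tree$Nnode, 31)         # n - 1 internal bifurcations
  expect_setequal(names(pb$trait), pb$tree$tip.label)

  # E[squared standardized contrast] = sigma2 under Brownian motion
  set.seed(4)
  pv <- replicate(100, {
    p <- gen_phylo_bm(cfg)
    mean(ape::pic(p$trait[p$tree$tip.label], p$tree)^2)
  })
  expect_lt(abs(mean(pv) - cfg$sigma2_bm) / cfg$sigma2_bm, 0.1)

  # zero rate: every tip keeps the root value
  pb0 <- gen_phylo_bm(sim_config(n_species_pool = 10, sigma2_bm = 0),
                      seed = 5)
  expect_true(all(pb0$trait == 0))
})

test_that("interval richness follows the imposed hump", {
  cfg <- sim_config(n_species_pool = 100, peak_richness = 40,
                    peak_elevation = 1450, hump_width = 900,
                    elev_range = c(200, 2900))
  tt <- gen_trait_table(cfg, seed = 7)
  comm <- gen_transect(cfg, tt, seed = 8)
  tab <- assemblage_table(bin_plots_to_intervals(comm))
  mids <- (tab$lower + tab$upper) / 2
  target <- pmin(pmax(round(40 * exp(-(mids - 1450)^2 / (2 * 900^2))),
                      cfg$min_richness), 100)
  expect_equal(tab$S, target)
  expect_equal(tab$n_plots, rep(4, nrow(tab)))
  # hump shape: interior maximum
  expect_gt(max(tab$S), tab$S[1])
  expect_gt(max(tab$S), tab$S[nrow(tab)])
})

test_that("filtering at phi = 1 clusters co-occurring morphologies", {
  cfg0 <- sim_config(n_species_pool = 80, peak_richness = 25, phi = 0)
  cfg1 <- sim_config(n_species_pool = 80, peak_richness = 25, phi = 1,
                     tau = 100)
  tt <- gen_trait_table(cfg0, seed = 11)
  ord <- trait_pcoa(gower_dissimilarity(tt), n_axes = 5)
  set.seed(12)
  mean_ses <- function(cfg) {
    v <- replicate(10, {
      asm <- bin_plots_to_intervals(gen_transect(cfg, tt))
      r <- ses(asm, ord, index = "mNND", n_reps = 199)
      mean(r$ses[r$flag == "ok"])
    })
    mean(v)
  }
  expect_lt(mean_ses(cfg1), mean_ses(cfg0) - 0.5)
})

test_that("climate covariates follow their construction", {
  cfg <- sim_config(elev_range = c(200, 2900))
  cl <- gen_climate(cfg, seed = 13)
  expect_equal(nrow(cl), nrow(assemblage_table(
    bin_plots_to_intervals(gen_transect(cfg, gen_trait_table(cfg,
                                                             seed = 1),
                                        seed = 2)))))
  # lapse: 26 degC at sea level, 20.5 at 1000 m
  expect_equal(cl$MAT, 26 - 5.5 * cl$mid / 1000)
  expect_gt(cor(cl$bryophyte_cover, cl$mid, method = "spearman"), 0.99)
  expect_true(all(diff(cl$lower) == 500 | diff(cl$lower) == 400))
})

test_that("four-transect preset reproduces contrasting richness
           magnitudes", {
  sim <- simulate_fourtransects(seed = 21, scale = 0.3)
  tab <- assemblage_table(bin_plots_to_intervals(sim$community))
  expect_setequal(unique(tab$transect), c("ECU", "MX", "PNG", "UG"))
  peak <- tapply(tab$S, tab$transect, max)
  expect_gt(peak[["ECU"]], peak[["MX"]])
  expect_gt(peak[["PNG"]], peak[["UG"]])
  # generated objects pass the io validation invariants
  expect_true(all(colSums(sim$community$incidence) > 0))
  expect_s3_class(sim$traits, "trait_table")
})
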