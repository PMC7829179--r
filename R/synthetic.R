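#' Simulation configuration for one elevational transect
#'
#' Bundles the parameters of the synthetic generator: pool size, the
#' elevational extent and banding, the Gaussian richness hump (richness is
#' imposed per interval, not emergent), the environmental-filtering
#' strength, trait marginals, and the phylogeny/Brownian-motion rates.
#'
#' Filtering: each species gets an optimal elevation tied to a latent
#' morphological axis (standardized laminar texture + log laminar
#' length), and membership of an interval is drawn without replacement
#' with weight `(1 - phi) + phi * exp(-(opt - mid)^2 / (2 tau^2))`.  At
#' `phi = 0` assembly is uniform (the null world: trait labels are
#' exchangeable by construction); at `phi = 1` with small `tau`,
#' co-occurring species share similar morphologies, giving the
#' trait-clustering signal the SES analysis is designed to detect.
#'
#' @param n_species_pool species pool size for the transect.
#' @param transect transect label.
#' @param elev_range numeric length-2: lowest/highest plot elevation (m).
#' @param peak_richness,peak_elevation,hump_width Gaussian richness hump:
#'   interval target richness is
#'   `round(peak_richness * exp(-(mid - peak_elevation)^2 /
#'   (2 hump_width^2)))`, floored at `min_richness` and capped at the
#'   pool size.
#' @param min_richness richness floor per interval (default 5).
#' @param phi environmental filtering strength in \[0, 1\].
#' @param tau elevational niche width of the filter (m, default 300).
#' @param plots_per_interval plots per 500-m band (default 4).
#' @param p_rhizome,p_dissection,p_texture category probabilities for the
#'   categorical/ordinal traits (codes 0:3, 0:2, 1:3).
#' @param p_hydathodes presence probability of hydathodes.
#' @param length_meanlog,length_sdlog log-normal parameters for laminar
#'   length (cm); draws are truncated to \[1, 600\].
#' @param birth_rate speciation rate of the pure-birth tree.
#' @param sigma2_bm Brownian-motion rate for the continuous tip trait.
#' @param width,first_bound elevational banding (default 500-m bands
#'   after a 0--400 m first band).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species_pool = 100, transect = "T1",
                       elev_range = c(200, 2900),
                       peak_richness = min(40, n_species_pool),
                       peak_elevation = 1450,
                       hump_width = 900, min_richness = 5,
                       phi = 0, tau = 300, plots_per_interval = 4,
                       p_rhizome = c(0.05, 0.50, 0.40, 0.05),
                       p_dissection = c(0.25, 0.35, 0.40),
                       p_texture = c(0.30, 0.45, 0.25),
                       p_hydathodes = 0.3,
                       length_meanlog = log(30), length_sdlog = 0.8,
                       birth_rate = 1, sigma2_bm = 1,
                       width = 500, first_bound = 400) {
  stopifnot(phi >= 0, phi <= 1, tau > 0,
            abs(sum(p_rhizome) - 1) < 1e-8,
            abs(sum(p_dissection) - 1) < 1e-8,
            abs(sum(p_texture) - 1) < 1e-8,
            p_hydathodes >= 0, p_hydathodes <= 1,
            peak_richness <= n_species_pool)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic species-by-trait table
#'
#' Independent draws per trait from the configured marginals; laminar
#' length is log-normal truncated to \[1, 600\] cm.  Fully deterministic
#' given the RNG state (or `seed`).
#'
#' @param cfg a [sim_config()].
#' @param species_ids optional ids (default `sp001`, ...; prefixed by the
#'   transect label when `prefix = TRUE`).
#' @param prefix prefix ids with the transect label (default FALSE).
#' @param seed optional integer seed.
#' @return A [trait_table()].
#' @export
gen_trait_table <- function(cfg, species_ids = NULL, prefix = FALSE,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_species_pool
  if (is.null(species_ids)) {
    species_ids <- sprintf("sp%03d", seq_len(n))
    if (prefix) species_ids <- paste(cfg$transect, species_ids, sep = "_")
  }
  len <- rlnorm(n, cfg$length_meanlog, cfg$length_sdlog)
  len <- pmin(pmax(len, 1), 600)
  df <- data.frame(
    rhizome_type = sample(0:3, n, replace = TRUE, prob = cfg$p_rhizome),
    laminar_dissection = sample(0:2, n, replace = TRUE,
                                prob = cfg$p_dissection),
    laminar_texture = sample(1:3, n, replace = TRUE, prob = cfg$p_texture),
    laminar_length = len,
    hydathodes = rbinom(n, 1, cfg$p_hydathodes))
  trait_table(df, species_ids = species_ids)
}

#' Generate a pure-birth tree with a Brownian tip trait
#'
#' Constant-rate pure-birth (Yule) tree with `n_species_pool` tips and a
#' continuous trait evolved along it by Brownian motion with rate
#' `sigma2_bm` from a root value of 0.
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return A list with `tree` (a `phylo`, tips `sp001`...) and `trait`
#'   (named numeric vector per tip).
#' @export
gen_phylo_bm <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_species_pool
  if (n < 4) stop("at least 4 tips are required")
  tree <- rphylo(n, birth = cfg$birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n))
  trait <- rTraitCont(tree, model = "BM", sigma = sqrt(cfg$sigma2_bm),
                      root.value = 0)
  list(tree = tree, trait = trait)
}

interval_grid <- function(cfg) {
  lo <- cfg$elev_range[1]; hi <- cfg$elev_range[2]
  bounds <- c(0, cfg$first_bound,
              seq(cfg$first_bound + cfg$width,
                  cfg$first_bound + 20 * cfg$width, by = cfg$width))
  keep <- which(bounds[-length(bounds)] < hi & bounds[-1] > lo)
  data.frame(lower = bounds[keep], upper = bounds[keep + 1],
             mid = (bounds[keep] + bounds[keep + 1]) / 2)
}

species_opt_elevation <- function(cfg, traits, mids) {
  latent <- as.numeric(scale(traits$laminar_texture)) +
    as.numeric(scale(log(traits$laminar_length)))
  r <- rank(latent, ties.method = "first")
  lo <- min(mids); hi <- max(mids)
  lo + (r - 0.5) / nrow(traits) * (hi - lo)
}

#' Generate one transect's elevational community
#'
#' Per interval, a target richness is read off the configured Gaussian
#' hump, members are drawn from the pool with the filtering weights (see
#' [sim_config()]), and each member is placed in 1 to 4 of the interval's
#' plots (more often few, so that Chao2's uniques/duplicates structure is
#' realistic).  Richness per interval is imposed by construction.
#'
#' @param cfg a [sim_config()].
#' @param traits the pool's [trait_table()] (its morphology drives the
#'   filter at `phi > 0`).
#' @param seed optional integer seed.
#' @return A [community_data()] for the transect.
#' @export
gen_transect <- function(cfg, traits, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(traits, "trait_table"),
            nrow(traits) == cfg$n_species_pool)
  ivl <- interval_grid(cfg)
  pool <- rownames(traits)
  opt <- species_opt_elevation(cfg, traits, ivl$mid)
  plot_rows <- list(); inc_rows <- list()
  offs <- seq(-150, 150, length.out = cfg$plots_per_interval)
  for (i in seq_len(nrow(ivl))) {
    mid <- ivl$mid[i]
    target <- round(cfg$peak_richness *
                      exp(-(mid - cfg$peak_elevation)^2 /
                            (2 * cfg$hump_width^2)))
    target <- min(max(target, cfg$min_richness), length(pool))
    w <- (1 - cfg$phi) +
      cfg$phi * exp(-(opt - mid)^2 / (2 * cfg$tau^2))
    members <- sample(pool, target, prob = w)
    elevs <- pmin(pmax(mid + offs, ivl$lower[i]), ivl$upper[i] - 1)
    inc <- matrix(0L, cfg$plots_per_interval, length(pool),
                  dimnames = list(NULL, pool))
    for (sp in members) {
      n_occ <- sample.int(cfg$plots_per_interval, 1,
                          prob = c(0.35, 0.30, 0.20,
                                   0.15)[seq_len(cfg$plots_per_interval)])
      inc[sample.int(cfg$plots_per_interval, n_occ), sp] <- 1L
    }
    ids <- sprintf("%s_%s_p%d", cfg$transect,
                   as.character(as.roman(i)),
                   seq_len(cfg$plots_per_interval))
    plot_rows[[i]] <- data.frame(plot_id = ids, elevation_m = elevs,
                                 stringsAsFactors = FALSE)
    inc_rows[[i]] <- inc
  }
  plots <- do.call(rbind, plot_rows)
  incidence <- do.call(rbind, inc_rows)
  rownames(incidence) <- plots$plot_id
  community_data(incidence, elevation_m = plots$elevation_m,
                 transect = cfg$transect, plot_ids = plots$plot_id)
}

#' Generate per-interval climate covariates
#'
#' Mean annual temperature decreases linearly with elevation (5.5 degC/km
#' lapse from a 26 degC base), annual precipitation is unimodal,
#' temperature/precipitation seasonality are constants plus noise, and
#' bryophyte cover (the air-humidity proxy) increases sigmoidally with
#' elevation.  Deterministic given the RNG state (or `seed`).
#'
#' @param cfg a [sim_config()].
#' @param lapse_rate temperature lapse rate (degC per km, default 5.5).
#' @param base_temp sea-level mean annual temperature (degC, default 26).
#' @param seed optional integer seed.
#' @return data.frame, one row per interval: transect, interval, lower,
#'   upper, mid, MAT, TS, AP, PS, bryophyte_cover.
#' @export
gen_climate <- function(cfg, lapse_rate = 5.5, base_temp = 26,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ivl <- interval_grid(cfg)
  n <- nrow(ivl)
  data.frame(
    transect = cfg$transect,
    interval = as.character(as.roman(
      ifelse(ivl$lower < cfg$first_bound, 1,
             2 + (ivl$lower - cfg$first_bound) %/% cfg$width))),
    lower = ivl$lower, upper = ivl$upper, mid = ivl$mid,
    MAT = base_temp - lapse_rate * ivl$mid / 1000,
    TS = 650 + rnorm(n, 0, 25),
    AP = 1200 + 1800 * exp(-(ivl$mid - 1200)^2 / (2 * 900^2)) +
      rnorm(n, 0, 50),
    PS = 45 + rnorm(n, 0, 5),
    bryophyte_cover = 100 / (1 + exp(-(ivl$mid - 1500) / 400)),
    stringsAsFactors = FALSE)
}

#' Simulate a four-transect study
#'
#' Generates four transects with contrasting pool sizes, elevational
#' extents and hump-shaped richness gradients (magnitudes modelled on
#' diverse Andean/New Guinean versus poorer Mexican/Ugandan fern
#' transects), one combined trait table over all pools, and the pooled
#' community and climate tables.
#'
#' @param seed integer seed (required: the simulation is defined by it).
#' @param phi filtering strength shared by all transects (default 0).
#' @param scale optional multiplier (0 < scale <= 1) on pool sizes and
#'   peak richness, for quick smaller runs.
#' @return A list with `traits` (combined [trait_table()]), `community`
#'   (single [community_data()] with 4 transects), `climate` (stacked
#'   covariate table), and `configs`.
#' @export
simulate_fourtransects <- function(seed, phi = 0, scale = 1) {
  set.seed(seed)
  stopifnot(scale > 0, scale <= 1)
  sz <- function(x) max(8, round(x * scale))
  cfgs <- list(
    ECU = sim_config(n_species_pool = sz(343), transect = "ECU",
                     elev_range = c(500, 4050), peak_richness = sz(120),
                     peak_elevation = 2150, hump_width = 1100, phi = phi),
    MX = sim_config(n_species_pool = sz(97), transect = "MX",
                    elev_range = c(300, 3000), peak_richness = sz(33),
                    peak_elevation = 1650, hump_width = 1000, phi = phi),
    PNG = sim_config(n_species_pool = sz(198), transect = "PNG",
                     elev_range = c(200, 3700), peak_richness = sz(62),
                     peak_elevation = 1150, hump_width = 1500, phi = phi),
    UG = sim_config(n_species_pool = sz(76), transect = "UG",
                    elev_range = c(700, 3200), peak_richness = sz(31),
                    peak_elevation = 1650, hump_width = 800, phi = phi))
  traits_list <- list(); comm_list <- list(); clim_list <- list()
  for (nm in names(cfgs)) {
    cfg <- cfgs[[nm]]
    tt <- gen_trait_table(cfg, prefix = TRUE)
    comm <- gen_transect(cfg, tt)
    traits_list[[nm]] <- tt
    comm_list[[nm]] <- comm
    clim_list[[nm]] <- gen_climate(cfg)
  }
  all_traits <- do.call(rbind, lapply(traits_list, as.data.frame))
  ids <- unlist(lapply(traits_list, rownames), use.names = FALSE)
  traits <- trait_table(all_traits, species_ids = ids)
  # stack the four communities over the union of species
  all_sp <- unlist(lapply(comm_list, function(cm) cm$species_ids),
                   use.names = FALSE)
  inc_list <- lapply(comm_list, function(cm) {
    m <- matrix(0L, nrow(cm$incidence), length(all_sp),
                dimnames = list(rownames(cm$incidence), all_sp))
    m[, colnames(cm$incidence)] <- cm$incidence
    m
  })
  incidence <- do.call(rbind, inc_list)
  plots <- do.call(rbind, lapply(comm_list, function(cm) cm$plots))
  community <- community_data(incidence, elevation_m = plots$elevation_m,
                              transect = plots$transect,
                              plot_ids = plots$plot_id)
  list(traits = traits, community = community,
       climate = do.call(rbind, clim_list), configs = cfgs)
}
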