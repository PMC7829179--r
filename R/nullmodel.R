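#' Randomize species labels on the trait table
#'
#' Returns a trait table whose species ids are a uniform random
#' permutation of the originals over the unchanged trait rows.  Community
#' membership is untouched, so richness patterns, range contiguity, trait
#' co-variances and overall phenotypes are all preserved; only the
#' species-to-phenotype assignment is broken.
#'
#' @param traits a [trait_table()].
#' @return A [trait_table()] with permuted species ids.
#' @export
shuffle_trait_labels <- function(traits) {
  stopifnot(inherits(traits, "trait_table"))
  ids <- rownames(traits)
  perm <- sample(length(ids))
  out <- traits
  rownames(out) <- ids[perm]
  out
}

index_fun <- function(index, k, hyp_mass) {
  switch(index,
    FRic = function(p) as.numeric(fric(p, k = k)),
    Hyp = function(p) as.numeric(hypervolume2d(p[, 1:2, drop = FALSE],
                                               mass = hyp_mass)),
    FEve = function(p) feve(p),
    mNND = function(p) unname(nnd(p)[1]),
    sdNND = function(p) unname(nnd(p)[2]),
    stop("unknown index: ", index))
}

index_min_S <- c(FRic = 2, Hyp = 3, FEve = 3, mNND = 2, sdNND = 2)

#' Standardized effect sizes under trait-label randomization
#'
#' For each replicate a single global permutation of species labels is
#' drawn (shared across all assemblages, preserving cross-assemblage trait
#' co-variance) and each assemblage's index recomputed.  Because Gower +
#' PCoA are label-independent, shuffling trait labels is equivalent to
#' permuting the rows of the observed ordination, so the ordination is
#' computed once and reused.  SES = (obs - null mean)/null sd; the
#' two-sided p-value uses the rank of the observed value among null +
#' observed, `p = 2 min(r_lo, r_up)/(n_reps + 1)` capped at 1, where
#' `r_lo = 1 + #\{null <= obs\}` and `r_up = 1 + #\{null >= obs\}`.
#'
#' @param assemblages list of assemblages ([bin_plots_to_intervals()]) or
#'   named list of species-id vectors.
#' @param ord an `ordination`; its rows define the randomization pool
#'   (pass the per-transect ordination for a per-transect pool, the global
#'   one for a global pool).
#' @param index one of `"FRic"`, `"Hyp"`, `"FEve"`, `"mNND"`, `"sdNND"`.
#' @param n_reps number of null replicates (study settings: 5000 for all
#'   indices, 500 for Hyp; a warning is issued below 100).
#' @param k leading axes for FRic/FEve/NND (default 5); Hyp always uses 2.
#' @param hyp_mass probability mass for [hypervolume2d()].
#' @param seed optional integer seed for the permutation stream.
#' @return data.frame of class `ses_result`: assemblage, index, S, obs,
#'   null_mean, null_sd, ses, p, n_reps, flag (`"ok"`, `"undefined"` when
#'   the index needs more species, `"zero_sd"` when every permutation
#'   yields the same value, e.g. an assemblage holding the whole pool).
#' @export
ses <- function(assemblages, ord, index = "mNND", n_reps = 999, k = 5,
                hyp_mass = 0.95, seed = NULL) {
  index <- match.arg(index, names(index_min_S))
  if (n_reps < 1) stop("n_reps must be positive")
  if (n_reps < 100)
    warning("n_reps < 100: null distribution will be poorly resolved")
  if (!is.null(seed)) set.seed(seed)
  pool <- rownames(ord$points)
  n_pool <- length(pool)
  k_eff <- if (index == "Hyp") 2L else min(k, ncol(ord$points))
  coords <- ord$points[, seq_len(k_eff), drop = FALSE]
  storage.mode(coords) <- "double"

  info <- lapply(seq_along(assemblages), function(i) {
    a <- assemblages[[i]]
    if (inherits(a, "interval_assemblage")) {
      sp <- a$species
      id <- paste(a$transect, as.character(a$interval), sep = ":")
    } else {
      sp <- a
      id <- if (!is.null(names(assemblages))) names(assemblages)[i]
            else paste0("A", i)
    }
    miss <- setdiff(sp, pool)
    if (length(miss))
      stop("species absent from the ordination pool: ",
           paste(head(miss, 5), collapse = ", "))
    list(id = id, idx = match(sp, pool), S = length(sp))
  })

  # one global permutation per replicate, drawn sequentially from the
  # seeded stream so results are reproducible and order-independent
  perms <- matrix(0L, n_reps, n_pool)
  for (r in seq_len(n_reps)) perms[r, ] <- sample.int(n_pool)

  fun <- index_fun(index, k = k_eff, hyp_mass = hyp_mass)
  fast_nnd <- index %in% c("mNND", "sdNND")
  rows <- lapply(info, function(a) {
    if (a$S < index_min_S[[index]])
      return(data.frame(assemblage = a$id, index = index, S = a$S,
                        obs = NA_real_, null_mean = NA_real_,
                        null_sd = NA_real_, ses = NA_real_, p = NA_real_,
                        n_reps = n_reps, flag = "undefined",
                        stringsAsFactors = FALSE))
    cc <- coords  # axis reduction for small S happens inside fric()
    obs <- fun(cc[a$idx, , drop = FALSE])
    if (fast_nnd) {
      null <- .nnd_null_cpp(cc, perms[, a$idx, drop = FALSE])
      null <- null[, if (index == "mNND") 1 else 2]
    } else {
      null <- vapply(seq_len(n_reps), function(r)
        fun(cc[perms[r, a$idx], , drop = FALSE]), 0)
    }
    nm <- mean(null); nsd <- sd(null)
    # guard against pure summation-order noise (e.g. an assemblage
    # holding the whole pool: every permutation gives the same point set)
    if (nsd < 1e-10 * max(1, abs(nm))) nsd <- 0
    if (nsd == 0) {
      sesv <- NA_real_; p <- NA_real_; flag <- "zero_sd"
    } else {
      sesv <- (obs - nm) / nsd
      r_lo <- 1 + sum(null <= obs)
      r_up <- 1 + sum(null >= obs)
      p <- min(1, 2 * min(r_lo, r_up) / (n_reps + 1))
      flag <- "ok"
    }
    data.frame(assemblage = a$id, index = index, S = a$S, obs = obs,
               null_mean = nm, null_sd = nsd, ses = sesv, p = p,
               n_reps = n_reps, flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ses_result", "data.frame")
  out
}
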