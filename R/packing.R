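#' Order adjacent assemblage pairs toward the richness peak
#'
#' Species richness along a transect is hump-shaped, so a directionality
#' is defined from both elevational extremes toward the interval where
#' richness peaks.  Walking in that direction, every adjacent pair is
#' emitted with the richer member as E1 and the poorer as E2; pairs with
#' equal richness get status `"none"` (no decomposition is possible).
#'
#' @param assemblages list of `interval_assemblage` objects from a single
#'   transect (any order; they are sorted by lower bound).
#' @return data.frame: e1, e2 (indices into the sorted assemblage list),
#'   pair (label), S1, S2, direction (`"ascending"`/`"descending"`),
#'   status (`"ok"` or `"none"`).
#' @export
order_packing_pairs <- function(assemblages) {
  if (length(assemblages) < 2)
    stop("at least 2 assemblages are required")
  tr <- unique(vapply(assemblages, function(a) a$transect, ""))
  if (length(tr) > 1)
    stop("assemblages must come from a single transect")
  o <- order(vapply(assemblages, function(a) a$lower, 0))
  assemblages <- assemblages[o]
  S <- vapply(assemblages, function(a) a$S, 0)
  labs <- vapply(assemblages, function(a) as.character(a$interval), "")
  peak <- which.max(S)
  mk <- function(i, j, dir) { # pair between positions i (nearer peak) and j
    hi <- if (S[i] >= S[j]) i else j
    lo <- if (S[i] >= S[j]) j else i
    data.frame(e1 = hi, e2 = lo,
               pair = paste(labs[hi], labs[lo], sep = "-"),
               S1 = S[hi], S2 = S[lo], direction = dir,
               status = if (S[i] == S[j]) "none" else "ok",
               stringsAsFactors = FALSE)
  }
  rows <- list()
  if (peak > 1)
    for (i in seq_len(peak - 1))
      rows[[length(rows) + 1]] <- mk(i + 1, i, "ascending")
  if (peak < length(S))
    for (i in seq(length(S), peak + 1))
      rows[[length(rows) + 1]] <- mk(i - 1, i, "descending")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

hullvol <- function(pts) convhull_volume(pts)$volume

# beam search over hull-vertex removal orders: keeps the `width`
# lowest-volume candidate subsets at each removal depth, so the first
# subset to reach the volume ceiling has maximum retained richness among
# the explored orders; exact ties are broken randomly
beam_shrink <- function(E1, target, tol, width = 10) {
  states <- list(seq_len(nrow(E1)))
  repeat {
    hulls <- lapply(states, function(s)
      convhull_volume(E1[s, , drop = FALSE]))
    done <- which(vapply(hulls, function(h)
      h$degenerate || h$volume <= target * (1 + tol), TRUE))
    if (length(done)) {
      i <- done[1]
      return(list(retained = states[[i]],
                  volume = if (hulls[[i]]$degenerate) 0
                           else hulls[[i]]$volume))
    }
    children <- list(); child_vol <- numeric(0); seen <- character(0)
    for (si in seq_along(states)) {
      s <- states[[si]]
      for (v in s[hulls[[si]]$vertices]) {   # only vertices shrink the hull
        ch <- setdiff(s, v)
        ky <- paste(ch, collapse = ",")
        if (ky %in% seen) next
        seen <- c(seen, ky)
        children[[length(children) + 1L]] <- ch
        child_vol <- c(child_vol, hullvol(E1[ch, , drop = FALSE]))
      }
    }
    keep <- order(child_vol, sample.int(length(child_vol)))
    keep <- keep[seq_len(min(width, length(children)))]
    states <- children[keep]
  }
}

#' Decompose a richness difference into morphospace expansion and packing
#'
#' Given the point sets of a richer (E1) and a poorer (E2) assemblage on
#' shared morphospace axes, searches for the largest subset of E1 whose
#' convex hull volume is at most `V2 (1 + tol)`, where V2 is E2's hull
#' volume.  Species removed from E1 to reach that volume represent the
#' richness increase due to morphoniche expansion; species retained beyond
#' E2's richness represent extra richness accommodated by packing inside
#' the existing volume.  The search is a greedy peripheral removal run as
#' a beam over removal orders: at each depth only hull vertices are
#' candidates for deletion, the `n_starts` lowest-volume candidate
#' subsets are kept in parallel (exact ties broken randomly), and the
#' first subset to fall inside the volume ceiling wins, which maximizes
#' retained species over the explored removal orders.
#'
#' @param E1 point matrix of the richer assemblage (S1 x k).
#' @param E2 point matrix of the poorer assemblage (S2 x k); only its hull
#'   volume is used.
#' @param tol relative volume tolerance defining "equivalent to or in the
#'   vicinity of" V2 (default 0.01).
#' @param n_starts beam width: number of candidate removal orders kept in
#'   parallel (default 10).
#' @param k number of leading axes to use; default `min(5, S2 - 1)` so
#'   both hulls are well defined.
#' @param seed optional integer seed.
#' @return A list of class `packing_result`: S1, S2, delta_S, expansion,
#'   packing, expansion_pct, packing_pct, retained (row indices into E1),
#'   volume_e1, volume_e2, achieved_volume, volume_ratio
#'   (achieved/V2), k_used, negative_packing flag.
#' @export
decompose_packing <- function(E1, E2, tol = 0.01, n_starts = 10, k = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  E1 <- as.matrix(E1); E2 <- as.matrix(E2)
  S1 <- nrow(E1); S2 <- nrow(E2)
  if (S1 <= S2) stop("E1 must be richer than E2 (pair ordering violated)")
  if (is.null(k)) k <- min(5, S2 - 1)
  k <- min(k, ncol(E1), ncol(E2), S2 - 1)
  if (k < 1) stop("E2 too small for any axis: need S2 >= 2")
  E1 <- E1[, seq_len(k), drop = FALSE]
  E2 <- E2[, seq_len(k), drop = FALSE]
  h2 <- convhull_volume(E2)
  if (h2$degenerate || h2$volume <= 0)
    stop("E2 hull is degenerate (volume 0); reduce the number of axes")
  V2 <- h2$volume
  h1 <- convhull_volume(E1)
  best <- beam_shrink(E1, V2, tol, width = n_starts)
  retained <- length(best$retained)
  expansion <- S1 - retained
  packing <- retained - S2
  dS <- S1 - S2
  structure(list(
    S1 = S1, S2 = S2, delta_S = dS,
    expansion = expansion, packing = packing,
    expansion_pct = 100 * expansion / dS,
    packing_pct = 100 * packing / dS,
    retained = best$retained,
    volume_e1 = h1$volume, volume_e2 = V2,
    achieved_volume = best$volume,
    volume_ratio = best$volume / V2,
    k_used = k,
    negative_packing = packing < 0
  ), class = "packing_result")
}

#' @export
print.packing_result <- function(x, ...) {
  cat(sprintf(
    "Packing/expansion decomposition (k = %d): S1 = %d, S2 = %d, dS = %d\n",
    x$k_used, x$S1, x$S2, x$delta_S))
  cat(sprintf("  expansion %d (%.1f%%), packing %d (%.1f%%)%s\n",
              x$expansion, x$expansion_pct, x$packing, x$packing_pct,
              if (x$negative_packing) "  [negative packing flagged]" else ""))
  cat(sprintf("  achieved/target volume ratio: %.3f\n", x$volume_ratio))
  invisible(x)
}

#' Packing/expansion decomposition along a transect
#'
#' Applies [order_packing_pairs()] and [decompose_packing()] to every
#' adjacent pair of one transect's interval assemblages embedded in a
#' shared ordination.
#'
#' @param assemblages list of `interval_assemblage` objects from one
#'   transect.
#' @param ord an `ordination` covering all member species.
#' @param tol,n_starts,seed passed to [decompose_packing()].
#' @param k maximum number of axes (default 5; reduced per pair so both
#'   hulls are defined).
#' @return data.frame: pair, S1, S2, expansion, packing, packing_pct,
#'   expansion_pct, status, volume_ratio, k_used.
#' @export
packing_transect <- function(assemblages, ord, tol = 0.01, n_starts = 10,
                             k = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  o <- order(vapply(assemblages, function(a) a$lower, 0))
  assemblages <- assemblages[o]
  pairs <- order_packing_pairs(assemblages)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    base <- data.frame(pair = p$pair, S1 = p$S1, S2 = p$S2,
                       expansion = NA_real_, packing = NA_real_,
                       packing_pct = NA_real_, expansion_pct = NA_real_,
                       status = p$status, volume_ratio = NA_real_,
                       k_used = NA_integer_, stringsAsFactors = FALSE)
    if (p$status == "none") return(base)
    kk <- min(k, p$S2 - 1)
    E1 <- assemblage_points(ord, assemblages[[p$e1]]$species, k = kk)
    E2 <- assemblage_points(ord, assemblages[[p$e2]]$species, k = kk)
    d <- tryCatch(
      decompose_packing(E1, E2, tol = tol, n_starts = n_starts, k = kk),
      error = function(e) NULL)
    if (is.null(d)) { base$status <- "degenerate"; return(base) }
    base$expansion <- d$expansion; base$packing <- d$packing
    base$packing_pct <- d$packing_pct; base$expansion_pct <- d$expansion_pct
    base$volume_ratio <- d$volume_ratio; base$k_used <- d$k_used
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
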