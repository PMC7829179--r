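#' Convex hull volume of a point set
#'
#' Exact volume of the convex hull in the dimension of the input (an
#' incremental beneath-beyond construction; area in 2-D, volume in 3-D,
#' hypervolume above).  Affinely degenerate point sets (fewer than d + 1
#' affinely independent points) have volume 0 and are flagged.
#'
#' @param x numeric matrix (points x coordinates).
#' @return A list with `volume`, `vertices` (row indices of hull
#'   vertices; empty when degenerate) and `degenerate`.
#' @export
convhull_volume <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  .convhull_cpp(x)
}

#' Functional richness (FRic): convex hull volume in morphospace
#'
#' The volume of the minimum convex polytope enclosing an assemblage's
#' points.  When the assemblage is too small for the requested
#' dimensionality (hull volume requires S >= k + 1), the number of axes is
#' reduced to `min(k, S - 1)` and the reduction recorded.  Point sets that
#' remain affinely degenerate after reduction return volume 0 with a
#' degeneracy flag rather than an error.
#'
#' @param points S x k coordinate matrix (leading ordination axes).
#' @param k number of axes requested (default: all columns).
#' @return Numeric hull volume with attributes `k_used`, `reduced`
#'   (logical: was k lowered because of small S) and `degenerate`.
#' @export
fric <- function(points, k = NULL) {
  points <- as.matrix(points)
  S <- nrow(points)
  if (is.null(k)) k <- ncol(points)
  k <- min(k, ncol(points))
  k_used <- min(k, S - 1)
  if (k_used < 1) stop("at least 2 species are required")
  h <- convhull_volume(points[, seq_len(k_used), drop = FALSE])
  structure(h$volume, k_used = k_used, reduced = k_used < k,
            degenerate = h$degenerate)
}

#' Two-axis kernel-density hypervolume
#'
#' Gaussian kernel density estimated on the first two morphospace axes
#' (per-axis Silverman bandwidths), evaluated on a regular grid spanning
#' the data range padded by 3 bandwidths; returns the area of the
#' highest-density region enclosing the stated probability mass.  This is
#' a deliberate simplification of box-kernel importance-sampling
#' hypervolume algorithms: a plain KDE plus probability-mass contour on a
#' grid, computable with two axes only.
#'
#' @param points S x 2 coordinate matrix (extra columns are ignored with
#'   the first two used).
#' @param mass probability mass enclosed (default 0.95).
#' @param grid_n grid resolution per axis (default 200).
#' @param bw optional length-2 vector of kernel standard deviations per
#'   axis; default Silverman's rule ([stats::bw.nrd0()]) per axis.
#' @return Numeric area (squared morphospace units) with attributes
#'   `bw` and `grid_n`.
#' @export
hypervolume2d <- function(points, mass = 0.95, grid_n = 200, bw = NULL) {
  points <- as.matrix(points)
  S <- nrow(points)
  if (S < 3) stop("at least 3 species are required")
  if (ncol(points) < 2) stop("two axes are required")
  x <- points[, 1]; y <- points[, 2]
  if (is.null(bw)) bw <- c(bw.nrd0(x), bw.nrd0(y))
  if (any(bw <= 0)) stop("zero bandwidth: degenerate axis spread")
  lims <- c(range(x) + c(-3, 3) * bw[1], range(y) + c(-3, 3) * bw[2])
  # MASS::kde2d uses h/4 as the Gaussian sd
  kd <- kde2d(x, y, h = 4 * bw, n = grid_n, lims = lims)
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  z <- kd$z / (sum(kd$z) * cell)          # renormalize on the grid
  dens <- sort(as.vector(z), decreasing = TRUE)
  n_in <- which(cumsum(dens) * cell >= mass)[1]
  if (is.na(n_in)) n_in <- length(dens)
  structure(n_in * cell, bw = bw, grid_n = grid_n)
}

#' Functional evenness (FEve) for presence/absence data
#'
#' Regularity of point spacing along the minimum spanning tree (MST)
#' connecting an assemblage's points in morphospace.  With equal species
#' weights the branch "evenness weight" is the branch length; with
#' `PEW_l = EW_l / sum(EW)` over the S - 1 branches,
#' `FEve = (sum_l min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1))`,
#' which is 1 when all branches are equal and tends to 0 as spacing
#' becomes extremely uneven.
#'
#' @param points S x k coordinate matrix, S >= 3.
#' @return FEve in \[0, 1\].
#' @export
feve <- function(points) {
  points <- as.matrix(points)
  S <- nrow(points)
  if (S < 3) stop("at least 3 species are required")
  dd <- dist(points)
  if (all(dd == 0)) stop("all points identical: MST has zero length")
  ew <- spantree(dd)$dist         # the S - 1 MST branch lengths
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Nearest-neighbour distances: mean (mNND) and standard deviation (sdNND)
#'
#' For each species, the Euclidean distance to its nearest other species
#' in morphospace; returns the mean and the sd (n - 1 divisor) of these S
#' values.  Low values indicate dense packing.
#'
#' @param points S x k coordinate matrix, S >= 2.
#' @return Named numeric vector `c(mNND = , sdNND = )`.
#' @export
nnd <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("at least 2 species are required")
  storage.mode(points) <- "double"
  v <- .nnd_cpp(points)
  c(mNND = v[1], sdNND = v[2])
}

#' Functional diversity index table for a set of assemblages
#'
#' Computes FRic, Hyp, FEve, mNND and sdNND for each assemblage embedded
#' in a shared ordination.  FRic/FEve/NND use the first `k` axes (k
#' reduced per assemblage when S is small); Hyp always uses the first two
#' axes.  Indices undefined for an assemblage (e.g. S < 3 for FEve and
#' Hyp) are returned as NA.
#'
#' @param assemblages list of assemblages from [bin_plots_to_intervals()],
#'   or a named list of species-id character vectors.
#' @param ord an `ordination` covering all member species.
#' @param k number of leading axes for FRic/FEve/NND (default 5).
#' @param hyp_mass probability mass for [hypervolume2d()].
#' @return data.frame: assemblage, transect, S, FRic, Hyp, FEve, mNND,
#'   sdNND, k_used, degenerate.
#' @export
fd_indices <- function(assemblages, ord, k = 5, hyp_mass = 0.95) {
  rows <- lapply(assemblages, function(a) {
    if (inherits(a, "interval_assemblage")) {
      sp <- a$species
      id <- paste(a$transect, as.character(a$interval), sep = ":")
      tr <- a$transect
    } else {
      sp <- a; id <- NA_character_; tr <- NA_character_
    }
    pts <- assemblage_points(ord, sp, k = k)
    S <- length(sp)
    fr <- if (S >= 2) fric(pts, k = k) else NA_real_
    hy <- if (S >= 3 && ncol(ord$points) >= 2)
      as.numeric(hypervolume2d(assemblage_points(ord, sp, k = 2),
                               mass = hyp_mass)) else NA_real_
    fe <- if (S >= 3) feve(pts) else NA_real_
    nd <- if (S >= 2) nnd(pts) else c(mNND = NA_real_, sdNND = NA_real_)
    data.frame(assemblage = id, transect = tr, S = S,
               FRic = as.numeric(fr), Hyp = hy, FEve = fe,
               mNND = unname(nd[1]), sdNND = unname(nd[2]),
               k_used = if (S >= 2) attr(fr, "k_used") else NA_integer_,
               degenerate = if (S >= 2) attr(fr, "degenerate") else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(names(assemblages)) && all(is.na(out$assemblage)))
    out$assemblage <- names(assemblages)
  rownames(out) <- NULL
  out
}
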