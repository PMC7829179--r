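#' Gower dissimilarity over mixed-scale traits
#'
#' Pairwise dissimilarity as the unweighted mean over traits of per-trait
#' distances: categorical traits score 0/1 (equal/different); binary
#' traits score 0/1 symmetrically by default (joint absence counts as
#' similarity); ordinal traits use absolute differences of their coded
#' levels divided by the domain range realized in the coding
#' (`max - min` of the declared codes); continuous traits use absolute
#' differences divided by the observed min-max range of the input table.
#' A trait with zero observed range contributes 0 to every pair and is
#' flagged with a warning; if all traits are constant the dissimilarity is
#' undefined and an error is raised.
#'
#' @param traits a [trait_table()].
#' @param log_length log-transform continuous traits before
#'   range-normalization (default FALSE).
#' @param binary_asymmetric treat binary traits asymmetrically (pairs with
#'   joint absence get zero weight for that trait, Jaccard-style);
#'   default FALSE (symmetric).
#' @return An object of class `dissimilarity_matrix`: a square symmetric
#'   matrix with zero diagonal, entries in \[0, 1\], species ids as
#'   dimnames, and attribute `constant_traits` naming flagged traits.
#' @export
gower_dissimilarity <- function(traits, log_length = FALSE,
                                binary_asymmetric = FALSE) {
  stopifnot(inherits(traits, "trait_table"))
  S <- nrow(traits)
  if (S < 2) stop("at least 2 species are required")
  schema <- attr(traits, "schema")
  ids <- rownames(traits)
  num <- matrix(0, S, S)   # sum of per-trait distances
  den <- matrix(0, S, S)   # sum of per-trait weights
  constant <- character(0)
  for (tr in names(schema)) {
    x <- traits[[tr]]
    sc <- schema[[tr]]$scale
    w <- matrix(1, S, S)
    if (sc %in% c("categorical", "binary")) {
      d <- outer(x, x, FUN = "!=") + 0
      if (sc == "binary" && binary_asymmetric) {
        joint_absent <- outer(x == 0, x == 0, FUN = "&")
        w[joint_absent] <- 0
      }
      if (length(unique(x)) == 1) constant <- c(constant, tr)
    } else {
      if (sc == "continuous") {
        if (log_length) x <- log(x)
        rng <- diff(range(x))
      } else {
        rng <- diff(range(schema[[tr]]$domain))
      }
      if (rng <= 0 || length(unique(x)) == 1) {
        if (length(unique(x)) == 1) constant <- c(constant, tr)
        d <- matrix(0, S, S)
        if (rng <= 0) rng <- 1
      } else {
        d <- abs(outer(x, x, FUN = "-")) / rng
      }
    }
    num <- num + d * w
    den <- den + w
  }
  if (length(constant) == length(schema))
    stop("all traits are constant: dissimilarity undefined")
  const_cont <- constant[vapply(constant, function(tr)
    schema[[tr]]$scale %in% c("continuous", "ordinal"), TRUE)]
  if (length(const_cont))
    warning("zero-range trait(s) contribute no distance: ",
            paste(const_cont, collapse = ", "))
  den[den == 0] <- 1           # all-absent binary-only pairs
  D <- num / den
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  structure(D, constant_traits = constant,
            class = c("dissimilarity_matrix", "matrix", "array"))
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical metric scaling: the squared dissimilarities are double
#' centered, eigendecomposed, and coordinates scaled by the square roots
#' of the positive eigenvalues.  Negative eigenvalues (Gower
#' dissimilarities need not be Euclidean) are discarded without correction
#' and counted, so the reported variance fractions are relative to the sum
#' of positive eigenvalues only.
#'
#' @param d a `dissimilarity_matrix` (or any square symmetric
#'   dissimilarity matrix).
#' @param n_axes number of axes requested (default 5); if fewer positive
#'   eigenvalues are available, fewer axes are returned with
#'   `truncated = TRUE`.
#' @return An object of class `ordination`: a list with `points` (species
#'   x axis coordinates), `eig` (positive eigenvalues, descending),
#'   `rel_eig` (variance explained per retained axis), `cum_var`
#'   (cumulative variance explained over all positive axes),
#'   `n_negative` (count of discarded negative eigenvalues) and
#'   `truncated`.
#' @export
trait_pcoa <- function(d, n_axes = 5) {
  d <- unclass(as.matrix(d))
  S <- nrow(d)
  if (S != ncol(d) || any(abs(d - t(d)) > 1e-12))
    stop("d must be a square symmetric dissimilarity matrix")
  if (n_axes > S - 1) stop("n_axes must be at most S - 1")
  # cmdscale warns whenever eigenvalues are non-positive, which is the
  # norm for Gower input; negatives are counted and reported instead
  fit <- suppressWarnings(cmdscale(d, k = S - 1, eig = TRUE))
  tol <- 1e-8 * max(abs(fit$eig))
  pos <- fit$eig[fit$eig > tol]
  n_neg <- sum(fit$eig < -tol)
  n_avail <- length(pos)
  truncated <- n_axes > n_avail
  if (truncated)
    warning("only ", n_avail, " positive eigenvalues; returning ",
            n_avail, " axes")
  k <- min(n_axes, n_avail)
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_len(k))
  rel <- pos / sum(pos)
  structure(list(points = pts, eig = pos, rel_eig = rel[seq_len(k)],
                 cum_var = cumsum(rel), n_negative = n_neg,
                 truncated = truncated),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  k <- ncol(x$points)
  cat("PCoA ordination:", nrow(x$points), "species,", k, "axes retained\n")
  cat(sprintf("  variance explained (cumulative over retained axes): %.1f%%\n",
              100 * x$cum_var[k]))
  cat("  negative eigenvalues discarded:", x$n_negative, "\n")
  invisible(x)
}

#' Write an ordination to CSV
#'
#' Writes the species x axis coordinates plus a sidecar eigenvalue table
#' (`<path>` and `<path base>_eig.csv`).
#'
#' @param x an `ordination`.
#' @param path output CSV for the coordinates.
#' @return `path`, invisibly.
#' @export
write_ordination <- function(x, path) {
  df <- cbind(species = rownames(x$points), as.data.frame(x$points))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  eigpath <- sub("\\.csv$", "", path)
  eigpath <- paste0(eigpath, "_eig.csv")
  eig <- data.frame(axis = seq_along(x$eig), eigenvalue = x$eig,
                    cum_var = x$cum_var)
  write.table(eig, eigpath, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the morphospace point set of an assemblage
#'
#' @param ord an `ordination`.
#' @param species character vector of member species ids.
#' @param k number of leading axes to use (default all retained).
#' @return Numeric matrix (S x k) of member coordinates.
#' @export
assemblage_points <- function(ord, species, k = NULL) {
  if (is.null(k)) k <- ncol(ord$points)
  k <- min(k, ncol(ord$points))
  miss <- setdiff(species, rownames(ord$points))
  if (length(miss))
    stop("species absent from the ordination: ",
         paste(head(miss, 5), collapse = ", "))
  ord$points[species, seq_len(k), drop = FALSE]
}
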