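#' Read and validate a newick phylogeny
#'
#' Reads a newick tree and checks it is usable for phylogenetic-signal
#' tests: unique tip labels, branch lengths present and non-negative,
#' and (optionally) tips matching a set of species ids.
#'
#' @param path newick file path.
#' @param species_ids optional character vector the tip labels must
#'   match exactly (set equality).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_phylogeny <- function(path, species_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths")
  if (!is.null(species_ids) && !setequal(tree$tip.label, species_ids))
    stop("tip labels and species ids differ: ",
         paste(head(c(setdiff(tree$tip.label, species_ids),
                      setdiff(species_ids, tree$tip.label)), 5),
               collapse = ", "))
  tree
}

match_tree_trait <- function(tree, x) {
  if (is.null(names(x))) stop("trait values must be named by species")
  tips <- tree$tip.label
  if (anyDuplicated(tips)) stop("duplicated tip labels")
  if (!setequal(tips, names(x)))
    stop("tip labels and trait names differ: ",
         paste(head(c(setdiff(tips, names(x)), setdiff(names(x), tips)), 5),
               collapse = ", "))
  x[tips]
}

#' Blomberg's K for a continuous trait on a phylogeny
#'
#' Ratio-based measure of phylogenetic signal.  With phylogenetic
#' covariance matrix `V` (shared branch lengths) and phylogenetic mean
#' `a = (1'V^-1 x)/(1'V^-1 1)`, the observed ratio is
#' `MSE0/MSE = (x-a)'(x-a) / (x-a)'V^-1(x-a)` and its Brownian-motion
#' expectation is `(tr(V) - n/(1'V^-1 1))/(n - 1)`; K is observed over
#' expected.  K is near 1 when the trait evolved by Brownian motion on the
#' tree (conservatism for K >= 1) and near 0 under convergence.  K is
#' invariant to affine transformations of the trait.
#'
#' @param tree a rooted `phylo` with branch lengths; tips must match the
#'   trait names (ultrametricity not required).
#' @param x named numeric vector of trait values (e.g. one PCoA axis).
#' @return Numeric K (>= 0).
#' @export
blomberg_k <- function(tree, x) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (Ntip(tree) < 4) stop("at least 4 species are required")
  x <- match_tree_trait(tree, x)
  V <- vcv(tree)
  n <- length(x)
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular phylogenetic covariance matrix (zero-length ",
         "duplicate tips?): ", conditionMessage(e)))
  ones <- rep(1, n)
  denom1 <- as.numeric(ones %*% Vi %*% ones)
  ahat <- as.numeric(ones %*% Vi %*% x) / denom1
  dev <- x - ahat
  mse0 <- sum(dev * dev)
  mse <- as.numeric(dev %*% Vi %*% dev)
  if (mse <= 0) return(0)
  expected <- (sum(diag(V)) - n / denom1) / (n - 1)
  (mse0 / mse) / expected
}

#' Tip-shuffle significance test for phylogenetic signal
#'
#' Computes Blomberg's K for the observed trait and tests significance by
#' randomly shuffling the taxa labels across the tips `n_reps` times and
#' comparing the variance of phylogenetically independent contrasts
#' (PICs): low observed contrast variance relative to the null indicates
#' signal.  Both tail probabilities are reported because a near-zero K
#' can be "significant" in either direction:
#' `p_signal = (1 + #\{null PIC var <= observed\})/(n_reps + 1)` and
#' `p_anti` symmetric.  Polytomies are resolved with zero-length branches
#' before contrast computation.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param x named numeric vector of trait values.
#' @param n_reps number of tip shuffles (default 999).
#' @param seed optional integer seed.
#' @return A one-row data.frame of class `k_result`: K, pic_var_obs,
#'   p_signal, p_anti, n_reps.
#' @export
k_test <- function(tree, x, n_reps = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- match_tree_trait(tree, x)
  K <- blomberg_k(tree, x)
  btree <- if (is.binary(tree)) tree else multi2di(tree, random = FALSE)
  pic_var <- function(v) {
    contrasts <- pic(v, btree)
    mean(contrasts^2)
  }
  obs <- pic_var(x)
  null <- vapply(seq_len(n_reps), function(r) {
    xs <- x
    names(xs) <- sample(names(x))
    pic_var(xs[btree$tip.label])
  }, 0)
  p_signal <- (1 + sum(null <= obs)) / (n_reps + 1)
  p_anti <- (1 + sum(null >= obs)) / (n_reps + 1)
  structure(data.frame(K = K, pic_var_obs = obs, p_signal = p_signal,
                       p_anti = p_anti, n_reps = n_reps),
            class = c("k_result", "data.frame"))
}

#' Phylogenetic signal of leading morphospace axes
#'
#' Runs [k_test()] on each of the first `n_axes` PCoA axes (the study
#' design tests axes 1 and 2 separately).
#'
#' @param tree a rooted `phylo`.
#' @param ord an `ordination` whose species match the tree tips.
#' @param n_axes number of leading axes to test (default 2).
#' @param n_reps tip shuffles per axis (default 999).
#' @param seed optional integer seed.
#' @return data.frame: axis, K, p_signal, p_anti, n_reps.
#' @export
axis_signal <- function(tree, ord, n_axes = 2, n_reps = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_axes <- min(n_axes, ncol(ord$points))
  out <- lapply(seq_len(n_axes), function(a) {
    x <- setNames(ord$points[, a], rownames(ord$points))
    cbind(axis = a, k_test(tree, x, n_reps = n_reps))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
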