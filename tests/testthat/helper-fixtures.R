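# shared fixtures and independent oracles, built in code

# minimal valid trait rows
make_traits <- function(df, ids = rownames(df)) {
  trait_table(df, species_ids = ids)
}

two_species_traits <- function() {
  make_traits(data.frame(
    rhizome_type = c(1, 1), laminar_dissection = c(0, 2),
    laminar_texture = c(1, 3), laminar_length = c(10, 30),
    hydathodes = c(0, 1), row.names = c("A", "B")))
}

# shoelace polygon area via grDevices::chull: independent 2-D hull oracle
shoelace_area <- function(p) {
  h <- chull(p)
  p <- p[h, , drop = FALSE]
  n <- nrow(p)
  s <- 0
  for (i in seq_len(n)) {
    j <- i %% n + 1
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  abs(s) / 2
}

unit_square <- function() rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

# exhaustive maximum-cardinality subset with hull volume <= target*(1+tol):
# brute-force oracle for the greedy packing search
best_subset_size <- function(E1, target, tol = 0.01) {
  S1 <- nrow(E1)
  for (size in S1:1) {
    for (idx in combn(S1, size, simplify = FALSE)) {
      h <- convhull_volume(E1[idx, , drop = FALSE])
      v <- if (h$degenerate) 0 else h$volume
      if (v <= target * (1 + tol)) return(size)
    }
  }
  0
}

# balanced 4-tip tree with unit branches for the PIC hand oracle
four_tip_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# lightweight assemblage stubs for pair ordering
stub_assemblages <- function(S, transect = "T1") {
  lapply(seq_along(S), function(i) {
    structure(list(interval = utils::as.roman(i), lower = (i - 1) * 500,
                   upper = i * 500, transect = transect,
                   plot_ids = character(0),
                   species = sprintf("s%d_%d", i, seq_len(S[i])),
                   S = S[i], incidence = NULL),
              class = "interval_assemblage")
  })
}
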