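#' Construct and validate plot-by-species community data
#'
#' Stores a binary plot x species incidence matrix together with plot
#' metadata (transect label and elevation).  Abundances, if supplied, are
#' binarized: all analyses are presence/absence based.
#'
#' @param incidence plot x species matrix (numeric; any positive entry is
#'   treated as a presence).
#' @param elevation_m numeric vector of plot elevations (m, >= 0).
#' @param transect character vector of transect labels per plot (recycled
#'   if length 1).
#' @param plot_ids plot identifiers; default row names of `incidence`.
#' @param drop_empty_species drop species recorded in no plot (default
#'   TRUE; the class invariant requires every species to occur somewhere).
#' @return An object of class `community_data`: a list with elements
#'   `plots` (data.frame: plot_id, transect, elevation_m), `incidence`
#'   (binary matrix) and `species_ids`.
#' @export
community_data <- function(incidence, elevation_m, transect = "T1",
                           plot_ids = rownames(incidence),
                           drop_empty_species = TRUE) {
  incidence <- as.matrix(incidence)
  n <- nrow(incidence)
  if (is.null(plot_ids)) plot_ids <- paste0("plot", seq_len(n))
  plot_ids <- as.character(plot_ids)
  if (anyDuplicated(plot_ids)) stop("duplicated plot ids")
  if (length(elevation_m) != n)
    stop("elevation_m length does not match the number of plots")
  if (any(!is.finite(elevation_m))) stop("elevations must be finite")
  if (any(elevation_m < 0)) stop("negative elevation")
  transect <- rep_len(as.character(transect), n)
  if (is.null(colnames(incidence)))
    stop("incidence must have species names as column names")
  if (any(!is.finite(incidence)) || any(incidence < 0))
    stop("incidence entries must be finite and non-negative")
  incidence <- (incidence > 0) + 0L
  storage.mode(incidence) <- "integer"
  if (drop_empty_species) {
    keep <- colSums(incidence) > 0
    incidence <- incidence[, keep, drop = FALSE]
  } else if (any(colSums(incidence) == 0)) {
    stop("species occurring in no plot: ",
         paste(head(colnames(incidence)[colSums(incidence) == 0], 5),
               collapse = ", "))
  }
  rownames(incidence) <- plot_ids
  structure(list(
    plots = data.frame(plot_id = plot_ids, transect = transect,
                       elevation_m = as.numeric(elevation_m),
                       stringsAsFactors = FALSE),
    incidence = incidence,
    species_ids = colnames(incidence)
  ), class = "community_data")
}

#' @export
print.community_data <- function(x, ...) {
  cat("Community data:", nrow(x$incidence), "plots,",
      ncol(x$incidence), "species,",
      length(unique(x$plots$transect)), "transect(s)\n")
  cat("  elevations:", min(x$plots$elevation_m), "-",
      max(x$plots$elevation_m), "m\n")
  invisible(x)
}

#' Read a community matrix from CSV/TSV
#'
#' Expected columns: `plot_id`, `transect`, `elevation_m`, then one 0/1
#' column per species.  Abundance entries are binarized on read.
#'
#' @param path file path.
#' @param sep field separator.
#' @return A [community_data()] object.
#' @export
read_community <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  need <- c("plot_id", "transect", "elevation_m")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  spcols <- setdiff(names(df), need)
  inc <- as.matrix(df[spcols])
  rownames(inc) <- df$plot_id
  community_data(inc, elevation_m = df$elevation_m,
                 transect = df$transect, plot_ids = df$plot_id)
}

#' Write community data to CSV/TSV
#'
#' @param x a [community_data()] object.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_community <- function(x, path, sep = ",") {
  df <- cbind(x$plots, as.data.frame(x$incidence))
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bin plots into elevational intervals and pool their species lists
#'
#' Plots are assigned to half-open elevation bands `[0, first_bound)`,
#' `[first_bound, first_bound + width)`, ... (default 0--400 m then 500-m
#' bands: 400--900, 900--1400, ...).  Within each transect, every occupied
#' band becomes one assemblage whose species list is the union of
#' presences over its member plots; empty bands are omitted.
#'
#' @param community a [community_data()] object.
#' @param width band width in metres (default 500).
#' @param first_bound upper bound of the irregular first band (default
#'   400).
#' @return A list of `interval_assemblage` objects, each a list with
#'   elements `interval` (roman label), `lower`, `upper`, `transect`,
#'   `plot_ids`, `species` (pooled, duplicate-free), `S` and `incidence`
#'   (member-plot x pooled-species submatrix), ordered by transect then
#'   elevation.
#' @export
bin_plots_to_intervals <- function(community, width = 500,
                                   first_bound = 400) {
  stopifnot(inherits(community, "community_data"))
  elev <- community$plots$elevation_m
  if (any(elev < 0)) stop("negative elevation")
  # band index: 0 for [0, first_bound), then 1, 2, ... per `width`
  band <- ifelse(elev < first_bound, 0L,
                 1L + floor((elev - first_bound) / width))
  lower <- ifelse(band == 0L, 0, first_bound + (band - 1L) * width)
  upper <- ifelse(band == 0L, first_bound, first_bound + band * width)
  out <- list()
  for (tr in unique(community$plots$transect)) {
    sel <- community$plots$transect == tr
    for (b in sort(unique(band[sel]))) {
      rows <- which(sel & band == b)
      inc <- community$incidence[rows, , drop = FALSE]
      pooled <- colnames(inc)[colSums(inc) > 0]
      out[[length(out) + 1L]] <- structure(list(
        interval = as.roman(b + 1L),
        lower = unname(lower[rows[1]]),
        upper = unname(upper[rows[1]]),
        transect = tr,
        plot_ids = community$plots$plot_id[rows],
        species = pooled,
        S = length(pooled),
        incidence = inc[, pooled, drop = FALSE]
      ), class = "interval_assemblage")
    }
  }
  out
}

#' @export
print.interval_assemblage <- function(x, ...) {
  cat(sprintf("Interval %s (%d-%d m, %s): %d plots, S = %d\n",
              as.character(x$interval), x$lower, x$upper, x$transect,
              length(x$plot_ids), x$S))
  invisible(x)
}

#' Tabulate interval assemblages
#'
#' @param assemblages list of assemblages from [bin_plots_to_intervals()].
#' @return data.frame with one row per assemblage: transect, interval,
#'   lower, upper, n_plots, S.
#' @export
assemblage_table <- function(assemblages) {
  do.call(rbind, lapply(assemblages, function(a)
    data.frame(transect = a$transect, interval = as.character(a$interval),
               lower = a$lower, upper = a$upper,
               n_plots = length(a$plot_ids), S = a$S,
               stringsAsFactors = FALSE)))
}
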