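#' Bias-corrected Chao2 incidence-based richness estimate
#'
#' Incidence form with plots as sampling units:
#' `S_chao = S_obs + ((m - 1)/m) * Q1 (Q1 - 1) / (2 (Q2 + 1))`,
#' where Q1 and Q2 are the numbers of species found in exactly one and
#' exactly two plots and m is the number of plots.  With a single plot the
#' corrected form is undefined; the observed richness is returned with an
#' insufficiency flag.
#'
#' @param incidence binary plot x species matrix for one interval.
#' @return A one-row data.frame: S_obs, Q1, Q2, m, S_chao, pct_excess
#'   (`(S_chao - S_obs)/S_obs * 100`), flag (`"ok"` or
#'   `"insufficient_plots"`).
#' @export
chao2 <- function(incidence) {
  incidence <- (as.matrix(incidence) > 0) + 0
  m <- nrow(incidence)
  counts <- colSums(incidence)
  counts <- counts[counts > 0]
  S_obs <- length(counts)
  Q1 <- sum(counts == 1)
  Q2 <- sum(counts == 2)
  if (m < 2) {
    return(data.frame(S_obs = S_obs, Q1 = Q1, Q2 = Q2, m = m,
                      S_chao = S_obs, pct_excess = 0,
                      flag = "insufficient_plots",
                      stringsAsFactors = FALSE))
  }
  S_chao <- S_obs + ((m - 1) / m) * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
  data.frame(S_obs = S_obs, Q1 = Q1, Q2 = Q2, m = m, S_chao = S_chao,
             pct_excess = 100 * (S_chao - S_obs) / S_obs, flag = "ok",
             stringsAsFactors = FALSE)
}

#' Chao2 richness estimates for all interval assemblages
#'
#' @param assemblages list from [bin_plots_to_intervals()] (each carries
#'   its member-plot incidence submatrix).
#' @return data.frame with one row per assemblage: transect, interval,
#'   then the [chao2()] columns.
#' @export
chao_richness <- function(assemblages) {
  rows <- lapply(assemblages, function(a)
    cbind(data.frame(transect = a$transect,
                     interval = as.character(a$interval),
                     stringsAsFactors = FALSE),
          chao2(a$incidence)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' R-squared of estimated on observed richness
#'
#' Ordinary least-squares R2 of the Chao estimates regressed on the
#' observed richness values, used as a sampling-evenness diagnostic: high
#' values indicate that sampling incompleteness is roughly evenly spread
#' across intervals.
#'
#' @param S_obs numeric vector of observed richness.
#' @param S_chao numeric vector of estimated richness (same length).
#' @return R2 in \[0, 1\].
#' @export
obs_vs_est_r2 <- function(S_obs, S_chao) {
  if (length(S_obs) != length(S_chao)) stop("length mismatch")
  if (length(S_obs) < 3) stop("at least 3 pairs are required")
  if (var(S_obs) == 0) stop("zero variance in observed richness")
  if (var(S_chao) == 0) stop("zero variance in estimated richness")
  cor(S_obs, S_chao)^2   # OLS R2 of the simple regression
}
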